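# Novelty filtering: left-normalize indel representations against the
# reference, subtract the original call set by exact normalized-key
# equality, keep PASS calls, and summarize what remains. Left-normalization
# gives every indel its unique leftmost VCF representation, so two callers
# describing the same physical event in a repeat cannot evade the match.

#' Left-normalize one indel to its canonical VCF representation
#'
#' While both alleles end in the same base, that base is dropped; whenever an
#' allele empties, both alleles are extended one reference base to the left.
#' Terminates at the unique leftmost anchored representation; idempotent.
#'
#' @param chrom,pos,ref,alt the indel (1-based anchored VCF convention).
#' @param reference named character vector of contigs.
#' @return list with `chrom`, `pos`, `ref`, `alt`.
#' @export
left_normalize <- function(chrom, pos, ref, alt, reference) {
  chrom_seq <- reference[[chrom]]
  if (is.null(chrom_seq)) stop("contig not in reference: ", chrom)
  if (substr(chrom_seq, pos, pos + nchar(ref) - 1L) != ref)
    stop("REF allele inconsistent with reference at ", chrom, ":", pos)
  r <- ref; a <- alt; p <- pos
  repeat {
    nr <- nchar(r); na <- nchar(a)
    if (nr == 1L && na == 1L) break
    if (substr(r, nr, nr) != substr(a, na, na)) break
    r2 <- substr(r, 1L, nr - 1L)
    a2 <- substr(a, 1L, na - 1L)
    if (nchar(r2) == 0L || nchar(a2) == 0L) {
      if (p == 1L) break               # cannot extend past the contig start
      prev <- substr(chrom_seq, p - 1L, p - 1L)
      r <- paste0(prev, r2); a <- paste0(prev, a2); p <- p - 1L
    } else {
      r <- r2; a <- a2
    }
  }
  # trim common leading bases while both alleles keep an anchor base
  while (nchar(r) > 1L && nchar(a) > 1L &&
         substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
    r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a)); p <- p + 1L
  }
  list(chrom = chrom, pos = p, ref = r, alt = a)
}

#' Left-normalize a variant table
#'
#' @param variants variant data.frame.
#' @param reference named character vector of contigs.
#' @return the table with `pos`, `ref`, `alt` normalized.
#' @export
normalize_indels <- function(variants, reference) {
  for (i in seq_len(nrow(variants))) {
    nm <- left_normalize(variants$chrom[i], variants$pos[i], variants$ref[i],
                         variants$alt[i], reference)
    variants$pos[i] <- nm$pos
    variants$ref[i] <- nm$ref
    variants$alt[i] <- nm$alt
  }
  variants
}

indel_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Subtract the original call set from new calls
#'
#' Both sides are left-normalized; a new call is kept iff its normalized key
#' (chrom, pos, ref, alt) does not occur in the original set.
#'
#' @param new_calls,original_calls variant data.frames.
#' @param reference named character vector of contigs.
#' @return the novel subset of `new_calls` (normalized representation).
#' @export
subtract_indels <- function(new_calls, original_calls, reference) {
  nn <- normalize_indels(new_calls, reference)
  no <- normalize_indels(original_calls, reference)
  out <- nn[!(indel_key(nn) %in% indel_key(no)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only PASS-filtered variants
#'
#' @param variants variant data.frame with a `filter` column.
#' @return the PASS subset.
#' @export
filter_pass <- function(variants) {
  out <- variants[variants$filter == "PASS", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify indels by kind, reading frame and length
#'
#' Length is the allele-length difference (the anchor base does not count);
#' an indel is frameshift iff its length is not a multiple of 3.
#'
#' @param ref,alt character vectors of anchored alleles.
#' @return data.frame with `kind` (`insertion`/`deletion`),
#'   `frame` (`frameshift`/`in-frame`) and `length` (signed: negative for
#'   deletions).
#' @export
classify_indel <- function(ref, alt) {
  len <- nchar(alt) - nchar(ref)
  if (any(len == 0L)) stop("length-0 allele pair is not an indel")
  data.frame(kind = ifelse(len > 0L, "insertion", "deletion"),
             frame = ifelse(abs(len) %% 3L != 0L, "frameshift", "in-frame"),
             length = len, stringsAsFactors = FALSE)
}

#' Summarize an indel set
#'
#' @param variants variant data.frame (may be empty).
#' @return list of class `indel_summary`: counts of insertions/deletions and
#'   frameshift/in-frame indels, the deletion:insertion ratio (2 decimals;
#'   `NA` for an empty set), percentage shares (2 decimals), and a signed
#'   length histogram (negative lengths are deletions).
#' @export
summarize_indels <- function(variants) {
  if (!nrow(variants)) {
    return(structure(list(n_insertions = 0L, n_deletions = 0L, n_total = 0L,
                          del_ins_ratio = NA_real_,
                          insertion_share = NA_real_,
                          deletion_share = NA_real_,
                          n_frameshift = 0L, n_inframe = 0L,
                          length_histogram = integer(0)),
                     class = "indel_summary"))
  }
  cls <- classify_indel(variants$ref, variants$alt)
  n_ins <- sum(cls$kind == "insertion")
  n_del <- sum(cls$kind == "deletion")
  hist <- table(cls$length)
  out <- list(
    n_insertions = n_ins, n_deletions = n_del, n_total = n_ins + n_del,
    del_ins_ratio = if (n_ins > 0L) round(n_del / n_ins, 2) else NA_real_,
    insertion_share = round(100 * n_ins / (n_ins + n_del), 2),
    deletion_share = round(100 * n_del / (n_ins + n_del), 2),
    n_frameshift = sum(cls$frame == "frameshift"),
    n_inframe = sum(cls$frame == "in-frame"),
    length_histogram = stats::setNames(as.integer(hist), names(hist)))
  structure(out, class = "indel_summary")
}

#' @export
print.indel_summary <- function(x, ...) {
  cat("Indel summary\n")
  cat(sprintf("  insertions: %d (%.2f%%)\n", x$n_insertions,
              x$insertion_share %||% NA))
  cat(sprintf("  deletions:  %d (%.2f%%)\n", x$n_deletions,
              x$deletion_share %||% NA))
  cat(sprintf("  total:      %d\n", x$n_total))
  cat(sprintf("  deletion:insertion ratio: %s\n",
              format(x$del_ins_ratio)))
  cat(sprintf("  frameshift: %d, in-frame: %d\n", x$n_frameshift,
              x$n_inframe))
  invisible(x)
}

#' Subtype-specific indels
#'
#' An indel is specific to a subtype when it occurs in at least one sample of
#' that subtype and in no sample of the other. Exactly two subtypes must be
#' present.
#'
#' @param per_sample_keys named list: sample id -> character vector of indel
#'   keys (e.g. from `indel_key()` on normalized calls).
#' @param labels data.frame with `sample_id` and `subtype`.
#' @return named list: subtype -> character vector of specific indel keys.
#' @export
subtype_specific <- function(per_sample_keys, labels) {
  labs <- labels$subtype[match(names(per_sample_keys), labels$sample_id)]
  if (any(is.na(labs)))
    stop("sample(s) without subtype label: ",
         paste(names(per_sample_keys)[is.na(labs)], collapse = ", "))
  subs <- sort(unique(labs))
  if (length(subs) != 2L)
    stop("subtype specificity is defined for exactly two subtypes, got ",
         length(subs))
  seen <- lapply(subs, function(s)
    unique(unlist(per_sample_keys[labs == s], use.names = FALSE)))
  names(seen) <- subs
  list2 <- list(setdiff(seen[[1]], seen[[2]]), setdiff(seen[[2]], seen[[1]]))
  names(list2) <- subs
  list2
}

#' Pearson chi-square homogeneity test of two signed length histograms
#'
#' Builds a 2 x L contingency table over the union of signed lengths; columns
#' whose combined expected count falls below 5 are pooled into their nearest
#' flanking column before testing.
#'
#' @param hist_a,hist_b named numeric vectors (names = signed indel lengths).
#' @return list with `statistic`, `p_value`, `df` and the pooled `table`.
#' @export
length_dist_chisq <- function(hist_a, hist_b) {
  if (!length(hist_a) || !length(hist_b))
    stop("both histograms must be non-empty")
  lens <- sort(unique(as.integer(c(names(hist_a), names(hist_b)))))
  tab <- rbind(a = as.numeric(hist_a[as.character(lens)]),
               b = as.numeric(hist_b[as.character(lens)]))
  tab[is.na(tab)] <- 0
  colnames(tab) <- as.character(lens)
  # pool sparse columns into their nearest flanking column
  repeat {
    if (ncol(tab) <= 2L) break
    # smallest expected count in each column under homogeneity
    low <- which(colSums(tab) * min(rowSums(tab)) / sum(tab) < 5)
    if (!length(low)) break
    j <- low[1]
    k <- if (j == 1L) 2L else j - 1L
    tab[, k] <- tab[, k] + tab[, j]
    colnames(tab)[k] <- paste(colnames(tab)[k], colnames(tab)[j], sep = "|")
    tab <- tab[, -j, drop = FALSE]
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       df = unname(ct$parameter), table = tab)
}
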