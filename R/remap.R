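# Two-tier remapping of QC'd reads. Both tiers satisfy the same aligner
# contract: a deterministic function from (read, reference) to at most one
# alignment record. The built-in aligner is seed-and-extend with affine-gap
# dynamic programming (match 1, mismatch -4, gap open -6, gap extend -1);
# tier two is the same engine with a shorter seed, standing in for a more
# sensitive second-pass aligner. MAPQ is a uniqueness proxy:
# min(60, best score - second-best candidate score).

#' Built-in seed-and-extend aligner
#'
#' @param seed_len exact-seed length anchoring candidate windows.
#' @param band half-width of the DP window around a candidate diagonal; also
#'   the largest indel shift recoverable.
#' @param match,mismatch,gap_open,gap_extend alignment scores (a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @param min_score_frac minimum alignment score as a fraction of
#'   `read length * match`; lower-scoring reads are reported unaligned.
#' @param max_candidates candidate diagonals evaluated per read.
#' @return list of class `indel_aligner`.
#' @export
aligner_builtin <- function(seed_len = 19L, band = 50L, match = 1L,
                            mismatch = -4L, gap_open = -6L, gap_extend = -1L,
                            min_score_frac = 0.25, max_candidates = 8L) {
  structure(list(seed_len = as.integer(seed_len), band = as.integer(band),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score_frac = min_score_frac,
                 max_candidates = as.integer(max_candidates)),
            class = "indel_aligner")
}

#' Sensitive variant of the built-in aligner (second tier)
#'
#' Same engine with an 11-base seed, catching reads whose longest exact
#' match to the reference is too short for the first tier.
#'
#' @param ... overrides passed to [aligner_builtin()].
#' @export
aligner_builtin_sensitive <- function(...) {
  args <- list(...)
  args$seed_len <- args$seed_len %||% 11L
  do.call(aligner_builtin, args)
}

#' Align reads against a reference
#'
#' @param reads FASTQ-style data.frame.
#' @param reference named character vector of contigs.
#' @param aligner an [aligner_builtin()] object.
#' @return list with `alignments` (SAM-style data.frame, one row per aligned
#'   read, flag 0) and `unaligned` (read ids that found no alignment).
#' @export
align_reads <- function(reads, reference, aligner = aligner_builtin()) {
  stopifnot(inherits(aligner, "indel_aligner"), length(names(reference)) > 0L)
  n <- nrow(reads)
  best <- data.frame(aligned = logical(n), pos = rep(NA_integer_, n),
                     mapq = rep(NA_integer_, n), score = rep(NA_integer_, n),
                     cigar = rep(NA_character_, n),
                     rname = rep(NA_character_, n),
                     stringsAsFactors = FALSE)
  for (contig in names(reference)) {
    res <- cpp_align_reads(reference[[contig]], reads$sequence,
                           aligner$seed_len, aligner$band, aligner$match,
                           aligner$mismatch, aligner$gap_open,
                           aligner$gap_extend, aligner$min_score_frac,
                           aligner$max_candidates)
    better <- res$aligned & (!best$aligned | res$score > best$score)
    if (any(better)) {
      best$aligned[better] <- TRUE
      best$pos[better] <- res$pos[better]
      best$mapq[better] <- res$mapq[better]
      best$score[better] <- res$score[better]
      best$cigar[better] <- res$cigar[better]
      best$rname[better] <- contig
    }
  }
  hit <- best$aligned
  nh <- sum(hit)
  alignments <- data.frame(
    qname = reads$read_id[hit], flag = rep(0L, nh), rname = best$rname[hit],
    pos = best$pos[hit], mapq = best$mapq[hit], cigar = best$cigar[hit],
    rnext = rep("*", nh), pnext = rep(0L, nh), tlen = rep(0L, nh),
    seq = reads$sequence[hit], qual = reads$qual[hit],
    tags = if (nh) paste0("AS:i:", best$score[hit]) else character(0),
    score = best$score[hit],
    stringsAsFactors = FALSE)
  list(alignments = alignments, unaligned = reads$read_id[!hit])
}

#' Two-tier mapping of rescued reads
#'
#' Reads are first given to the primary aligner; only reads it fails on are
#' passed to the secondary aligner, so no read can receive two alignments.
#'
#' @param reads FASTQ-style data.frame.
#' @param reference named character vector of contigs.
#' @param primary,secondary aligner objects.
#' @return list with `alignments` (merged) and `stats` (`total`,
#'   `tier1_mapped`, `tier2_mapped`, `still_unmapped`, `mapped_fraction`).
#' @export
two_tier_map <- function(reads, reference,
                         primary = aligner_builtin(),
                         secondary = aligner_builtin_sensitive()) {
  t1 <- align_reads(reads, reference, primary)
  rest <- reads[reads$read_id %in% t1$unaligned, , drop = FALSE]
  t2 <- align_reads(rest, reference, secondary)
  merged <- rbind(t1$alignments, t2$alignments)
  rownames(merged) <- NULL
  stats <- list(total = nrow(reads),
                tier1_mapped = nrow(t1$alignments),
                tier2_mapped = nrow(t2$alignments),
                still_unmapped = length(t2$unaligned),
                mapped_fraction = if (nrow(reads) == 0L) 0 else
                  (nrow(t1$alignments) + nrow(t2$alignments)) / nrow(reads))
  list(alignments = merged, stats = stats)
}

# unclipped 5' position of an alignment: leftmost mapped base minus leading
# soft clip on the plus strand; rightmost mapped base plus trailing soft clip
# on the minus strand
unclipped_5prime <- function(alignments) {
  n <- nrow(alignments)
  out <- integer(n)
  minus <- bitwAnd(alignments$flag, 16L) != 0L
  for (i in seq_len(n)) {
    p <- parse_cigar(alignments$cigar[i])
    if (!minus[i]) {
      lead <- if (nrow(p) && p$op[1] == "S") p$len[1] else 0L
      out[i] <- alignments$pos[i] - lead
    } else {
      trail <- if (nrow(p) && p$op[nrow(p)] == "S") p$len[nrow(p)] else 0L
      out[i] <- alignments$pos[i] + sum(p$len[p$op %in% c("M", "D", "N", "=", "X")]) - 1L + trail
    }
  }
  out
}

#' Mark duplicate alignments
#'
#' Records are grouped by (contig, unclipped 5' position, strand); within a
#' group the record with the highest base-quality sum keeps its flag, the
#' rest get bit 0x400 set. Ties are broken by query-name order.
#'
#' @param alignments mapped SAM-style data.frame.
#' @return list with `alignments` (flags updated) and `n_duplicates`.
#' @export
mark_duplicates <- function(alignments) {
  if (!nrow(alignments))
    return(list(alignments = alignments, n_duplicates = 0L))
  strand <- ifelse(bitwAnd(alignments$flag, 16L) != 0L, "-", "+")
  key <- paste(alignments$rname, unclipped_5prime(alignments), strand,
               sep = "\r")
  qsum <- vapply(alignments$qual, function(q)
    if (q == "*") 0L else sum(utf8ToInt(q) - 33L), integer(1),
    USE.NAMES = FALSE)
  ord <- order(key, -qsum, alignments$qname)
  dup <- duplicated(key[ord])
  mark <- logical(nrow(alignments))
  mark[ord] <- dup
  alignments$flag <- ifelse(mark, bitwOr(alignments$flag, 1024L),
                            alignments$flag)
  list(alignments = alignments, n_duplicates = sum(mark))
}

#' Mean mapping quality of non-duplicate mapped records
#'
#' @param alignments SAM-style data.frame.
#' @return arithmetic mean MAPQ; 0 with a warning for empty input.
#' @export
mean_mapq <- function(alignments) {
  keep <- bitwAnd(alignments$flag, 4L) == 0L &
    bitwAnd(alignments$flag, 1024L) == 0L
  if (!any(keep)) {
    warning("no mapped non-duplicate records; mean MAPQ reported as 0")
    return(0)
  }
  mean(alignments$mapq[keep])
}
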