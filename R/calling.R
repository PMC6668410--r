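# Evidence-based indel calling from CIGAR operations. Every I/D operation in
# a non-duplicate mapped record yields a candidate keyed by
# (chrom, anchor position, ref allele, alt allele) in the VCF anchor-base
# convention: the anchor is the reference base immediately left of the event
# and is the first base of both alleles. A read spans a candidate if its
# aligned reference span covers the anchor through the first position after
# the event. Soft-clipped bases contribute to neither support nor span.

#' Collect indel evidence from alignments
#'
#' @param alignments sorted-or-not SAM-style data.frame; duplicate (0x400)
#'   and unmapped records are excluded.
#' @param reference named character vector of contigs.
#' @return data.frame with one row per candidate: `chrom`, `pos` (1-based
#'   anchor), `ref`, `alt`, `supporting`, `spanning`, `mean_support_baseq`.
#' @export
collect_evidence <- function(alignments, reference) {
  keep <- bitwAnd(alignments$flag, 4L) == 0L &
    bitwAnd(alignments$flag, 1024L) == 0L
  aln <- alignments[keep, , drop = FALSE]
  if (!nrow(aln))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      supporting = integer(0), spanning = integer(0),
                      mean_support_baseq = numeric(0),
                      stringsAsFactors = FALSE))
  ref_len <- cigar_ref_length(aln$cigar)
  ref_end <- aln$pos + ref_len - 1L
  contig_len <- nchar(reference)[match(aln$rname, names(reference))]
  over <- is.na(contig_len) | ref_end > contig_len
  if (any(over)) {
    warning(sum(over), " record(s) whose CIGAR runs past the reference end skipped")
    aln <- aln[!over, , drop = FALSE]
    ref_end <- ref_end[!over]
  }
  has_indel <- grepl("[ID]", aln$cigar)
  events <- list()
  for (i in which(has_indel)) {
    cg <- parse_cigar(aln$cigar[i])
    refpos <- aln$pos[i]          # next reference base to consume
    qpos <- 1L                    # next read base to consume
    chrom_seq <- reference[[aln$rname[i]]]
    q <- utf8ToInt(aln$qual[i]) - 33L
    for (k in seq_len(nrow(cg))) {
      op <- cg$op[k]; len <- cg$len[k]
      if (op %in% c("M", "=", "X")) {
        refpos <- refpos + len; qpos <- qpos + len
      } else if (op == "S") {
        qpos <- qpos + len
      } else if (op == "I") {
        anchor <- refpos - 1L
        if (anchor >= 1L) {
          anchor_base <- substr(chrom_seq, anchor, anchor)
          ins <- substr(aln$seq[i], qpos, qpos + len - 1L)
          events[[length(events) + 1L]] <- data.frame(
            chrom = aln$rname[i], pos = anchor,
            ref = anchor_base, alt = paste0(anchor_base, ins),
            baseq = mean(q[qpos:(qpos + len - 1L)]),
            stringsAsFactors = FALSE)
        }
        qpos <- qpos + len
      } else if (op %in% c("D", "N")) {
        if (op == "D") {
          anchor <- refpos - 1L
          if (anchor >= 1L) {
            flanks <- c(qpos - 1L, qpos)
            flanks <- flanks[flanks >= 1L & flanks <= length(q)]
            events[[length(events) + 1L]] <- data.frame(
              chrom = aln$rname[i], pos = anchor,
              ref = substr(chrom_seq, anchor, anchor + len),
              alt = substr(chrom_seq, anchor, anchor),
              baseq = if (length(flanks)) mean(q[flanks]) else 0,
              stringsAsFactors = FALSE)
          }
        }
        refpos <- refpos + len
      }
      # H and P consume neither read nor reference here
    }
  }
  if (!length(events))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      supporting = integer(0), spanning = integer(0),
                      mean_support_baseq = numeric(0),
                      stringsAsFactors = FALSE))
  ev <- do.call(rbind, events)
  key <- paste(ev$chrom, ev$pos, ev$ref, ev$alt, sep = "\r")
  agg_n <- tapply(rep(1L, nrow(ev)), key, sum)
  agg_q <- tapply(ev$baseq, key, mean)
  uk <- names(agg_n)
  first <- match(uk, key)
  out <- data.frame(chrom = ev$chrom[first], pos = ev$pos[first],
                    ref = ev$ref[first], alt = ev$alt[first],
                    supporting = as.integer(agg_n),
                    spanning = 0L,
                    mean_support_baseq = as.numeric(agg_q),
                    stringsAsFactors = FALSE)
  # spanning: reads whose aligned span covers [anchor, anchor + len(ref)]
  for (j in seq_len(nrow(out))) {
    same <- aln$rname == out$chrom[j]
    out$spanning[j] <- sum(same & aln$pos <= out$pos[j] &
                             ref_end >= out$pos[j] + nchar(out$ref[j]))
  }
  out$spanning <- pmax(out$spanning, out$supporting)
  ord <- order(out$chrom, out$pos, out$ref, out$alt)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call indels from collected evidence
#'
#' Every evidence record becomes a variant; FILTER is `PASS` iff the
#' support-count, support-fraction and base-quality thresholds are all met,
#' otherwise it names the first failed criterion, checked in the order
#' `noSpan`, `lowFrac`, `lowSupport`, `lowBaseQ`.
#'
#' @param evidence data.frame from [collect_evidence()].
#' @param min_support minimum number of supporting reads.
#' @param min_frac minimum supporting / spanning fraction. The default 0.3
#'   lies between a 25% supported event (not called) and a 50% supported
#'   event (called).
#' @param min_mean_baseq minimum mean base quality of the supporting bases.
#' @param sample_id optional sample label.
#' @return variant data.frame (`chrom`, `pos`, `ref`, `alt`, `filter`,
#'   `spanning`, `supporting`, `sample_id`).
#' @export
call_indels <- function(evidence, min_support = 2L, min_frac = 0.3,
                        min_mean_baseq = 20, sample_id = NA_character_) {
  n <- nrow(evidence)
  if (n == 0L) return(empty_variants())
  filter <- character(n)
  for (i in seq_len(n)) {
    s <- evidence$supporting[i]; sp <- evidence$spanning[i]
    filter[i] <-
      if (sp == 0L) "noSpan"
      else if (s / sp < min_frac) "lowFrac"
      else if (s < min_support) "lowSupport"
      else if (evidence$mean_support_baseq[i] < min_mean_baseq) "lowBaseQ"
      else "PASS"
  }
  data.frame(chrom = evidence$chrom, pos = evidence$pos, ref = evidence$ref,
             alt = evidence$alt, filter = filter,
             spanning = evidence$spanning, supporting = evidence$supporting,
             sample_id = sample_id, stringsAsFactors = FALSE)
}
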