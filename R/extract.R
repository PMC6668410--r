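# Extraction of "originally unmapped" reads from an alignment file.
# Only primary records are considered: secondary (0x100) and supplementary
# (0x800) records duplicate a primary and are never exported. Reads whose
# mate is unmapped but which are themselves mapped are not exported either —
# the pipeline targets reads that were themselves left unmapped and treats
# everything downstream as single-end.

#' Is an alignment record an unmapped primary record?
#'
#' @param flag integer vector of SAM flag bitfields.
#' @return logical: `TRUE` iff bit 0x4 is set and neither 0x100 nor 0x800 is.
#' @examples
#' is_unmapped(c(4L, 0L, 77L, 260L))
#' @export
is_unmapped <- function(flag) {
  bitwAnd(flag, 4L) != 0L &
    bitwAnd(flag, 256L) == 0L &
    bitwAnd(flag, 2048L) == 0L
}

#' Extract unmapped reads from an alignment set
#'
#' Unmapped primary records are exported as reads. If the record's
#' reverse-strand bit (0x10) is set, the stored sequence is
#' reverse-complemented and the quality string reversed, so the exported read
#' is in original sequencing orientation. Records storing no sequence (`*`)
#' are skipped with a warning and counted in the stats.
#'
#' @param alignments alignment data.frame as from [read_sam()].
#' @return list with `reads` (FASTQ-style data.frame) and `stats`
#'   (`total_primary`, `mapped`, `unmapped`, `skipped_no_seq`).
#' @export
extract_unmapped <- function(alignments) {
  primary <- bitwAnd(alignments$flag, 256L) == 0L &
    bitwAnd(alignments$flag, 2048L) == 0L
  prim <- alignments[primary, , drop = FALSE]
  unm <- is_unmapped(prim$flag)
  sel <- prim[unm, , drop = FALSE]
  no_seq <- sel$seq == "*" | is.na(sel$seq)
  if (any(no_seq))
    warning(sum(no_seq), " unmapped record(s) without stored sequence skipped")
  sel <- sel[!no_seq, , drop = FALSE]
  rev <- bitwAnd(sel$flag, 16L) != 0L
  seqs <- sel$seq
  quals <- sel$qual
  if (any(rev)) {
    seqs[rev] <- reverse_complement(seqs[rev])
    quals[rev] <- reverse_string(quals[rev])
  }
  reads <- data.frame(read_id = sel$qname, sequence = seqs, qual = quals,
                      stringsAsFactors = FALSE)
  stats <- list(total_primary = sum(primary),
                mapped = sum(primary) - sum(unm),
                unmapped = sum(unm),
                skipped_no_seq = sum(no_seq))
  list(reads = reads, stats = stats)
}
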