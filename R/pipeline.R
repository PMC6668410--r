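# End-to-end orchestration: extract unmapped reads, quality-control them,
# remap in two tiers, mark duplicates, call indels from CIGAR evidence,
# left-normalize and subtract the original call set, and keep the PASS
# calls — the novel high-quality (NHQ) indels.

#' Run the full indel-rescue pipeline
#'
#' @param original_sam path to a text SAM file, or a list as from
#'   [read_sam()].
#' @param reference path to a FASTA file, or a named character vector.
#' @param original_vcf path to a VCF, or a variant data.frame; the original
#'   call set to subtract.
#' @param qc a [qc_params()] object.
#' @param primary,secondary aligners for the two mapping tiers.
#' @param min_support,min_frac,min_mean_baseq calling thresholds passed to
#'   [call_indels()].
#' @param sample_id sample label attached to the calls.
#' @param verbose log per-stage counts with [message()].
#' @return list with `nhq` (normalized PASS novel indels), `novel` (all
#'   novel calls), `calls` (all calls from rescued reads), `summary`
#'   (an `indel_summary` of the NHQ set) and `report` (per-stage stats).
#' @export
run_pipeline <- function(original_sam, reference, original_vcf,
                         qc = qc_params(),
                         primary = aligner_builtin(),
                         secondary = aligner_builtin_sensitive(),
                         min_support = 2L, min_frac = 0.3,
                         min_mean_baseq = 20,
                         sample_id = NA_character_, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  if (is.character(original_sam)) original_sam <- read_sam(original_sam)
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference))
    reference <- read_fasta(reference)
  if (is.character(original_vcf)) original_vcf <- read_vcf(original_vcf)

  ext <- extract_unmapped(original_sam$alignments)
  say("extract: ", ext$stats$unmapped, " unmapped of ",
      ext$stats$total_primary, " primary records")

  qcres <- qc_stream(ext$reads, qc)
  say("qc: ", qcres$stats$reads_out, " of ", qcres$stats$reads_in,
      " reads retained (", round(100 * qcres$stats$retained_fraction, 2),
      "%)")

  mapres <- two_tier_map(qcres$reads, reference, primary, secondary)
  say("map: tier1 ", mapres$stats$tier1_mapped, ", tier2 ",
      mapres$stats$tier2_mapped, ", unmapped ",
      mapres$stats$still_unmapped, " (mapped fraction ",
      round(100 * mapres$stats$mapped_fraction, 2), "%)")

  dup <- mark_duplicates(mapres$alignments)
  say("duplicates: ", dup$n_duplicates, " marked")

  evidence <- collect_evidence(dup$alignments, reference)
  calls <- call_indels(evidence, min_support = min_support,
                       min_frac = min_frac,
                       min_mean_baseq = min_mean_baseq,
                       sample_id = sample_id)
  say("call: ", nrow(calls), " candidate indels, ",
      sum(calls$filter == "PASS"), " PASS")

  novel <- subtract_indels(calls, original_vcf, reference)
  nhq <- filter_pass(novel)
  say("novel: ", nrow(novel), " not in the original call set; NHQ: ",
      nrow(nhq))

  summary <- summarize_indels(nhq)
  report <- list(extraction = ext$stats, qc = qcres$stats,
                 mapping = mapres$stats,
                 duplicates = list(n_duplicates = dup$n_duplicates,
                                   mean_mapq = if (nrow(dup$alignments))
                                     mean_mapq(dup$alignments) else 0),
                 calls = list(n_candidates = nrow(calls),
                              n_pass = sum(calls$filter == "PASS")),
                 novelty = list(n_novel = nrow(novel), n_nhq = nrow(nhq)),
                 summary = unclass(summary))
  list(nhq = nhq, novel = novel, calls = calls, summary = summary,
       report = report)
}
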