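# Seeded synthetic-data generator. It emulates the input state the pipeline
# is built for: a reference, a haploid donor carrying planted indels, and a
# read set in which the reads overlapping a chosen subset of the planted
# indels are contaminated (adapter run-through plus a quality-collapsed
# tail) and therefore sit in the "original" alignment as unmapped records.
# Those indels are consequently absent from the original call set — hidden —
# and are exactly what the pipeline should rescue.

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the test suite:
#' a 100 kb reference, 100-base reads at 30x coverage, 10 planted indels of
#' lengths 1-20 with a deletion:insertion skew of 1.3:1, all of them hidden,
#' and error-free base calls. Contaminated reads keep a 64-base genomic
#' prefix followed by adapter sequence with Phred-2 qualities, so adapter
#' clipping and the quality trimmers both engage and the survivor still
#' clears the 36-base length floor.
#'
#' @param ref_length reference length in bases.
#' @param n_indels number of planted indels.
#' @param indel_min,indel_max planted indel length range.
#' @param geom_decay per-base decay of the indel length distribution
#'   (probability of length L proportional to `geom_decay^L`).
#' @param del_prob probability a planted indel is a deletion
#'   (default 1.3 / 2.3, the observed deletion:insertion skew).
#' @param read_length read length in bases.
#' @param coverage mean read coverage of the donor.
#' @param contamination_fraction minimum fraction of reads contaminated;
#'   reads overlapping hidden indels are always contaminated first.
#' @param hidden_frac fraction of planted indels hidden by contamination.
#' @param contaminated_prefix genomic prefix length kept in a contaminated
#'   read before the adapter tail starts.
#' @param base_error_rate per-base substitution error probability.
#' @param adapter adapter sequence appended to contaminated reads.
#' @param contig_name reference contig name.
#' @param sample_id sample label used in outputs.
#' @param seed integer seed; identical configs give identical outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(ref_length = 100000L, n_indels = 10L,
                       indel_min = 1L, indel_max = 20L, geom_decay = 0.75,
                       del_prob = 1.3 / 2.3, read_length = 100L,
                       coverage = 30, contamination_fraction = 0.1,
                       hidden_frac = 1, contaminated_prefix = 64L,
                       base_error_rate = 0,
                       adapter = NULL, contig_name = "sim_ref",
                       sample_id = "sample1", seed = 1L) {
  if (is.null(adapter)) adapter <- unname(truseq2_se_adapters()[1])
  stopifnot(contamination_fraction >= 0, contamination_fraction <= 1,
            hidden_frac >= 0, hidden_frac <= 1, coverage >= 0,
            indel_min >= 1L, indel_max >= indel_min)
  structure(list(ref_length = as.integer(ref_length),
                 n_indels = as.integer(n_indels),
                 indel_min = as.integer(indel_min),
                 indel_max = as.integer(indel_max),
                 geom_decay = geom_decay, del_prob = del_prob,
                 read_length = as.integer(read_length), coverage = coverage,
                 contamination_fraction = contamination_fraction,
                 hidden_frac = hidden_frac,
                 contaminated_prefix = as.integer(contaminated_prefix),
                 base_error_rate = base_error_rate, adapter = adapter,
                 contig_name = contig_name, sample_id = sample_id,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a uniform random reference sequence
#'
#' @param ref_length length in bases (at least 1000).
#' @param seed RNG seed.
#' @param contig_name contig name of the single reference sequence.
#' @return named character vector of length 1.
#' @export
simulate_reference <- function(ref_length, seed = 1L,
                               contig_name = "sim_ref") {
  if (ref_length < 1000L) stop("ref_length must be at least 1000")
  seq <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), ref_length,
                                      replace = TRUE), collapse = ""))
  stats::setNames(seq, contig_name)
}

#' Plant indels into a reference, producing a donor and a truth set
#'
#' Planted events are separated by at least twice the read length so read
#' loci stay independent. The returned truth table is left-normalized;
#' applying it to the reference reconstructs the donor.
#'
#' @param reference named character vector (single contig).
#' @param config a [sim_config()].
#' @return list with `donor` (character), `truth` (normalized variant
#'   data.frame) and `events` (raw events with donor coordinates:
#'   `donor_start`, `donor_end` bracket the event on the donor).
#' @export
plant_indels <- function(reference, config) {
  chrom <- names(reference)
  refseq <- reference[[1]]
  L <- nchar(refseq)
  rl <- config$read_length
  n <- config$n_indels
  sep <- 2L * rl
  lo <- sep
  hi <- L - sep
  if (n > 0L && (hi < lo || (hi - lo) < (n - 1L) * sep))
    stop("reference too short to separate ", n, " indels by ", sep, " bases")
  out <- with_seed(config$seed + 1L, {
    anchors <- integer(0)
    if (n > 0L) {
      for (try in 1:200) {
        anchors <- sort(sample(lo:hi, n))
        if (n == 1L || min(diff(anchors)) >= sep) break
        anchors <- integer(0)
      }
      if (!length(anchors)) stop("could not place indels with the required separation")
    }
    lens <- if (n > 0L)
      sample(config$indel_min:config$indel_max, n, replace = TRUE,
             prob = config$geom_decay^(config$indel_min:config$indel_max))
    else integer(0)
    is_del <- stats::runif(n) < config$del_prob
    ref_al <- character(n); alt_al <- character(n)
    for (i in seq_len(n)) {
      p <- anchors[i]
      if (is_del[i]) {
        ref_al[i] <- substr(refseq, p, p + lens[i])
        alt_al[i] <- substr(refseq, p, p)
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE),
                     collapse = "")
        ref_al[i] <- substr(refseq, p, p)
        alt_al[i] <- paste0(substr(refseq, p, p), ins)
      }
    }
    list(anchors = anchors, lens = lens, is_del = is_del,
         ref_al = ref_al, alt_al = alt_al)
  })
  # splice the donor and record donor coordinates of each event
  donor_parts <- character(0)
  donor_start <- integer(n); donor_end <- integer(n)
  cur <- 1L; shift <- 0L
  for (i in seq_len(n)) {
    p <- out$anchors[i]
    donor_parts <- c(donor_parts, substr(refseq, cur, p))
    d_anchor <- p + shift
    if (out$is_del[i]) {
      cur <- p + out$lens[i] + 1L
      shift <- shift - out$lens[i]
      donor_start[i] <- d_anchor; donor_end[i] <- d_anchor + 1L
    } else {
      ins <- substr(out$alt_al[i], 2L, nchar(out$alt_al[i]))
      donor_parts <- c(donor_parts, ins)
      cur <- p + 1L
      shift <- shift + out$lens[i]
      donor_start[i] <- d_anchor; donor_end[i] <- d_anchor + out$lens[i] + 1L
    }
  }
  donor_parts <- c(donor_parts, substr(refseq, cur, L))
  donor <- paste(donor_parts, collapse = "")
  events <- data.frame(chrom = rep(chrom, n), pos = out$anchors,
                       ref = out$ref_al, alt = out$alt_al,
                       donor_start = donor_start, donor_end = donor_end,
                       stringsAsFactors = FALSE)
  truth <- data.frame(chrom = events$chrom, pos = events$pos,
                      ref = events$ref, alt = events$alt,
                      filter = rep("PASS", n),
                      spanning = rep(NA_integer_, n),
                      supporting = rep(NA_integer_, n),
                      sample_id = rep(config$sample_id, n),
                      stringsAsFactors = FALSE)
  truth <- normalize_indels(truth, reference)
  list(donor = donor, truth = truth, events = events)
}

#' Apply a variant table to a reference (reconstruction check)
#'
#' Independent patch routine used to verify that the truth set reproduces
#' the donor.
#'
#' @param reference named character vector (single contig).
#' @param variants variant data.frame sorted by position, non-overlapping.
#' @return the patched sequence.
#' @export
apply_variants <- function(reference, variants) {
  refseq <- reference[[1]]
  v <- variants[order(variants$pos), , drop = FALSE]
  parts <- character(0)
  cur <- 1L
  for (i in seq_len(nrow(v))) {
    parts <- c(parts, substr(refseq, cur, v$pos[i] - 1L), v$alt[i])
    cur <- v$pos[i] + nchar(v$ref[i])
  }
  parts <- c(parts, substr(refseq, cur, nchar(refseq)))
  paste(parts, collapse = "")
}

#' Simulate reads, the original alignment and the original call set
#'
#' Uncontaminated reads are aligned to the reference with the built-in
#' aligner and appear as mapped records; contaminated reads appear as
#' unmapped (flag 4) records carrying their raw sequence (half of them
#' stored reverse-complemented with the 0x10 bit set, as alignment files in
#' the wild do). The original call set is called from the mapped records
#' only.
#'
#' @param donor donor sequence from [plant_indels()].
#' @param reference named character vector (single contig).
#' @param config a [sim_config()].
#' @param events the `events` table from [plant_indels()].
#' @return list with `reads` (all reads, FASTQ orientation), `sam`
#'   (header + alignments), `original_vcf`, `contaminated_ids`, `stats`.
#' @export
simulate_reads <- function(donor, reference, config, events) {
  rl <- config$read_length
  dl <- nchar(donor)
  n_reads <- max(1L, round(config$coverage * dl / rl))
  sim <- with_seed(config$seed + 2L, {
    starts <- sample.int(dl - rl + 1L, n_reads, replace = TRUE)
    seqs <- substring(donor, starts, starts + rl - 1L)
    if (config$base_error_rate > 0) {
      n_err <- stats::rbinom(n_reads, rl, config$base_error_rate)
      for (i in which(n_err > 0L)) {
        posn <- sample.int(rl, n_err[i])
        s <- strsplit(seqs[i], "")[[1]]
        for (p in posn) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
        seqs[i] <- paste(s, collapse = "")
      }
    }
    # choose hidden indels, contaminate every read overlapping one
    n_hidden <- round(config$hidden_frac * nrow(events))
    hidden_idx <- if (nrow(events)) sort(sample.int(nrow(events), n_hidden)) else integer(0)
    contaminated <- logical(n_reads)
    for (i in hidden_idx) {
      contaminated <- contaminated |
        (starts <= events$donor_end[i] & starts + rl - 1L >= events$donor_start[i])
    }
    n_target <- ceiling(config$contamination_fraction * n_reads)
    deficit <- n_target - sum(contaminated)
    if (deficit > 0L) {
      pool <- which(!contaminated)
      contaminated[sample(pool, min(deficit, length(pool)))] <- TRUE
    }
    store_rev <- contaminated & stats::runif(n_reads) < 0.5
    list(starts = starts, seqs = seqs, contaminated = contaminated,
         hidden_idx = hidden_idx, store_rev = store_rev)
  })
  ids <- sprintf("read%06d", seq_len(n_reads))
  quals <- strrep("I", rl)
  seqs <- sim$seqs
  qual_v <- rep(quals, n_reads)
  keep <- config$contaminated_prefix
  if (any(sim$contaminated)) {
    tail_len <- rl - keep
    ad <- strrep(config$adapter, ceiling(tail_len / nchar(config$adapter)))
    tail_seq <- substr(ad, 1L, tail_len)
    ci <- which(sim$contaminated)
    seqs[ci] <- paste0(substr(seqs[ci], 1L, keep), tail_seq)
    qual_v[ci] <- paste0(strrep("I", keep), strrep("#", tail_len))
  }
  reads <- data.frame(read_id = ids, sequence = seqs, qual = qual_v,
                      stringsAsFactors = FALSE)
  clean <- reads[!sim$contaminated, , drop = FALSE]
  aln <- align_reads(clean, reference, aligner_builtin())
  mapped <- aln$alignments
  # unmapped records: contaminated reads plus any clean read the aligner missed
  unmapped_ids <- c(reads$read_id[sim$contaminated], aln$unaligned)
  unm <- reads[match(unmapped_ids, reads$read_id), , drop = FALSE]
  rev_store <- sim$store_rev[match(unmapped_ids, reads$read_id)]
  useq <- unm$sequence; uqual <- unm$qual
  if (any(rev_store)) {
    useq[rev_store] <- reverse_complement(useq[rev_store])
    uqual[rev_store] <- reverse_string(uqual[rev_store])
  }
  nu <- nrow(unm)
  unmapped_rec <- data.frame(
    qname = unm$read_id, flag = ifelse(rev_store, 20L, 4L),
    rname = rep("*", nu), pos = rep(0L, nu), mapq = rep(0L, nu),
    cigar = rep("*", nu), rnext = rep("*", nu), pnext = rep(0L, nu),
    tlen = rep(0L, nu), seq = useq, qual = uqual, tags = rep("", nu),
    stringsAsFactors = FALSE)
  mapped$score <- NULL
  alignments <- rbind(mapped, unmapped_rec)
  ord <- order(match(alignments$qname, reads$read_id))
  alignments <- alignments[ord, , drop = FALSE]
  rownames(alignments) <- NULL
  evidence <- collect_evidence(mapped, reference)
  original_vcf <- call_indels(evidence, sample_id = config$sample_id)
  list(reads = reads,
       sam = list(header = sam_header(reference), alignments = alignments),
       original_vcf = original_vcf,
       contaminated_ids = reads$read_id[sim$contaminated],
       hidden_idx = sim$hidden_idx,
       stats = list(n_reads = n_reads, n_contaminated = sum(sim$contaminated),
                    n_mapped = nrow(mapped)))
}

#' Simulate a complete single-sample dataset
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, writes `ref.fa`,
#'   `reads.fastq`, `original.sam`, `original.vcf`, `truth.vcf` and
#'   `labels.tsv` there.
#' @return list with `reference`, `donor`, `truth`, `hidden_truth` (the
#'   hidden subset of the truth), `events`, `reads`, `sam`, `original_vcf`,
#'   `contaminated_ids`, `stats`.
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL) {
  reference <- simulate_reference(config$ref_length, config$seed,
                                  config$contig_name)
  planted <- plant_indels(reference, config)
  rd <- simulate_reads(planted$donor, reference, config, planted$events)
  hidden_truth <- planted$truth[rd$hidden_idx, , drop = FALSE]
  out <- list(reference = reference, donor = planted$donor,
              truth = planted$truth, hidden_truth = hidden_truth,
              events = planted$events, reads = rd$reads, sam = rd$sam,
              original_vcf = rd$original_vcf,
              contaminated_ids = rd$contaminated_ids, stats = rd$stats)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(reference, file.path(outdir, "ref.fa"))
    write_fastq(rd$reads, file.path(outdir, "reads.fastq"))
    write_sam(rd$sam, file.path(outdir, "original.sam"))
    write_vcf(rd$original_vcf, file.path(outdir, "original.vcf"), reference)
    write_vcf(planted$truth, file.path(outdir, "truth.vcf"), reference)
    write_subtype_labels(
      data.frame(sample_id = config$sample_id, subtype = "Basal"),
      file.path(outdir, "labels.tsv"))
  }
  out
}
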