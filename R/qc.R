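# Trimmomatic-style single-end quality control: adapter clipping, LEADING /
# TRAILING end trimming, sliding-window quality cutting and a minimum-length
# drop, applied in that order. 'N' bases count as quality 0 in every
# threshold comparison. All trimming yields a contiguous prefix/suffix of the
# input read, never a rearrangement.

#' TruSeq2 single-end adapter sequences
#'
#' The adapter set bundled for single-end trimming, mirroring the
#' Trimmomatic distribution file of the same name.
#'
#' @return named character vector of adapter sequences.
#' @export
truseq2_se_adapters <- function() {
  path <- system.file("extdata", "truseq2-se.fa", package = "indelrescue")
  read_fasta(path)
}

#' Quality-control parameters
#'
#' Defaults follow the Trimmomatic invocation
#' `LEADING:3 TRAILING:3 SLIDINGWINDOW:4:15 MINLEN:36` with TruSeq2
#' single-end adapters.
#'
#' @param adapters character vector of adapter sequences.
#' @param leading_q,trailing_q Phred threshold below which leading/trailing
#'   bases (and `N`s) are removed.
#' @param window,window_q sliding-window width and mean-quality threshold.
#' @param min_len reads shorter than this after trimming are dropped.
#' @param min_adapter_overlap minimum read/adapter overlap for a clip.
#' @param max_adapter_mismatch_frac maximum mismatch fraction in the overlap.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(adapters = truseq2_se_adapters(),
                      leading_q = 3L, trailing_q = 3L,
                      window = 4L, window_q = 15L, min_len = 36L,
                      min_adapter_overlap = 8L,
                      max_adapter_mismatch_frac = 0.1) {
  stopifnot(length(adapters) >= 1L, window >= 1L,
            leading_q >= 0L, trailing_q >= 0L, window_q >= 0L, min_len >= 0L)
  structure(list(adapters = toupper(unname(adapters)), leading_q = leading_q,
                 trailing_q = trailing_q, window = window, window_q = window_q,
                 min_len = min_len, min_adapter_overlap = min_adapter_overlap,
                 max_adapter_mismatch_frac = max_adapter_mismatch_frac),
            class = "qc_params")
}

# effective qualities: N bases count as 0
effective_quals <- function(sequence, qual) {
  q <- phred_decode(qual)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  q[bases == "N"] <- 0L
  q
}

take_prefix <- function(read, n) {
  read$sequence <- substr(read$sequence, 1L, n)
  read$qual <- substr(read$qual, 1L, n)
  read
}

#' Clip adapter sequence from the 3' side of a read
#'
#' The read is truncated at the start of the best adapter match (lowest
#' mismatch fraction, then longest overlap, then leftmost). A match requires
#' an overlap of at least `min_adapter_overlap` bases — at the 3' end the
#' overlap is whatever read length remains — with a mismatch fraction at most
#' `max_adapter_mismatch_frac`.
#'
#' @param read single-row read data.frame (`read_id`, `sequence`, `qual`).
#' @param params a [qc_params()] object.
#' @return the (possibly truncated) read.
#' @export
clip_adapter <- function(read, params) {
  n <- nchar(read$sequence)
  if (n == 0L) return(read)
  rb <- utf8ToInt(read$sequence)
  best_start <- NA_integer_
  best_frac <- Inf
  best_ov <- 0L
  for (ad in params$adapters) {
    ab <- utf8ToInt(ad)
    la <- length(ab)
    max_start <- n - params$min_adapter_overlap + 1L
    if (max_start < 1L) next
    for (i in seq_len(max_start)) {          # i = 1-based clip point
      ov <- min(n - i + 1L, la)
      mm <- sum(rb[i:(i + ov - 1L)] != ab[1:ov])
      if (mm / ov <= params$max_adapter_mismatch_frac) {
        frac <- mm / ov
        if (frac < best_frac || (frac == best_frac && ov > best_ov)) {
          best_frac <- frac; best_ov <- ov; best_start <- i
        }
      }
    }
  }
  if (is.na(best_start)) return(read)
  take_prefix(read, best_start - 1L)
}

#' Trim low-quality or N bases from both read ends
#'
#' @param read single-row read data.frame.
#' @param leading_q,trailing_q Phred thresholds.
#' @return the trimmed read.
#' @export
trim_ends <- function(read, leading_q = 3L, trailing_q = 3L) {
  n <- nchar(read$sequence)
  if (n == 0L) return(read)
  q <- effective_quals(read$sequence, read$qual)
  keep <- which(q >= leading_q)
  first <- if (length(keep)) keep[1] else n + 1L
  if (first > n) return(take_prefix(read, 0L))
  keep2 <- which(q >= trailing_q)
  last <- keep2[length(keep2)]
  if (last < first) return(take_prefix(read, 0L))
  read$sequence <- substr(read$sequence, first, last)
  read$qual <- substr(read$qual, first, last)
  read
}

#' Sliding-window quality trim
#'
#' The read is truncated at the first base of the first window (width
#' `window`, or the shorter tail window) whose mean quality falls below
#' `window_q`.
#'
#' @param read single-row read data.frame.
#' @param window window width in bases.
#' @param window_q mean-quality threshold.
#' @return the trimmed read.
#' @export
sliding_window_trim <- function(read, window = 4L, window_q = 15L) {
  n <- nchar(read$sequence)
  if (n == 0L) return(read)
  q <- effective_quals(read$sequence, read$qual)
  cs <- c(0, cumsum(q))
  ends <- pmin(seq_len(n) + window - 1L, n)
  means <- (cs[ends + 1L] - cs[seq_len(n)]) / (ends - seq_len(n) + 1L)
  fail <- which(means < window_q)
  if (!length(fail)) return(read)
  take_prefix(read, fail[1] - 1L)
}

#' Quality-control one read
#'
#' Applies adapter clipping, leading/trailing trimming, sliding-window
#' cutting and the minimum-length filter, in that order.
#'
#' @param read single-row read data.frame.
#' @param params a [qc_params()] object.
#' @return the surviving read, or `NULL` if dropped by the length filter.
#' @export
qc_read <- function(read, params = qc_params()) {
  r <- clip_adapter(read, params)
  r <- trim_ends(r, params$leading_q, params$trailing_q)
  r <- sliding_window_trim(r, params$window, params$window_q)
  if (nchar(r$sequence) < params$min_len) return(NULL)
  r
}

#' Quality-control a stream of reads
#'
#' @param reads FASTQ-style data.frame.
#' @param params a [qc_params()] object.
#' @return list with `reads` (survivors) and `stats`
#'   (`reads_in`, `reads_out`, `retained_fraction`, `bases_trimmed`; trimmed
#'   bases include the full length of dropped reads).
#' @export
qc_stream <- function(reads, params = qc_params()) {
  n_in <- nrow(reads)
  out <- vector("list", n_in)
  for (i in seq_len(n_in)) out[[i]] <- qc_read(reads[i, , drop = FALSE], params)
  kept <- !vapply(out, is.null, logical(1))
  surv <- if (any(kept)) do.call(rbind, out[kept]) else
    data.frame(read_id = character(0), sequence = character(0),
               qual = character(0), stringsAsFactors = FALSE)
  rownames(surv) <- NULL
  stats <- list(
    reads_in = n_in,
    reads_out = nrow(surv),
    retained_fraction = if (n_in == 0L) 0 else nrow(surv) / n_in,
    bases_trimmed = sum(nchar(reads$sequence)) - sum(nchar(surv$sequence)))
  list(reads = surv, stats = stats)
}
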