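# Internal helpers shared across modules. All genomic coordinates in this
# package follow the convention of the format they came from: SAM/VCF are
# 1-based inclusive, BED is 0-based half-open. Helpers that mix the two say so.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decode a Phred+33 quality string to integer qualities
#'
#' @param qual character vector of quality strings (one per read).
#' @return For length-1 input, an integer vector; otherwise a list of integer
#'   vectors. Values are on the Phred scale (0-93).
#' @examples
#' phred_decode("!I") # 0 40
#' @export
phred_decode <- function(qual) {
  dec <- lapply(qual, function(q) {
    v <- utf8ToInt(q) - 33L
    if (length(v) && (min(v) < 0L || max(v) > 93L))
      stop("quality characters outside the Phred+33 range [0, 93]")
    v
  })
  if (length(dec) == 1L) dec[[1L]] else dec
}

#' Encode integer Phred qualities as a Phred+33 string
#'
#' @param q integer vector of qualities in [0, 93].
#' @return a single quality string.
#' @export
phred_encode <- function(q) {
  if (any(q < 0L | q > 93L)) stop("Phred qualities must lie in [0, 93]")
  intToUtf8(as.integer(q) + 33L)
}

# vectorized reverse complement of plain character DNA (ACGTN, case kept upper)
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# vectorized string reversal (used for quality strings of minus-strand reads)
reverse_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# open a text connection that transparently handles gzip input
open_text <- function(path) {
  con <- gzfile(path, open = "rt")
  con
}

# run-length CIGAR string -> data.frame(len, op); "*" -> zero rows
#' Parse a CIGAR string
#'
#' @param cigar a single CIGAR string; `"*"` yields zero operations.
#' @return data.frame with columns `len` (integer) and `op` (character).
#' @examples
#' parse_cigar("20M5D16M")
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*")
    return(data.frame(len = integer(0), op = character(0),
                      stringsAsFactors = FALSE))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) || !length(ops))
    stop("malformed CIGAR string: ", cigar)
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

# number of query bases consumed by a CIGAR (ops M, I, S, =, X)
cigar_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# number of reference bases consumed by a CIGAR (ops M, D, N, =, X)
cigar_ref_length <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# evaluate an expression under a seeded, restored RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
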