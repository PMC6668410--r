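# Gene-interval overlap of indels and the cancer-gene enrichment tests:
# a one-sided two-proportion z-test (unpooled standard error), a
# Yates-corrected chi-square on the 2x2 table, and a resampling test with
# the exact hypergeometric tail as its analytic oracle.

#' Overlap indels with gene intervals
#'
#' An indel's affected reference span is `[pos, pos + nchar(ref) - 1]` in
#' 1-based coordinates; a gene (0-based half-open) overlaps iff the two
#' intervals intersect at all (any-overlap rule).
#'
#' @param indels variant data.frame.
#' @param intervals gene-interval data.frame from [read_bed()].
#' @return list with `overlapped_genes` (character vector of gene names hit
#'   by at least one indel), `per_gene_counts` (named integer, hit genes
#'   only) and `n_overlapped`.
#' @export
overlap_genes <- function(indels, intervals) {
  if (!nrow(indels) || !nrow(intervals)) {
    return(list(overlapped_genes = character(0),
                per_gene_counts = integer(0), n_overlapped = 0L))
  }
  span_start <- indels$pos
  span_end <- indels$pos + nchar(indels$ref) - 1L
  counts <- integer(nrow(intervals))
  for (g in seq_len(nrow(intervals))) {
    # the anchored span is compared directly against the half-open interval:
    # a span starting at the interval's exclusive end does not overlap
    counts[g] <- sum(indels$chrom == intervals$chrom[g] &
                       span_start < intervals$end[g] &
                       span_end >= intervals$start[g])
  }
  hit <- counts > 0L
  list(overlapped_genes = intervals$name[hit],
       per_gene_counts = stats::setNames(counts[hit], intervals$name[hit]),
       n_overlapped = sum(hit))
}

#' One-sided two-proportion z-test (unpooled standard error)
#'
#' Tests H1: p1 > p2 with
#' z = (p1 - p2) / sqrt(p1(1-p1)/n1 + p2(1-p2)/n2). The unpooled form is
#' deliberate: it is the variant whose value is reported alongside the
#' Yates chi-square in the worked cancer-gene example.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with `statistic` (z), `p_value` (upper tail), `sidedness`,
#'   `method`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 < 1L || n2 < 1L) stop("both sample sizes must be at least 1")
  stopifnot(x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  z <- (p1 - p2) / se
  list(statistic = z, p_value = stats::pnorm(z, lower.tail = FALSE),
       sidedness = "one-sided", method = "two-proportion z (unpooled SE)")
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' chi^2 = sum over cells of (max(|O - E| - 0.5, 0))^2 / E, compared to a
#' chi-square distribution with 1 degree of freedom (two-sided).
#'
#' @param a,b first row (e.g. category 1 overlapped / not overlapped).
#' @param c,d second row.
#' @return list with `statistic`, `p_value`, `sidedness`, `method`.
#' @export
yates_chisq <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("2x2 table with a zero marginal")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       sidedness = "two-sided", method = "Pearson chi-square with Yates correction")
}

#' Resampling enrichment test with hypergeometric oracle
#'
#' Each replicate draws `draw_size` genes without replacement from a universe
#' of `universe_size` genes of which `n_marked` are marked (overlapping).
#' The p-value is the fraction of replicates whose marked count reaches the
#' observed overlap under the chosen rule. The exact hypergeometric tail is
#' returned alongside as an analytic oracle.
#'
#' @param universe_size number of genes in the background universe.
#' @param n_marked marked (overlapping) genes in the universe.
#' @param draw_size genes drawn per replicate.
#' @param observed observed overlap count being tested.
#' @param reps number of replicates (default 1000).
#' @param seed optional RNG seed for reproducible draws.
#' @param rule `"at_least"` counts replicates with marked count >= observed
#'   (default); `"greater"` uses strict >.
#' @return list with `p_value`, `p_exact` (hypergeometric tail under the
#'   same rule), `null_distribution` (integer vector of length `reps`),
#'   `observed`, `rule`, `method`.
#' @export
permutation_enrichment <- function(universe_size, n_marked, draw_size,
                                   observed, reps = 1000L, seed = NULL,
                                   rule = c("at_least", "greater")) {
  rule <- match.arg(rule)
  if (reps < 1L) stop("reps must be at least 1")
  if (draw_size > universe_size || n_marked > universe_size)
    stop("draw_size and n_marked must not exceed universe_size")
  draws <- integer(reps)
  run <- function() {
    for (r in seq_len(reps))
      draws[r] <<- sum(sample.int(universe_size, draw_size) <= n_marked)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
  hits <- if (rule == "at_least") sum(draws >= observed) else
    sum(draws > observed)
  cut <- if (rule == "at_least") observed - 1L else observed
  p_exact <- stats::phyper(cut, n_marked, universe_size - n_marked,
                           draw_size, lower.tail = FALSE)
  list(p_value = hits / reps, p_exact = p_exact,
       null_distribution = draws, observed = observed, rule = rule,
       method = "resampling enrichment (without replacement)")
}
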