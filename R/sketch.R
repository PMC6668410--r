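# Bottom-s MinHash sketching of read sets and Mash-style distances.
# A sketch holds the s smallest distinct 64-bit hash values over all
# canonical k-mers (lexicographic minimum of a k-mer and its reverse
# complement; k-mers containing N are skipped). The Jaccard index of two
# sketches is estimated on the merged bottom-s sketch of their union, and
# converted to a mutation-distance proxy d = -(1/k) * ln(2j / (1 + j)).

#' Build a bottom-s MinHash sketch of a read set
#'
#' @param sequences character vector of read sequences (or a FASTQ-style
#'   data.frame with a `sequence` column).
#' @param sample_id sample label stored in the sketch.
#' @param k k-mer length (default 21).
#' @param s sketch capacity: number of smallest hashes kept (default 1000).
#' @param hash_seed seed of the 64-bit k-mer hash; sketches are only
#'   comparable at equal `k`, `s` and seed.
#' @return list of class `minhash_sketch` with fields `sample_id`, `k`, `s`,
#'   `hash_seed`, `hashes` (strictly increasing numeric vector).
#' @export
build_sketch <- function(sequences, sample_id = "sample", k = 21L, s = 1000L,
                         hash_seed = 42L) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  if (!length(sequences)) stop("no reads to sketch")
  h <- cpp_canonical_kmer_hashes(toupper(sequences), as.integer(k),
                                 as.numeric(hash_seed))
  if (!length(h)) stop("no valid k-mer of length ", k, " in the read set")
  structure(list(sample_id = sample_id, k = as.integer(k), s = as.integer(s),
                 hash_seed = as.numeric(hash_seed),
                 hashes = head(h, s)),
            class = "minhash_sketch")
}

check_compatible <- function(a, b) {
  if (a$k != b$k || a$s != b$s || a$hash_seed != b$hash_seed)
    stop("sketches are not comparable: k/s/hash_seed differ")
}

#' Mash distance between two sketches
#'
#' The Jaccard index j is estimated as the shared fraction of the s smallest
#' hashes of the merged sketch union; d = 0 when j = 1, d = 1 when j = 0,
#' otherwise d = -(1/k) * ln(2j / (1 + j)).
#'
#' @param a,b `minhash_sketch` objects with equal `k`, `s` and seed.
#' @return distance in [0, 1].
#' @export
mash_distance <- function(a, b) {
  check_compatible(a, b)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  x <- head(merged, min(a$s, length(merged)))
  j <- sum(x %in% a$hashes & x %in% b$hashes) / length(x)
  if (j <= 0) return(1)
  if (j >= 1) return(0)
  min(1, -(1 / a$k) * log(2 * j / (1 + j)))
}

#' Pairwise Mash distance matrix
#'
#' @param sketches list of mutually compatible `minhash_sketch` objects.
#' @return symmetric matrix with zero diagonal, dimnames = sample ids.
#' @export
distance_matrix <- function(sketches) {
  n <- length(sketches)
  if (n < 2L) stop("need at least two sketches")
  ids <- vapply(sketches, `[[`, "", "sample_id")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      m[i, j] <- m[j, i] <- mash_distance(sketches[[i]], sketches[[j]])
  m
}

#' Agglomerative clustering of a distance matrix
#'
#' @param m symmetric distance matrix.
#' @param linkage linkage method passed to [stats::hclust()]
#'   (default `"average"`).
#' @param n_clusters number of clusters obtained by cutting the tree.
#' @return list with `labels` (named integer cluster labels), `merge`
#'   (the dendrogram merge matrix) and the `hclust` object.
#' @export
hierarchical_cluster <- function(m, linkage = "average", n_clusters = 2L) {
  if (n_clusters > nrow(m))
    stop("n_clusters exceeds the number of samples")
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  labels <- stats::cutree(hc, k = n_clusters)
  list(labels = labels, merge = hc$merge, hclust = hc)
}

#' Confusion matrix of binary cluster labels against truth
#'
#' Cluster identities are matched to the true labels by maximal agreement
#' (so an inverted labelling still scores perfectly).
#'
#' @param cluster_labels vector with two distinct values.
#' @param true_labels vector with two distinct values, same length.
#' @return list with `table` (2x2 counts, rows = true labels) and
#'   `concordance` (agreeing samples / total).
#' @export
confusion_matrix <- function(cluster_labels, true_labels) {
  stopifnot(length(cluster_labels) == length(true_labels))
  tab <- table(true = true_labels, cluster = cluster_labels)
  if (nrow(tab) > 2L || ncol(tab) > 2L)
    stop("confusion_matrix is defined for binary labels")
  agree <- sum(diag(as.matrix(tab)))
  if (ncol(tab) == 2L) {
    flipped <- sum(diag(as.matrix(tab)[, 2:1, drop = FALSE]))
    if (flipped > agree) {
      tab <- tab[, 2:1, drop = FALSE]
      agree <- flipped
    }
  }
  list(table = tab, concordance = agree / length(true_labels))
}

#' Serialize a sketch to JSON
#'
#' @param sketch a `minhash_sketch`.
#' @param path output file.
#' @export
write_sketch <- function(sketch, path) {
  jsonlite::write_json(unclass(sketch), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sketch from JSON
#'
#' @param path file written by [write_sketch()].
#' @return a `minhash_sketch`.
#' @export
read_sketch <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sample_id = x$sample_id, k = as.integer(x$k),
                 s = as.integer(x$s), hash_seed = as.numeric(x$hash_seed),
                 hashes = as.numeric(x$hashes)),
            class = "minhash_sketch")
}
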