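# MinHash sketches, Mash distances, clustering and the confusion matrix.

test_that("sketches are deterministic and capped at s distinct hashes", {
  set.seed(61)
  reads <- replicate(20, random_dna(50))
  a <- build_sketch(reads, "s1", k = 21, s = 100, hash_seed = 7)
  b <- build_sketch(reads, "s1", k = 21, s = 100, hash_seed = 7)
  expect_identical(a$hashes, b$hashes)
  expect_true(all(diff(a$hashes) > 0))  # strictly increasing
  expect_lte(length(a$hashes), 100L)
  # fewer distinct canonical k-mers than s: sketch holds all of them
  one <- build_sketch("ACGTACGTAC", "s2", k = 4, s = 1000, hash_seed = 7)
  kmers <- substring("ACGTACGTAC", 1:7, 4:10)
  rc <- vapply(kmers, function(x)
    paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = ""),
    "")
  expect_equal(length(one$hashes), length(unique(pmin(kmers, rc))))
  expect_error(build_sketch("ACG", k = 21), "k-mer")
})

test_that("a k-mer and its reverse complement hash identically", {
  km <- "ACGTTGCAACGTTGCAACGTT"
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(km, "")[[1]])), collapse = "")
  a <- build_sketch(km, k = 21, s = 10, hash_seed = 3)
  b <- build_sketch(rc, k = 21, s = 10, hash_seed = 3)
  expect_identical(a$hashes, b$hashes)
  # k-mers containing N are skipped entirely
  expect_error(build_sketch("ACGTNACGTNACGTNACGTNA", k = 21, s = 10),
               "k-mer")
})

test_that("mash distance has the closed-form value and metric properties", {
  set.seed(62)
  reads <- replicate(30, random_dna(60))
  a <- build_sketch(reads, "a", k = 21, s = 200, hash_seed = 1)
  expect_equal(mash_distance(a, a), 0)
  other <- build_sketch(replicate(30, random_dna(60)), "b", k = 21, s = 200,
                        hash_seed = 1)
  d <- mash_distance(a, other)
  expect_equal(d, mash_distance(other, a))
  expect_gte(d, 0)
  # disjoint random read sets at this size share essentially no 21-mers
  expect_equal(d, 1)
  # closed form at j = 0.5, k = 21
  expect_equal(-(1 / 21) * log(2 * 0.5 / (1 + 0.5)), 0.019308,
               tolerance = 1e-4)
  incompatible <- build_sketch(reads, "c", k = 15, s = 200, hash_seed = 1)
  expect_error(mash_distance(a, incompatible), "not comparable")
})

test_that("the merged-sketch Jaccard estimate converges to the truth", {
  set.seed(63)
  # two k-mer pools with known overlap; reads are the k-mers themselves
  pool <- unique(replicate(6000, random_dna(21)))[1:5000]
  A <- pool[1:3000]
  B <- pool[1001:4000]  # true intersection 2000, union 4000
  # canonical dedup: none of these random 21-mers collide with an rc twin
  sa <- build_sketch(A, "A", k = 21, s = 4096, hash_seed = 5)
  sb <- build_sketch(B, "B", k = 21, s = 4096, hash_seed = 5)
  merged <- sort(unique(c(sa$hashes, sb$hashes)))
  x <- head(merged, 4096)
  j_hat <- sum(x %in% sa$hashes & x %in% sb$hashes) / length(x)
  J <- 2000 / 4000
  expect_lt(abs(j_hat - J), 3 * sqrt(J * (1 - J) / 4096))
})

test_that("distance matrices are symmetric with zero diagonal", {
  set.seed(64)
  reads <- replicate(30, random_dna(60))
  s1 <- build_sketch(reads, "s1")
  s2 <- build_sketch(reads, "s2")
  s3 <- build_sketch(replicate(30, random_dna(60)), "s3")
  m <- distance_matrix(list(s1, s2, s3))
  expect_equal(m, t(m))
  expect_equal(diag(m), c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(m["s1", "s2"], 0)   # identical read sets
  expect_equal(m["s1", "s3"], 1)   # disjoint k-mer content
  expect_error(distance_matrix(list(s1)), "two sketches")
})

test_that("clustering recovers two synthetic read populations exactly", {
  pops <- two_population_reads()
  sketches <- lapply(names(pops), function(id)
    build_sketch(pops[[id]], id, k = 21, s = 500, hash_seed = 9))
  m <- distance_matrix(sketches)
  cl <- hierarchical_cluster(m, n_clusters = 2)
  truth <- sub("_s[0-9]+$", "", rownames(m))
  cm <- confusion_matrix(cl$labels, truth)
  expect_equal(cm$concordance, 1.0)
  expect_error(hierarchical_cluster(m, n_clusters = 10), "exceeds")
  # single pair cuts into two singletons
  m2 <- m[1:2, 1:2]
  expect_equal(sort(unname(hierarchical_cluster(m2, n_clusters = 2)$labels)),
               c(1L, 2L))
})

test_that("confusion matrix matches clusters to labels by best agreement", {
  truth <- rep(c("Basal", "LumA"), c(16, 14))
  perfect <- rep(c(1L, 2L), c(16, 14))
  expect_equal(confusion_matrix(perfect, truth)$concordance, 1.0)
  # inverted cluster ids still score perfectly
  expect_equal(confusion_matrix(3L - perfect, truth)$concordance, 1.0)
  # three Basal samples assigned to the LumA cluster: 27 of 30 concordant
  three_off <- perfect
  three_off[12:14] <- 2L
  expect_equal(confusion_matrix(three_off, truth)$concordance, 0.9)
})

test_that("sketch JSON serialization round-trips exactly", {
  set.seed(65)
  s <- build_sketch(replicate(10, random_dna(40)), "sX", k = 21, s = 64,
                    hash_seed = 13)
  f <- tempfile(fileext = ".json")
  write_sketch(s, f)
  back <- read_sketch(f)
  expect_equal(back, s)
})
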