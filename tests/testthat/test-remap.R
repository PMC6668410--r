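# Built-in aligner against an independent full-matrix DP oracle, two-tier
# mapping, duplicate marking and mean MAPQ.

test_that("exact substrings align at the right position with a full-M CIGAR", {
  set.seed(41)
  ref <- c(chrA = random_dna(1000))
  read <- substr(ref[[1]], 101, 136)  # 0-based offset 100
  res <- align_reads(make_read(read), ref)
  expect_equal(res$alignments$pos, 101L)
  expect_equal(res$alignments$cigar, "36M")
  expect_equal(res$alignments$rname, "chrA")
})

test_that("deletion reads get gapped CIGARs scoring like the DP oracle", {
  set.seed(42)
  ref <- c(chrA = random_dna(200))
  # read = ref[50:70) + ref[75:91) in 0-based slices: a 5-base deletion
  read <- paste0(substr(ref[[1]], 51, 70), substr(ref[[1]], 76, 91))
  res <- align_reads(make_read(read), ref)
  aln <- res$alignments
  expect_equal(nrow(aln), 1L)
  oracle <- fit_align_oracle_score(read, ref[[1]])
  expect_equal(aln$score, oracle)
  cg <- parse_cigar(aln$cigar)
  expect_equal(sum(cg$len[cg$op == "D"]), 5L)
  # left-normalized, the called event is the planted deletion irrespective
  # of where inside a repeat the DP placed the gap
  ev <- collect_evidence(aln, ref)
  nm <- left_normalize(ev$chrom, ev$pos, ev$ref, ev$alt, ref)
  planted <- left_normalize("chrA", 70L, substr(ref[[1]], 70, 75),
                            substr(ref[[1]], 70, 70), ref)
  expect_equal(nm, planted)
})

test_that("aligner score equals the unbanded DP oracle on random indel reads", {
  set.seed(43)
  ref <- c(chrA = random_dna(800))
  for (i in 1:10) {
    start <- sample(1:700, 1)
    read <- substr(ref[[1]], start, start + 79)
    kind <- sample(c("ins", "del", "sub"), 1)
    if (kind == "ins") {
      at <- sample(20:60, 1)
      read <- paste0(substr(read, 1, at), random_dna(sample(1:10, 1)),
                     substr(read, at + 1, 80))
    } else if (kind == "del") {
      at <- sample(20:60, 1)
      read <- paste0(substr(read, 1, at),
                     substr(read, at + sample(1:10, 1) + 1, 80))
    } else {
      at <- sample(1:80, 1)
      substr(read, at, at) <- sample(c("A", "C", "G", "T"), 1)
    }
    res <- align_reads(make_read(read), ref)
    expect_equal(res$alignments$score, fit_align_oracle_score(read, ref[[1]]),
                 info = paste("case", i, kind))
  }
})

test_that("reads absent from the reference do not align", {
  set.seed(44)
  ref <- c(chrA = random_dna(2000))
  repeat {  # verify absence by substring search before trusting the aligner
    rd <- random_dna(36)
    if (!grepl(rd, ref[[1]], fixed = TRUE)) break
  }
  res <- align_reads(make_read(rd), ref)
  expect_equal(nrow(res$alignments), 0L)
  expect_equal(res$unaligned, "r1")
  # shorter than the seed: unalignable
  res2 <- align_reads(make_read(substr(ref[[1]], 1, 10)), ref)
  expect_equal(nrow(res2$alignments), 0L)
})

test_that("two-tier mapping partitions reads and reports the mapped fraction", {
  set.seed(45)
  ref <- c(chrA = random_dna(3000))
  alignable <- do.call(rbind, lapply(1:65, function(i) {
    s <- sample(1:2900, 1)
    make_read(substr(ref[[1]], s, s + 59), read_id = paste0("a", i))
  }))
  junk <- do.call(rbind, lapply(1:35, function(i)
    make_read(random_dna(60), read_id = paste0("j", i))))
  reads <- rbind(alignable, junk)
  res <- two_tier_map(reads, ref)
  st <- res$stats
  expect_equal(st$tier1_mapped + st$tier2_mapped + st$still_unmapped,
               st$total)
  expect_equal(st$mapped_fraction, 0.65)
  expect_equal(nrow(res$alignments), 65L)
  # a primary tier that fails everything routes all reads to tier two
  res2 <- two_tier_map(alignable, ref,
                       primary = aligner_builtin(min_score_frac = 2),
                       secondary = aligner_builtin())
  expect_equal(res2$stats$tier1_mapped, 0L)
  expect_equal(res2$stats$tier2_mapped, 65L)
  # a fully capable tier one leaves nothing for tier two
  res3 <- two_tier_map(alignable, ref)
  expect_equal(res3$stats$tier2_mapped, 0L)
})

test_that("duplicate marking keeps the highest-quality record per placement", {
  a <- make_aln("readA", 0L, pos = 100L, cigar = "35M",
                seq = strrep("A", 35), qual = strrep("I", 35))  # sum 1400
  b <- make_aln("readB", 0L, pos = 100L, cigar = "35M",
                seq = strrep("A", 35), qual = strrep("C", 35))  # sum 1190
  res <- mark_duplicates(rbind(a, b))
  expect_equal(res$n_duplicates, 1L)
  marked <- bitwAnd(res$alignments$flag, 1024L) != 0L
  expect_equal(res$alignments$qname[marked], "readB")
  # all distinct positions: nothing marked
  c2 <- make_aln("readC", 0L, pos = 200L, cigar = "35M", seq = strrep("A", 35))
  expect_equal(mark_duplicates(rbind(a, c2))$n_duplicates, 0L)
  # three identical placements: exactly two marked, one survivor
  res3 <- mark_duplicates(rbind(a, b, make_aln("readD", 0L, pos = 100L,
                                               cigar = "35M",
                                               seq = strrep("A", 35))))
  expect_equal(res3$n_duplicates, 2L)
  expect_equal(sum(bitwAnd(res3$alignments$flag, 1024L) == 0L), 1L)
})

test_that("duplicate grouping uses the unclipped 5' position and strand", {
  # leading soft clip shifts the unclipped start back to 100
  a <- make_aln("readA", 0L, pos = 105L, cigar = "5S30M", seq = strrep("A", 35))
  b <- make_aln("readB", 0L, pos = 100L, cigar = "35M", seq = strrep("A", 35))
  expect_equal(mark_duplicates(rbind(a, b))$n_duplicates, 1L)
  # same coordinates on opposite strands are not duplicates
  c2 <- make_aln("readC", 16L, pos = 100L, cigar = "35M", seq = strrep("A", 35))
  expect_equal(mark_duplicates(rbind(b, c2))$n_duplicates, 0L)
})

test_that("mean_mapq averages non-duplicate mapped records", {
  a <- make_aln("a", 0L, mapq = 60L)
  b <- make_aln("b", 0L, mapq = 0L)
  expect_equal(mean_mapq(rbind(a, a)), 60)
  expect_equal(mean_mapq(rbind(a, b)), 30)
  expect_warning(res <- mean_mapq(a[0, ]), "MAPQ")
  expect_equal(res, 0)
  # duplicates are excluded from the average
  dupped <- rbind(a, b)
  dupped$flag[2] <- 1024L
  expect_equal(mean_mapq(dupped), 60)
})
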