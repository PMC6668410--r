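# Left-normalization, set subtraction, classification, summaries,
# subtype-specific indels and the length-distribution test.

test_that("left_normalize collapses every representation in a homopolymer", {
  # reference carries ATTTTG at positions 100-105
  ref <- c(cX = paste0(strrep("C", 99), "ATTTTG", strrep("C", 100)))
  # every way of writing "delete one T" must collapse to (100, AT, A)
  reps <- list(c(100L, "AT", "A"), c(101L, "TT", "T"), c(102L, "TT", "T"),
               c(103L, "TT", "T"))
  for (r in reps) {
    nm <- left_normalize("cX", as.integer(r[1]), r[2], r[3], ref)
    expect_equal(nm, list(chrom = "cX", pos = 100L, ref = "AT", alt = "A"),
                 info = paste("raw pos", r[1]))
  }
  # idempotence on an already-leftmost indel
  once <- left_normalize("cX", 100L, "AT", "A", ref)
  expect_equal(left_normalize("cX", once$pos, once$ref, once$alt, ref), once)
  # an insertion whose preceding base differs is already canonical
  ref2 <- c(cY = paste0(strrep("G", 99), "AC", strrep("G", 99)))
  nm2 <- left_normalize("cY", 100L, "A", "AC", ref2)
  # AC insertion context: inserting C before the existing C shifts once
  expect_equal(left_normalize("cY", nm2$pos, nm2$ref, nm2$alt, ref2), nm2)
  nm3 <- left_normalize("cY", 100L, "A", "AT", ref2)
  expect_equal(nm3, list(chrom = "cY", pos = 100L, ref = "A", alt = "AT"))
  # alleles inconsistent with the reference raise a locus-naming error
  expect_error(left_normalize("cX", 100L, "GG", "G", ref), "cX:100")
})

test_that("subtraction matches indels across representations", {
  ref <- c(cX = paste0(strrep("C", 99), "ATTTTG", strrep("C", 100)))
  new_calls <- data.frame(chrom = "cX", pos = 102L, ref = "TT", alt = "T",
                          filter = "PASS", spanning = 4L, supporting = 2L,
                          sample_id = "s1", stringsAsFactors = FALSE)
  orig <- data.frame(chrom = "cX", pos = 103L, ref = "TT", alt = "T",
                     filter = "PASS", spanning = NA_integer_,
                     supporting = NA_integer_, sample_id = "s0",
                     stringsAsFactors = FALSE)
  # same physical deletion at different raw positions: matched, excluded
  expect_equal(nrow(subtract_indels(new_calls, orig, ref)), 0L)
  # identical sets -> empty; disjoint sets -> identity
  expect_equal(nrow(subtract_indels(new_calls, new_calls, ref)), 0L)
  other <- data.frame(chrom = "cX", pos = 150L, ref = "CC", alt = "C",
                      filter = "PASS", spanning = NA_integer_,
                      supporting = NA_integer_, sample_id = "s0",
                      stringsAsFactors = FALSE)
  res <- subtract_indels(new_calls, other, ref)
  expect_equal(nrow(res), 1L)
  expect_equal(res$pos, 100L)  # returned in normalized representation
})

test_that("filter_pass keeps exactly the PASS records", {
  v <- data.frame(chrom = "c", pos = 1:3, ref = "AT", alt = "A",
                  filter = c("PASS", "lowFrac", "PASS"),
                  spanning = NA_integer_, supporting = NA_integer_,
                  sample_id = NA_character_, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_pass(v)), 2L)
  expect_equal(nrow(filter_pass(v[v$filter != "PASS", ])), 0L)
  expect_equal(nrow(filter_pass(v[v$filter == "PASS", ])), 2L)
})

test_that("classification follows allele-length difference and frame rule", {
  # a 15-base deletion is in-frame
  del15 <- classify_indel(paste0("A", strrep("T", 15)), "A")
  expect_equal(del15$kind, "deletion")
  expect_equal(del15$frame, "in-frame")
  expect_equal(del15$length, -15L)
  # the 1-base CT->C deletion is a frameshift
  d1 <- classify_indel("CT", "C")
  expect_equal(d1$kind, "deletion")
  expect_equal(d1$frame, "frameshift")
  # a 28-base insertion is a frameshift (28 mod 3 = 1)
  i28 <- classify_indel("A", paste0("A", strrep("G", 28)))
  expect_equal(i28$kind, "insertion")
  expect_equal(i28$frame, "frameshift")
  expect_error(classify_indel("A", "T"), "not an indel")
})

test_that("summaries reproduce ratio and share arithmetic", {
  mk <- function(n_ins, n_del) {
    n <- n_ins + n_del
    data.frame(chrom = rep("c", n), pos = seq_len(n),
               ref = rep(c("A", "AT"), c(n_ins, n_del)),
               alt = rep(c("AT", "A"), c(n_ins, n_del)),
               filter = rep("PASS", n), spanning = rep(NA_integer_, n),
               supporting = rep(NA_integer_, n),
               sample_id = rep(NA_character_, n),
               stringsAsFactors = FALSE)
  }
  s <- summarize_indels(mk(31924L, 41073L))
  expect_equal(s$del_ins_ratio, 1.29)
  expect_equal(s$insertion_share, 43.73)
  expect_equal(s$n_total, 72997L)
  expect_equal(s$n_total, s$n_insertions + s$n_deletions)
  expect_equal(s$n_total, s$n_frameshift + s$n_inframe)
  expect_equal(sum(s$length_histogram), s$n_total)
  # empty set: zeros and NA ratio
  s0 <- summarize_indels(mk(0L, 0L))
  expect_equal(s0$n_total, 0L)
  expect_true(is.na(s0$del_ins_ratio))
  # additivity over a disjoint partition
  a <- summarize_indels(mk(10L, 5L)); b <- summarize_indels(mk(3L, 7L))
  both <- summarize_indels(mk(13L, 12L))
  expect_equal(a$n_insertions + b$n_insertions, both$n_insertions)
  expect_equal(a$n_deletions + b$n_deletions, both$n_deletions)
})

test_that("subtype-specific indels require presence in exactly one subtype", {
  labels <- data.frame(sample_id = c("b1", "b2", "l1", "l2"),
                       subtype = c("Basal", "Basal", "LumA", "LumA"),
                       stringsAsFactors = FALSE)
  keys <- list(b1 = c("c:1:AT:A", "c:5:G:GT"), b2 = c("c:5:G:GT"),
               l1 = c("c:9:T:TA"), l2 = c("c:9:T:TA", "c:5:G:GT"))
  res <- subtype_specific(keys, labels)
  expect_setequal(res$Basal, "c:1:AT:A")    # only in Basal samples
  expect_setequal(res$LumA, "c:9:T:TA")
  expect_false("c:5:G:GT" %in% unlist(res))  # shared: specific to neither
  expect_error(subtype_specific(keys[1:2], labels[1:2, ]), "two subtypes")
})

test_that("length-distribution chi-square matches the textbook formula", {
  ha <- c(`-1` = 50, `1` = 50)
  hb <- c(`-1` = 90, `1` = 10)
  res <- length_dist_chisq(ha, hb)
  # hand computation on the 2x2 table: E = (70, 30; 70, 30)
  exp_stat <- (50 - 70)^2 / 70 + (50 - 30)^2 / 30 +
    (90 - 70)^2 / 70 + (10 - 30)^2 / 30
  expect_equal(res$statistic, exp_stat)
  expect_equal(res$p_value, pchisq(exp_stat, 1, lower.tail = FALSE))
  # identical histograms: statistic 0, p 1
  res0 <- length_dist_chisq(ha, ha)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # disjoint supports: overwhelming evidence of difference
  res2 <- length_dist_chisq(c(`-2` = 200, `-1` = 200),
                            c(`1` = 200, `2` = 200))
  expect_lt(res2$p_value, 1e-10)
  expect_error(length_dist_chisq(ha, numeric(0)), "non-empty")
})

test_that("sparse length bins are pooled before testing", {
  ha <- c(`-3` = 1, `-1` = 60, `1` = 60, `5` = 2)
  hb <- c(`-1` = 50, `1` = 70, `4` = 1)
  res <- length_dist_chisq(ha, hb)
  exp_counts <- outer(rowSums(res$table), colSums(res$table)) / sum(res$table)
  expect_true(all(exp_counts >= 5))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})
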