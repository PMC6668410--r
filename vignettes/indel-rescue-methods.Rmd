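---
title: "Rescuing indels from unmapped reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescuing indels from unmapped reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelrescue)
```

## The problem and the model

Short-read variant calling starts from an alignment, and whatever the
aligner could not place is excluded from everything downstream. Reads fail
to map for reasons that are often repairable: adapter read-through, a
collapsed-quality tail, or an indel larger than the aligner's gap
tolerance. When the reads covering an indel locus systematically fail for
one of these reasons, the indel disappears from the call set entirely.

`indelrescue` models the repair as a five-stage pipeline:

1. **Extraction.** Unmapped *primary* records (SAM flag 0x4 set, 0x100 and
   0x800 clear) are exported as single-end reads. If a record stores the
   sequence reverse-complemented (0x10), the exported read is restored to
   sequencing orientation. Secondary/supplementary records duplicate a
   primary and are never exported; mapped reads whose *mate* is unmapped
   are not exported either — the target is reads that themselves failed.
2. **Quality control.** Trimmomatic-style single-end trimming, in the
   fixed order adapter → leading → trailing → sliding window → length
   filter (see parameters below). `N` bases count as quality 0 in every
   threshold comparison. Each step keeps a contiguous substring, so a
   surviving read is always a substring of its input, and the composite
   operation is idempotent.
3. **Two-tier remapping.** Reads go to a primary seed-and-extend aligner;
   only its failures go to a second, more sensitive tier (shorter seeds).
   Tiering makes "both aligners placed the read differently" unreachable
   by construction. Duplicates are then marked per (contig, unclipped 5'
   position, strand), keeping the record with the highest base-quality sum
   (ties broken by read name).
4. **Calling.** Every I/D CIGAR operation in a non-duplicate mapped record
   yields a candidate in the VCF anchor-base convention. A read *supports*
   a candidate if it carries the event; it *spans* the candidate if its
   aligned reference span covers the anchor through the first position
   after the event. FILTER is `PASS` when supporting reads ≥ 2,
   supporting/spanning ≥ 0.3, and mean supporting base quality ≥ 20;
   otherwise the first failed criterion is named, checked in the order
   `noSpan`, `lowFrac`, `lowSupport`, `lowBaseQ`.
5. **Novelty.** Both the new calls and the original call set are
   left-normalized — while both alleles end in the same base, drop it;
   when an allele empties, extend both one reference base leftward — which
   yields the unique leftmost representation, so the same physical event
   written at different positions in a repeat still matches. New calls
   whose normalized key (chrom, pos, REF, ALT) is absent from the original
   set, and which carry `PASS`, are the novel high-quality (NHQ) indels.

The haploid, single-sample model is deliberate: the pipeline never uses
genotypes or ploidy, and multi-sample joint calling is out of scope.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `leading_q`, `trailing_q` | 3 | Phred floor for end trimming (`LEADING:3`, `TRAILING:3`). |
| `window`, `window_q` | 4, 15 | sliding-window width (bases) and mean-quality cut (`SLIDINGWINDOW:4:15`). |
| `min_len` | 36 | reads shorter than this after trimming are dropped (`MINLEN:36`). |
| `min_adapter_overlap` | 8 | smallest read/adapter overlap that can trigger a clip; below this, chance matches dominate. |
| `max_adapter_mismatch_frac` | 0.1 | mismatch tolerance within the overlap. |
| `seed_len` | 19 (tier 1), 11 (tier 2) | exact-seed length; tier 2 trades specificity for sensitivity on reads with short exact stretches. |
| `band` | 50 | half-width of the DP window around a candidate diagonal; bounds the recoverable indel shift. |
| match/mismatch/gap open/gap extend | 1 / −4 / −6 / −1 | affine scores; a gap of length L costs 6 + L. |
| `min_score_frac` | 0.25 | alignment score floor as a fraction of read length × match. Chosen so a minimally surviving QC'd read (36–64 bp) carrying an insertion up to 20 bp still clears the floor (e.g. a 64 bp read with a 20 bp insertion scores 44 − 26 = 18 = 0.28 × 64). Spurious placements are already excluded by the exact-seed requirement, so the floor can be permissive. |
| `min_support`, `min_frac`, `min_mean_baseq` | 2, 0.3, 20 | calling thresholds. `min_frac = 0.3` is chosen to sit between a 25%-supported event (not called) and a 50%-supported event (called), the two support regimes the method is designed to distinguish. |
| `k`, `s` | 21, 1000 | MinHash k-mer length and sketch capacity (Mash's published defaults). |
| linkage | average | standard choice for clustering a distance matrix; configurable. |

MAPQ is a uniqueness proxy, `min(60, best − second-best candidate score)`,
bounded like SAM MAPQ and monotone in how much the best placement
dominates. It is not calibrated as an error probability.

## Statistical tests

The **two-proportion z-test** uses the *unpooled* standard error,
\(z = (\hat p_1 - \hat p_2) / \sqrt{\hat p_1(1-\hat p_1)/n_1 + \hat p_2(1-\hat p_2)/n_2}\),
with a one-sided upper-tail p-value (alternative \(p_1 > p_2\)). The
choice of the unpooled form is load-bearing: on the worked cancer-gene
table (62/142 vs 6,829/20,172) it gives z = 2.35, where the pooled form
gives ≈ 2.46. The **Yates chi-square** is the standard continuity-corrected
statistic with cell terms clamped at zero (via `stats::chisq.test`). The
**resampling test** draws genes without replacement and reports the
fraction of replicates reaching at least the observed overlap; the strict
“greater than” rule is also selectable. Its analytic oracle is the exact
hypergeometric tail, returned alongside every result — at 1,000 replicates
the Monte-Carlo standard error around a tail of ~0.009 is ~0.003, so
seeded results between roughly 0.004 and 0.015 are expected. The
**length-distribution comparison** is a Pearson chi-square of homogeneity
on the 2 × L table of signed indel lengths; columns whose smallest
expected count falls below 5 are pooled into their nearest flanking column
first, to keep the asymptotic test valid.

## The synthetic-data generator

`sim_config()` describes the study conditions used throughout the tests: a
100 kb uniform-random reference, 100-base reads at 30× coverage, 10
planted indels of lengths 1–20 with a deletion:insertion skew of 1.3:1 and
a geometric-like length decay (probability ∝ 0.75^L), planted at least two
read lengths apart so loci stay independent. A configurable subset of the
planted indels (all of them by default) is *hidden*: every read whose span
overlaps such an indel is contaminated — its tail is replaced by adapter
sequence with Phred-2 qualities after a 64-base genomic prefix — and enters
the "original" alignment as an unmapped record. The original call set is
called from the mapped records only, so hidden indels are absent from it
by construction, and the pipeline's job is to get them back. The 64-base
prefix is chosen so that both the adapter clipper and the quality trimmers
engage on every contaminated read while the survivor still clears the
36-base length floor.

What the simulator does *not* emulate: realistic quality-by-cycle error
profiles, paired-end structure, PCR duplicate stacks, repetitive genome
content, heterozygosity, and structural variants beyond 45 bp. Passing the
recovery tests therefore demonstrates that the machinery is correct under
clean, independent-locus conditions; it does not certify recall on real
tumour genomes, where repeats and haplotypes make both mapping and
support-counting harder.

## Numerical and degenerate-input choices

* Alignment ties (equally scoring gap placements inside a repeat) are
  resolved deterministically by the DP traceback; the *called variant* is
  made placement-independent by left-normalization, so tests compare
  normalized keys, not CIGAR strings.
* `mash_distance` caps at 1 when the sketches share nothing and returns
  exactly 0 for identical sketches; sketches are only comparable at equal
  k, s and hash seed, and any mismatch is an error rather than a silent
  recompute.
* Hash values are 64-bit (seeded splitmix finalizer over 2-bit-encoded
  canonical k-mers) truncated to their top 53 bits so they survive R's
  numeric type with ordering and equality intact.
* Empty inputs return empty-but-well-formed results (zero-row tables,
  all-zero stats, `NA` ratio for an empty summary); `mean_mapq` of an
  empty set is 0 with a warning. Reads shorter than the seed are counted
  unalignable, never errors.
* All randomness (simulation, resampling) flows through explicit integer
  seeds; identical configurations give byte-identical outputs, and the RNG
  state of the calling session is restored afterwards.
* Phred+64 input is rejected, not auto-detected: quality characters
  outside the Phred+33 range [0, 93] are an error.

## Problem sizes in the test suite

Unit fixtures use references of 0.2–5 kb; the aligner is cross-checked
against an unbanded full-matrix DP oracle on references up to 1 kb; the
end-to-end recovery tests run the full 100 kb / 30× / 10-indel
configuration (about 30,000 reads, ~20 s each) at base error rates 0 and
0.1%; the MinHash estimator is checked at sketch size 4,096 against a
known Jaccard index of 0.5. These sizes were chosen as the smallest at
which each property is meaningfully exercised.

## Known limitations

* The caller reads indels directly off CIGAR operations; there is no local
  assembly, no genotype likelihoods, and no SNV output. Indels the aligner
  represents as mismatch runs instead of gaps are invisible to it.
* Soft-clipped bases contribute to neither support nor span, so
  breakpoint-adjacent evidence is conservative.
* The adapter clipper is a simple-mode overlap scan; palindrome-mode
  (pair-aware) clipping is not replicated, as the pipeline is single-end
  throughout.
* Subtype-specific indels are defined for exactly two subtype labels;
  more requires a different definition and is refused rather than guessed.
* The two-tier design assigns each read to at most one aligner, so
  disagreement between tiers cannot occur — which also means the second
  tier can never rescue a read the first tier placed badly.
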