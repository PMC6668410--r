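# Shared fixtures and independent oracles. Everything is generated in code
# under fixed seeds; nothing is read from disk except the bundled adapter
# FASTA.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_read <- function(sequence, qual = NULL, read_id = "r1") {
  if (is.null(qual)) qual <- strrep("I", nchar(sequence))
  data.frame(read_id = read_id, sequence = sequence, qual = qual,
             stringsAsFactors = FALSE)
}

# SAM-style alignment row builder
make_aln <- function(qname = "r1", flag = 0L, rname = "chr1", pos = 1L,
                     mapq = 60L, cigar = "10M", seq = strrep("A", 10L),
                     qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = "*", pnext = 0L, tlen = 0L,
             seq = seq, qual = qual, tags = "", stringsAsFactors = FALSE)
}

# Independent full-matrix affine-gap fitting alignment (read global,
# reference local): the oracle for the seed-and-extend aligner. Plain R,
# unbanded, no seeding — deliberately shares no code with the implementation.
fit_align_oracle_score <- function(read, ref, match = 1, mismatch = -4,
                                   gap_open = -6, gap_extend = -1) {
  n <- nchar(read); m <- nchar(ref)
  rb <- strsplit(read, "")[[1]]
  gb <- strsplit(ref, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  D <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0
  for (i in 2:(n + 1)) {
    I[i, 1] <- gap_open + (i - 1) * gap_extend
    for (j in 2:(m + 1)) {
      s <- if (rb[i - 1] == gb[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], I[i - 1, j - 1], D[i - 1, j - 1]) + s
      I[i, j] <- max(M[i - 1, j] + gap_open + gap_extend,
                     I[i - 1, j] + gap_extend)
      D[i, j] <- max(M[i, j - 1] + gap_open + gap_extend,
                     D[i, j - 1] + gap_extend)
    }
  }
  max(M[n + 1, ], I[n + 1, ])
}

# small two-population read sets with (near-)disjoint k-mer content
two_population_reads <- function(n_samples_per_pop = 3, n_reads = 50,
                                 read_len = 60, seed = 11) {
  set.seed(seed)
  popA <- random_dna(2000)
  popB <- random_dna(2000)
  out <- list()
  for (p in 1:2) {
    src <- if (p == 1) popA else popB
    for (s in seq_len(n_samples_per_pop)) {
      starts <- sample.int(nchar(src) - read_len + 1, n_reads, replace = TRUE)
      out[[sprintf("pop%d_s%d", p, s)]] <-
        substring(src, starts, starts + read_len - 1)
    }
  }
  out
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
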