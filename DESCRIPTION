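Package: indelrescue
Title: Rescue of Novel Indels from Originally Unmapped Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline that recovers insertion/deletion variants
    hidden in the unmapped reads of a short-read alignment. Unmapped reads are
    extracted from a text SAM alignment, quality-controlled with
    Trimmomatic-style adapter clipping and quality trimming, remapped with a
    two-tier seed-and-extend aligner, and indels are called from CIGAR
    evidence with read-support filters. Calls already present in the original
    call set are subtracted after VCF left-normalization, and the surviving
    PASS calls ("novel high-quality" indels) feed downstream analyses:
    length and frameshift summaries, MinHash/Mash-distance sample clustering
    with subtype confusion matrices, subtype-specific indels, and
    oncogene/tumour-suppressor enrichment tests (two-proportion z,
    Yates-corrected chi-square, and a resampling test with an exact
    hypergeometric oracle). A seeded simulator generates a reference, a donor
    with planted indels, and adapter-contaminated reads so the whole pipeline
    is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
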