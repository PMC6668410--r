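# Readers and writers for the plain-text formats the pipeline exchanges:
# 4-line FASTQ (Phred+33 only), FASTA (via Biostrings), text SAM v1.6,
# a minimal VCF 4.2 dialect (CHROM/POS/REF/ALT/FILTER plus read-support INFO
# keys), BED3+2 gene intervals and the two-column sample-subtype table.
# Readers consume their input in bounded chunks so parser state stays
# constant-size per record; gzip-compressed input is accepted everywhere.

CHUNK_LINES <- 40000L

# ---- FASTQ -----------------------------------------------------------------

#' Read a 4-line FASTQ file (Phred+33)
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @return data.frame with columns `read_id`, `sequence`, `qual`
#'   (the Phred+33-encoded quality string). Use [phred_decode()] for numeric
#'   qualities.
#' @export
read_fastq <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  out <- list()
  line_no <- 0L
  carry <- character(0)
  repeat {
    lines <- c(carry, readLines(con, n = CHUNK_LINES))
    if (!length(lines)) break
    nrec <- length(lines) %/% 4L
    carry <- if (nrec * 4L < length(lines)) lines[(nrec * 4L + 1L):length(lines)] else character(0)
    if (nrec == 0L) {
      if (length(readLines(con, n = 1L)) == 0L && length(carry))
        stop("truncated FASTQ record starting at line ", line_no + 1L)
      next
    }
    lines <- lines[seq_len(nrec * 4L)]
    ids <- lines[seq(1L, by = 4L, length.out = nrec)]
    seqs <- lines[seq(2L, by = 4L, length.out = nrec)]
    plus <- lines[seq(3L, by = 4L, length.out = nrec)]
    quals <- lines[seq(4L, by = 4L, length.out = nrec)]
    bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+"))
    if (length(bad))
      stop("malformed FASTQ record at line ", line_no + (bad[1] - 1L) * 4L + 1L)
    mism <- which(nchar(seqs) != nchar(quals))
    if (length(mism))
      stop("sequence/quality length mismatch at line ",
           line_no + (mism[1] - 1L) * 4L + 1L)
    out[[length(out) + 1L]] <- data.frame(
      read_id = sub("^@", "", sub("[ \t].*$", "", ids)),
      sequence = toupper(seqs), qual = quals, stringsAsFactors = FALSE)
    line_no <- line_no + nrec * 4L
  }
  if (length(carry))
    stop("truncated FASTQ record starting at line ", line_no + 1L)
  if (!length(out))
    return(data.frame(read_id = character(0), sequence = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  invisible(lapply(res$qual, phred_decode))  # range check
  res
}

#' Write reads to a 4-line FASTQ file (Phred+33)
#'
#' @param reads data.frame as returned by [read_fastq()].
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "qual") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$qual)))
    stop("sequence/quality length mismatch")
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

# ---- FASTA -----------------------------------------------------------------

#' Read a FASTA reference as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one element per contig, upper-case.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("[ \t].*$", "", names(out))
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---- SAM (text) ------------------------------------------------------------

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual")

#' Read a text SAM file
#'
#' @param path SAM file (text, optionally gzip-compressed).
#' @param validate check that query-consuming CIGAR length matches the
#'   sequence length on mapped records (default `TRUE`).
#' @return list with `header` (character vector of `@` lines) and
#'   `alignments` (data.frame with the 11 mandatory SAM columns plus `tags`).
#' @export
read_sam <- function(path, validate = TRUE) {
  con <- open_text(path)
  on.exit(close(con))
  header <- character(0)
  chunks <- list()
  repeat {
    lines <- readLines(con, n = CHUNK_LINES)
    if (!length(lines)) break
    hdr <- startsWith(lines, "@")
    header <- c(header, lines[hdr])
    body <- lines[!hdr]
    if (!length(body)) next
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L))
      stop("SAM record with fewer than 11 mandatory columns: ",
           body[which(nf < 11L)[1]])
    aln <- data.frame(
      qname = vapply(fields, `[[`, "", 1L),
      flag = as.integer(vapply(fields, `[[`, "", 2L)),
      rname = vapply(fields, `[[`, "", 3L),
      pos = as.integer(vapply(fields, `[[`, "", 4L)),
      mapq = as.integer(vapply(fields, `[[`, "", 5L)),
      cigar = vapply(fields, `[[`, "", 6L),
      rnext = vapply(fields, `[[`, "", 7L),
      pnext = as.integer(vapply(fields, `[[`, "", 8L)),
      tlen = as.integer(vapply(fields, `[[`, "", 9L)),
      seq = toupper(vapply(fields, `[[`, "", 10L)),
      qual = vapply(fields, `[[`, "", 11L),
      tags = vapply(fields, function(f)
        if (length(f) > 11L) paste(f[12:length(f)], collapse = "\t") else "",
        ""),
      stringsAsFactors = FALSE)
    chunks[[length(chunks) + 1L]] <- aln
  }
  aln <- if (length(chunks)) do.call(rbind, chunks) else
    data.frame(qname = character(0), flag = integer(0), rname = character(0),
               pos = integer(0), mapq = integer(0), cigar = character(0),
               rnext = character(0), pnext = integer(0), tlen = integer(0),
               seq = character(0), qual = character(0), tags = character(0),
               stringsAsFactors = FALSE)
  if (validate && nrow(aln)) {
    mapped <- bitwAnd(aln$flag, 4L) == 0L & aln$seq != "*" & aln$cigar != "*"
    if (any(mapped)) {
      qlen <- cigar_query_length(aln$cigar[mapped])
      bad <- which(qlen != nchar(aln$seq[mapped]))
      if (length(bad))
        stop("CIGAR/sequence length mismatch for read ",
             aln$qname[mapped][bad[1]])
    }
  }
  list(header = header, alignments = aln)
}

#' Write a text SAM file
#'
#' @param sam list with `header` and `alignments` as from [read_sam()].
#' @param path output file.
#' @export
write_sam <- function(sam, path) {
  aln <- sam$alignments
  body <- paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq, aln$cigar,
                aln$rnext %||% "*", aln$pnext %||% 0L, aln$tlen %||% 0L,
                aln$seq, aln$qual, sep = "\t")
  tags <- aln$tags %||% rep("", nrow(aln))
  has_tag <- !is.na(tags) & tags != ""
  body[has_tag] <- paste(body[has_tag], tags[has_tag], sep = "\t")
  writeLines(c(sam$header, body), path)
  invisible(path)
}

# minimal SAM header for a reference
sam_header <- function(reference) {
  c("@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", names(reference), "\tLN:", nchar(reference)))
}

# ---- VCF -------------------------------------------------------------------

IUPAC_RE <- "^[ACGTNRYSWKMBDHVacgtnryswkmbdhv]+$"

#' Read indels (or all variants) from a VCF file
#'
#' Multi-allelic rows are split into one record per ALT allele.
#'
#' @param path VCF file (any 4.x dialect; only CHROM, POS, REF, ALT, FILTER
#'   and the optional `SUPP`/`SPAN` INFO keys are interpreted).
#' @param indels_only keep only records with `nchar(REF) != nchar(ALT)`
#'   (default `TRUE`).
#' @param sample_id optional sample label attached to every record.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `filter`,
#'   `spanning`, `supporting`, `sample_id`.
#' @export
read_vcf <- function(path, indels_only = TRUE, sample_id = NA_character_) {
  con <- open_text(path)
  on.exit(close(con))
  chunks <- list()
  repeat {
    lines <- readLines(con, n = CHUNK_LINES)
    if (!length(lines)) break
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines)) next
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 7L))
      stop("VCF record with fewer than 7 columns: ", lines[which(nf < 7L)[1]])
    chrom <- vapply(fields, `[[`, "", 1L)
    pos <- as.integer(vapply(fields, `[[`, "", 2L))
    ref <- toupper(vapply(fields, `[[`, "", 4L))
    alt_raw <- toupper(vapply(fields, `[[`, "", 5L))
    filt <- vapply(fields, `[[`, "", 7L)
    info <- vapply(fields, function(f) if (length(f) >= 8L) f[[8L]] else ".", "")
    if (any(!grepl(IUPAC_RE, ref)))
      stop("non-IUPAC characters in REF at ",
           chrom[which(!grepl(IUPAC_RE, ref))[1]])
    alts <- strsplit(alt_raw, ",", fixed = TRUE)
    n_alt <- lengths(alts)
    idx <- rep(seq_along(alts), n_alt)
    alt <- unlist(alts)
    if (any(!grepl(IUPAC_RE, alt)))
      stop("non-IUPAC characters in ALT at ", chrom[idx[which(!grepl(IUPAC_RE, alt))[1]]])
    supp <- suppressWarnings(as.integer(sub(".*SUPP=([0-9]+).*", "\\1", info)))
    span <- suppressWarnings(as.integer(sub(".*SPAN=([0-9]+).*", "\\1", info)))
    chunks[[length(chunks) + 1L]] <- data.frame(
      chrom = chrom[idx], pos = pos[idx], ref = ref[idx], alt = alt,
      filter = filt[idx], spanning = span[idx], supporting = supp[idx],
      sample_id = sample_id, stringsAsFactors = FALSE)
  }
  v <- if (length(chunks)) do.call(rbind, chunks) else empty_variants(sample_id)
  if (indels_only) v <- v[nchar(v$ref) != nchar(v$alt), , drop = FALSE]
  rownames(v) <- NULL
  v
}

empty_variants <- function(sample_id = NA_character_) {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), filter = character(0), spanning = integer(0),
             supporting = integer(0),
             sample_id = character(0), stringsAsFactors = FALSE)
}

#' Write variants to a minimal VCF 4.2 file
#'
#' @param variants data.frame as from [read_vcf()] or [call_indels()].
#' @param path output file.
#' @param reference optional named character vector used to emit `##contig`
#'   header lines.
#' @export
write_vcf <- function(variants, path, reference = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SUPP,Number=1,Type=Integer,Description=\"Reads supporting the indel\">",
           "##INFO=<ID=SPAN,Number=1,Type=Integer,Description=\"Reads spanning the indel locus\">")
  if (!is.null(reference))
    hdr <- c(hdr, paste0("##contig=<ID=", names(reference),
                         ",length=", nchar(reference), ">"))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- ifelse(is.na(variants$supporting %||% NA) | is.na(variants$spanning %||% NA),
                 ".",
                 paste0("SUPP=", variants$supporting, ";SPAN=", variants$spanning))
  if (!nrow(variants)) info <- character(0)
  body <- if (nrow(variants))
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt, ".",
          variants$filter %||% "PASS", info, sep = "\t") else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- BED gene intervals ----------------------------------------------------

#' Read gene intervals from a BED3+2 file
#'
#' Coordinates are kept 0-based half-open exactly as in the file. Column 4 is
#' the gene name, column 5 a category label (`oncogene`, `tumour_suppressor`
#' or `noncancer`; missing columns default to `noncancer`).
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `category`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) stop("BED line with fewer than 3 columns")
  start <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  if (any(start >= end))
    stop("BED interval with start >= end at line ", which(start >= end)[1])
  data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start, end = end,
    name = vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else ".", ""),
    category = vapply(fields, function(f)
      if (length(f) >= 5L) f[[5L]] else "noncancer", ""),
    stringsAsFactors = FALSE)
}

#' Write gene intervals to a BED file
#'
#' @param intervals data.frame as from [read_bed()].
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  writeLines(paste(intervals$chrom, intervals$start, intervals$end,
                   intervals$name, intervals$category, sep = "\t"), path)
  invisible(path)
}

# ---- sample -> subtype labels ---------------------------------------------

#' Read a two-column sample-to-subtype table
#'
#' @param path tab-separated file with columns sample id and subtype label.
#' @return data.frame with `sample_id`, `subtype`.
#' @export
read_subtype_labels <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("sample_id", "subtype"),
                    colClasses = "character")
  tab
}

#' Write a two-column sample-to-subtype table
#' @param labels data.frame with `sample_id`, `subtype`.
#' @param path output file.
#' @export
write_subtype_labels <- function(labels, path) {
  write.table(labels[, c("sample_id", "subtype")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
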