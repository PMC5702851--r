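# Readers/writers for the external formats the pipeline touches.
#
# Internal convention throughout the package: coordinates are 1-based, fully
# closed, on the reference strand. GTF is already 1-based closed; BED's
# 0-based half-open intervals are converted at this boundary and nowhere else.

#' Read a reference genome from FASTA
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return a [Biostrings::DNAStringSet] with unique names, sequence uppercased.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) abort("duplicate sequence names in FASTA")
  g
}

#' Write a genome to FASTA
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Parses a GTF2.2 file into a tibble of features (one row per exon/CDS/UTR
#' record), keeping the 1-based closed coordinates as-is.
#'
#' @param path path to a GTF file.
#' @return tibble with columns `chrom`, `source`, `feature`, `start`, `end`,
#'   `score`, `strand`, `frame`, `gene_id`, `transcript_id`.
#' @export
read_gtf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- stringr::str_split_fixed(lines, "\t", 9)
  if (ncol(fields) < 9 || any(fields[, 9] == "")) {
    bad <- which(fields[, 9] == "")[1]
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields", bad))
  }
  attr_get <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0(key, ' "([^"]*)"'))
    m[, 2]
  }
  tibble(
    chrom = fields[, 1],
    source = fields[, 2],
    feature = fields[, 3],
    start = as.integer(fields[, 4]),
    end = as.integer(fields[, 5]),
    score = fields[, 6],
    strand = fields[, 7],
    frame = fields[, 8],
    gene_id = attr_get(fields[, 9], "gene_id"),
    transcript_id = attr_get(fields[, 9], "transcript_id")
  )
}

#' Write gene models to GTF
#'
#' @param models tibble as returned by [read_gtf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- sprintf(
    '%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\tgene_id "%s"; transcript_id "%s";',
    models$chrom, models$source, models$feature, models$start, models$end,
    models$score, models$strand, models$frame, models$gene_id,
    models$transcript_id
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read repeat intervals from BED
#'
#' BED is 0-based half-open; intervals are converted to the package's 1-based
#' closed convention (`start` = BED start + 1).
#'
#' @param path path to a BED3/BED4 file.
#' @return tibble with `chrom`, `start`, `end` (1-based closed) and `kind`
#'   (BED name column, `NA` for BED3).
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- stringr::str_split(lines, "\t")
  n <- lengths(fields)
  if (any(n < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields", which(n < 3)[1]))
  }
  start0 <- as.integer(vapply(fields, `[`, "", 2))
  end0 <- as.integer(vapply(fields, `[`, "", 3))
  if (any(start0 >= end0)) abort("BED interval with start >= end")
  tibble(
    chrom = vapply(fields, `[`, "", 1),
    start = start0 + 1L,
    end = end0,
    kind = vapply(fields, function(f)
      if (length(f) >= 4) f[4] else NA_character_, character(1))
  )
}

#' Write repeat intervals to BED
#'
#' @param intervals tibble as returned by [read_bed()] (1-based closed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  has_kind <- !is.na(intervals$kind)
  lines <- ifelse(
    has_kind,
    sprintf("%s\t%d\t%d\t%s", intervals$chrom, intervals$start - 1L,
            intervals$end, intervals$kind),
    sprintf("%s\t%d\t%d", intervals$chrom, intervals$start - 1L, intervals$end)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a known-variant list
#'
#' Tab-separated with header `chrom pos ref alt zygosity`; positions 1-based.
#'
#' @param path path to the TSV.
#' @return tibble with those columns; `zygosity` in `het`, `hom`, `unknown`.
#' @export
read_known_variants <- function(path) {
  v <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    zygosity = readr::col_character()
  ))
  if (any(v$ref == v$alt)) abort("known variant with ref == alt")
  if (any(nchar(v$ref) != 1L | nchar(v$alt) != 1L)) {
    abort("known variants must be single-nucleotide")
  }
  v
}

#' Write a known-variant list
#'
#' @param variants tibble as returned by [read_known_variants()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_known_variants <- function(variants, path) {
  readr::write_tsv(variants[, c("chrom", "pos", "ref", "alt", "zygosity")], path)
  invisible(path)
}

# SAM --------------------------------------------------------------------

#' Read aligned reads from a SAM file
#'
#' Supports the subset of SAM the pipeline needs: uncompressed text, header
#' lines ignored except for validation, and the FLAG (duplicate bit 0x400
#' honoured), RNAME, POS, MAPQ, SEQ and QUAL fields. CIGARs are carried along
#' but the pipeline assumes match-only alignments.
#'
#' @param path path to a SAM file.
#' @param sample sample identifier attached to every read; defaults to the
#'   file name without extension.
#' @param genome optional [Biostrings::DNAStringSet]; when given, reads on
#'   chromosomes absent from it raise a reference-mismatch error.
#' @return tibble with columns `sample`, `qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`, `mate_pos`, `duplicate`.
#' @export
read_sam <- function(path, sample = NULL, genome = NULL) {
  sample <- sample %||% sub("\\.sam$", "", basename(path))
  lines <- readr::read_lines(path)
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  fields <- stringr::str_split_fixed(rec, "\t", 12)
  if (length(rec) && any(fields[, 11] == "")) {
    abort(sprintf("malformed SAM line %d: fewer than 11 fields",
                  which(fields[, 11] == "")[1]))
  }
  flag <- as.integer(fields[, 2])
  reads <- tibble(
    sample = rep(sample, length(rec)),
    qname = fields[, 1],
    flag = flag,
    chrom = fields[, 3],
    pos = as.integer(fields[, 4]),
    mapq = as.integer(fields[, 5]),
    cigar = fields[, 6],
    seq = fields[, 10],
    qual = fields[, 11],
    mate_pos = ifelse(fields[, 8] == "0", NA_integer_, as.integer(fields[, 8])),
    duplicate = bitwAnd(flag, 1024L) > 0L
  )
  if (!is.null(genome)) {
    unknown <- setdiff(unique(reads$chrom), c("*", names(genome)))
    if (length(unknown)) {
      abort(sprintf("SAM references chromosome(s) absent from genome: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  reads
}

#' Write aligned reads to a SAM file
#'
#' @param reads tibble as returned by [read_sam()].
#' @param path output path.
#' @param genome optional [Biostrings::DNAStringSet] used to emit `@SQ`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, genome = NULL) {
  header <- "@HD\tVN:1.6\tSO:coordinate"
  if (!is.null(genome)) {
    header <- c(header, sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                                Biostrings::width(genome)))
  }
  flag <- reads$flag
  flag <- ifelse(reads$duplicate, bitwOr(flag, 1024L), flag)
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
    reads$qname, flag, reads$chrom, reads$pos, reads$mapq, reads$cigar,
    ifelse(is.na(reads$mate_pos), "*", "="),
    ifelse(is.na(reads$mate_pos), 0L, reads$mate_pos),
    reads$seq, reads$qual
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

# FASTQ ------------------------------------------------------------------

#' Read raw reads from FASTQ
#'
#' @param path path to an uncompressed FASTQ file.
#' @return tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) %% 4 != 0) abort("FASTQ file length not a multiple of 4")
  idx <- seq(1, length(lines), by = 4)
  tibble(
    id = sub("^@", "", lines[idx]),
    seq = lines[idx + 1],
    qual = lines[idx + 3]
  )
}

#' Write raw reads to FASTQ
#'
#' @param reads tibble with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  readr::write_lines(lines, path)
  invisible(path)
}
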