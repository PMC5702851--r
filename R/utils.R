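#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over DNA strings (IUPAC codes supported via
#' Biostrings). RNA `U` is normalised to `T` first.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  x <- chartr("Uu", "Tt", x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 helpers -------------------------------------------------------

qual_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

int_to_qual <- function(ints) {
  vapply(ints, function(i) rawToChar(as.raw(i + 33L)), character(1))
}

# single-base lookups against a DNAStringSet, vectorised over positions
genome_base <- function(genome, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (!ch %in% names(genome)) {
      abort(sprintf("chromosome '%s' not present in genome", ch))
    }
    s <- as.character(genome[[ch]])
    p <- pos[idx]
    if (any(p < 1L | p > nchar(s))) {
      abort(sprintf("position out of range on chromosome '%s'", ch))
    }
    out[idx] <- stringr::str_sub(s, p, p)
  }
  out
}

# contiguous slice, 1-based closed
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    abort(sprintf("chromosome '%s' not present in genome", chrom))
  }
  s <- genome[[chrom]]
  if (start < 1L || end > length(s) || start > end) {
    abort(sprintf("slice %s:%d-%d out of range", chrom, start, end))
  }
  as.character(Biostrings::subseq(s, start, end))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)
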