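# Fixtures built in code: a toy genome with known coding sequence, small
# read builders, and independent oracles used across test files.

# 120 bp toy chromosome; a plus-strand gene (exon 1..30, CDS 4..15 reading
# ATG AAA CAA TGA) and a minus-strand gene (exon 61..100, CDS 80..91 whose
# coding sequence is also ATG AAA CAA TGA).
toy_genome <- function() {
  plus_cds <- "ATGAAACAATGA"
  minus_cds_genomic <- editomer::revcomp("ATGAAACAATGA")
  s <- paste0(
    "GGC", plus_cds, strrep("C", 15),         # 1..30: exon of gene A
    strrep("G", 30),                          # 31..60: intergenic
    "TTCTTCTTCTTCTTCTTCT",                    # 61..79: 3'UTR of gene B (minus)
    minus_cds_genomic,                        # 80..91: CDS of gene B
    strrep("A", 9),                           # 92..100: 5'UTR of gene B
    strrep("G", 20)                           # 101..120
  )
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "chr1"
  g
}

toy_models <- function() {
  tibble::tribble(
    ~chrom, ~source, ~feature, ~start, ~end, ~score, ~strand, ~frame,
    ~gene_id, ~transcript_id,
    "chr1", "toy", "exon", 1L, 30L, ".", "+", ".", "geneA", "geneA.t1",
    "chr1", "toy", "five_prime_utr", 1L, 3L, ".", "+", ".", "geneA", "geneA.t1",
    "chr1", "toy", "CDS", 4L, 15L, ".", "+", "0", "geneA", "geneA.t1",
    "chr1", "toy", "three_prime_utr", 16L, 30L, ".", "+", ".", "geneA", "geneA.t1",
    "chr1", "toy", "exon", 61L, 100L, ".", "-", ".", "geneB", "geneB.t1",
    "chr1", "toy", "three_prime_utr", 61L, 79L, ".", "-", ".", "geneB", "geneB.t1",
    "chr1", "toy", "CDS", 80L, 91L, ".", "-", "0", "geneB", "geneB.t1",
    "chr1", "toy", "five_prime_utr", 92L, 100L, ".", "-", ".", "geneB", "geneB.t1"
  )
}

# quick aligned-read builder with sane defaults
make_reads <- function(pos, seq, chrom = "chr1", sample = "s1", mapq = 60L,
                       qual = NULL, qname = NULL, mate_pos = NA_integer_) {
  n <- length(pos)
  seq <- rep_len(seq, n)
  tibble::tibble(
    sample = sample,
    qname = qname %||% sprintf("r%03d", seq_len(n)),
    flag = 0L,
    chrom = rep_len(chrom, n),
    pos = as.integer(pos),
    mapq = rep_len(as.integer(mapq), n),
    cigar = sprintf("%dM", nchar(seq)),
    seq = seq,
    qual = rep_len(qual %||% strrep("F", nchar(seq[1])), n),
    mate_pos = rep_len(as.integer(mate_pos), n),
    duplicate = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent per-read counting oracle for pileup
naive_pileup_oracle <- function(reads, genome, min_mapq = 20L) {
  counts <- list()
  for (i in seq_len(nrow(reads))) {
    if (reads$duplicate[i] || reads$mapq[i] < min_mapq) next
    bases <- strsplit(reads$seq[i], "")[[1]]
    for (k in seq_along(bases)) {
      if (!bases[k] %in% c("A", "C", "G", "T")) next
      key <- paste(reads$chrom[i], reads$pos[i] + k - 1L, bases[k])
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  counts
}

# brute-force single-linkage clustering oracle over positions
single_linkage_oracle <- function(pos, window) {
  n <- length(pos)
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) <= window && cl[i] != cl[j]) {
        cl[cl == max(cl[i], cl[j])] <- min(cl[i], cl[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(cl, unique(cl))
}

# exhaustive complementarity search used as the miRNA scanner oracle:
# does any alignment give >= seed_min consecutive WC pairs with seed 2..8?
mirna_seed_oracle <- function(window, mirna, seed_min = 7L) {
  mirna <- chartr("Uu", "Tt", toupper(mirna))
  wb <- strsplit(toupper(window), "")[[1]]
  mb <- strsplit(mirna, "")[[1]]
  wc <- function(m, t) {
    (m == "A" && t == "T") || (m == "T" && t == "A") ||
      (m == "C" && t == "G") || (m == "G" && t == "C")
  }
  for (a in 3:(length(wb) + 8)) {     # a = t + m over all overlaps
    run <- 0L
    for (m in 2:min(8L, length(mb))) {
      t <- a - m
      ok <- t >= 1 && t <= length(wb) && wc(mb[m], wb[t])
      run <- if (ok) run + 1L else 0L
      if (run >= seed_min) return(TRUE)
    }
  }
  FALSE
}

default_groups <- function() {
  tibble::tibble(
    sample = c(sprintf("control_rep%d", 1:3), sprintf("gentamicin_rep%d", 1:4),
               sprintf("neomycin_rep%d", 1:2)),
    group = c(rep("control", 3), rep("gentamicin", 4), rep("neomycin", 2))
  )
}
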