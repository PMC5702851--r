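Package: editomer
Title: Detection and Differential Analysis of A-to-I RNA Editing from Matched
    RNA/DNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for calling adenosine-to-inosine (A-to-I) RNA
    editing sites from matched RNA-seq and DNA-seq alignments and for
    quantifying how editing responds to treatment. Implements read trimming and
    quality filtering, duplicate marking, pileup base counting, a candidate
    filter cascade (DNA variants, known SNPs, intergenic positions,
    homopolymers, simple repeats) and hyper-editing cluster calling; per-sample
    editing degrees with group means and a high/low variation classifier;
    two-sample sequence-logo statistics for flanking-sequence context; FPKM
    expression quantification with fold-change calls and the editing-expression
    correlation; and a simplified miRNA seed-match scanner for binding sites
    gained or lost by editing. A synthetic editome generator produces genomes,
    gene models, variants and pre-aligned reads with planted truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
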