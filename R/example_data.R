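# Curated worked-example tables shipped with the package: editing sites and
# expression values in hearing-loss- and ototoxicity-associated zebrafish
# genes under gentamicin and neomycin treatment. Editing degrees are stored
# as printed percentages and converted to proportions on load.

example_path <- function(file) {
  system.file("extdata", file, package = "editomer", mustWork = TRUE)
}

pct_cols <- c("control", "gentamicin", "neomycin")

#' Editing sites in deafness- and ototoxicity-associated genes
#'
#' Twenty-four editing sites in hearing-related zebrafish genes whose
#' group-mean editing degree changes by more than 15 percentage points in
#' both aminoglycoside arms relative to control.
#'
#' @return tibble with `chrom`, `pos`, `type`, group-mean editing degrees
#'   (`control`, `gentamicin`, `neomycin`, proportions in `[0, 1]`),
#'   `region`, `alteration`, `gene`.
#' @export
example_deafness_sites <- function() {
  out <- readr::read_tsv(example_path("deafness_editing_sites.tsv"),
                         show_col_types = FALSE)
  out[pct_cols] <- out[pct_cols] / 100
  out
}

#' FPKM values of down-regulated deafness genes
#'
#' Twenty-seven hearing-related genes down-regulated more than 1.5-fold in
#' both aminoglycoside arms, with per-condition FPKM and the reported log2
#' fold changes.
#'
#' @return tibble with `gene`, `control_fpkm`, `gentamicin_fpkm`,
#'   `log2fc_gentamicin`, `neomycin_fpkm`, `log2fc_neomycin`.
#' @export
example_deafness_expression <- function() {
  readr::read_tsv(example_path("deafness_expression_fpkm.tsv"),
                  show_col_types = FALSE)
}

#' Editing sites in genes with >1.5-fold expression change
#'
#' Twenty-one editing sites with more than a 15-percentage-point editing
#' change in genes whose expression differs more than 1.5-fold in both
#' aminoglycoside arms.
#'
#' @return tibble with `chrom`, `pos`, `type`, editing-degree proportions
#'   per group, `region`, `gene`, `expression_change`.
#' @export
example_expression_sites <- function() {
  out <- readr::read_tsv(example_path("expression_editing_sites.tsv"),
                         show_col_types = FALSE)
  out[pct_cols] <- out[pct_cols] / 100
  out
}

#' Editing sites in predicted miRNA binding elements
#'
#' Three sites where editing is predicted to create or destroy an miRNA
#' binding site, with the miRNA and the base pair formed at the edited
#' position before and after editing.
#'
#' @return tibble with site keys, editing-degree proportions, miRNA pairing
#'   before/after editing, `gene`, `expression_change`.
#' @export
example_mirna_sites <- function() {
  out <- readr::read_tsv(example_path("mirna_rebinding_sites.tsv"),
                         show_col_types = FALSE)
  out[pct_cols] <- out[pct_cols] / 100
  out
}
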