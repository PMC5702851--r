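#' Configuration for the synthetic editome generator
#'
#' Bundles and validates every tunable of the simulator: genome and gene-model
#' sizing, planted editing clusters with per-condition editing rates, germline
#' SNP decoys, homopolymer/simple-repeat decoys, treatment-group layout, and
#' sequencing parameters. The defaults describe the study design the pipeline
#' targets: nine RNA samples split control 3 / gentamicin 4 / neomycin 2 plus
#' one pooled DNA sample, clustered A-to-G editing placed mostly in 3'UTRs,
#' and treatment editing rates about 25 percentage points above control.
#'
#' @param seed integer seed; identical configs give byte-identical outputs.
#' @param n_chromosomes,chrom_length genome sizing (bases).
#' @param n_genes,exons_per_gene,exon_length,intron_length gene-model sizing.
#' @param utr5_fraction,utr3_fraction fraction of the transcript annotated as
#'   5'/3' UTR; the remainder is CDS (trimmed to a multiple of 3).
#' @param n_edit_clusters,sites_per_cluster,cluster_span planted hyper-editing
#'   clusters: number of clusters, sites per cluster, and the genomic span
#'   (bases) each cluster is confined to.
#' @param utr3_site_fraction fraction of clusters placed in 3'UTRs (the rest
#'   go to CDS).
#' @param edit_rates named numeric vector, condition -> per-site true editing
#'   proportion in `[0,1]`.
#' @param n_het_snps,n_hom_snps exonic germline SNP decoys.
#' @param n_homopolymer_decoys,n_repeat_decoys reference decoys planted inside
#'   gene bodies: single-base runs of length >= 6, and simple tandem repeats
#'   recorded as BED intervals.
#' @param decoy_mismatch_rate RNA-only mismatch rate planted at decoy
#'   positions so the location filters have something to remove.
#' @param groups named integer vector, group -> replicate count.
#' @param rna_depth,dna_depth mean per-base coverage.
#' @param read_length read length in bases.
#' @param base_error_rate per-base sequencing error probability.
#' @param mapq_high,mapq_low,mapq_low_fraction mapping-quality mixture: reads
#'   get `mapq_high` except a `mapq_low_fraction` share at `mapq_low`.
#' @param duplicate_fraction fraction of RNA fragments duplicated (PCR-style,
#'   same coordinates, new read name).
#' @param expr_frac_down,expr_frac_up,expr_fold_range fraction of genes whose
#'   abundance is scaled down/up in both treatments, and the fold range the
#'   scaling is drawn from.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 50000L,
                       n_genes = 12L,
                       exons_per_gene = 3L,
                       exon_length = 500L,
                       intron_length = 300L,
                       utr5_fraction = 0.1,
                       utr3_fraction = 0.4,
                       n_edit_clusters = 12L,
                       sites_per_cluster = 4L,
                       cluster_span = 150L,
                       utr3_site_fraction = 0.75,
                       edit_rates = c(control = 0.35, gentamicin = 0.62,
                                      neomycin = 0.60),
                       n_het_snps = 30L,
                       n_hom_snps = 30L,
                       n_homopolymer_decoys = 8L,
                       n_repeat_decoys = 8L,
                       decoy_mismatch_rate = 0.3,
                       groups = c(control = 3L, gentamicin = 4L, neomycin = 2L),
                       rna_depth = 50,
                       dna_depth = 30,
                       read_length = 100L,
                       base_error_rate = 0.002,
                       mapq_high = 60L,
                       mapq_low = 10L,
                       mapq_low_fraction = 0.05,
                       duplicate_fraction = 0.02,
                       expr_frac_down = 0.3,
                       expr_frac_up = 0.1,
                       expr_fold_range = c(1.5, 2)) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    utr5_fraction = utr5_fraction, utr3_fraction = utr3_fraction,
    n_edit_clusters = as.integer(n_edit_clusters),
    sites_per_cluster = as.integer(sites_per_cluster),
    cluster_span = as.integer(cluster_span),
    utr3_site_fraction = utr3_site_fraction,
    edit_rates = edit_rates,
    n_het_snps = as.integer(n_het_snps), n_hom_snps = as.integer(n_hom_snps),
    n_homopolymer_decoys = as.integer(n_homopolymer_decoys),
    n_repeat_decoys = as.integer(n_repeat_decoys),
    decoy_mismatch_rate = decoy_mismatch_rate,
    groups = groups,
    rna_depth = rna_depth, dna_depth = dna_depth,
    read_length = as.integer(read_length),
    base_error_rate = base_error_rate,
    mapq_high = as.integer(mapq_high), mapq_low = as.integer(mapq_low),
    mapq_low_fraction = mapq_low_fraction,
    duplicate_fraction = duplicate_fraction,
    expr_frac_down = expr_frac_down, expr_frac_up = expr_frac_up,
    expr_fold_range = expr_fold_range
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$edit_rates, cfg$base_error_rate, cfg$decoy_mismatch_rate,
             cfg$mapq_low_fraction, cfg$duplicate_fraction,
             cfg$utr5_fraction, cfg$utr3_fraction, cfg$utr3_site_fraction)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (is.null(names(cfg$edit_rates)) || anyDuplicated(names(cfg$edit_rates))) {
    abort("edit_rates must be uniquely named by condition")
  }
  if (is.null(names(cfg$groups)) || any(cfg$groups < 1)) {
    abort("groups must be named and replicate counts >= 1")
  }
  missing_rates <- setdiff(names(cfg$groups), names(cfg$edit_rates))
  if (length(missing_rates)) {
    abort(sprintf("group(s) without an edit rate: %s",
                  paste(missing_rates, collapse = ", ")))
  }
  if (cfg$chrom_length <= cfg$read_length) {
    abort("chrom_length must exceed read_length")
  }
  if (cfg$sites_per_cluster < 1) abort("sites_per_cluster must be >= 1")
  if (cfg$utr5_fraction + cfg$utr3_fraction >= 1) {
    abort("utr5_fraction + utr3_fraction must leave room for a CDS")
  }
  if (cfg$exon_length <= cfg$read_length) {
    abort("exon_length must exceed read_length (reads are emitted within exons)")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s) x %d bp, %d genes x %d exons\n",
              x$n_chromosomes, x$chrom_length, x$n_genes, x$exons_per_gene))
  cat(sprintf("  editing: %d clusters x %d sites; rates %s\n",
              x$n_edit_clusters, x$sites_per_cluster,
              paste(sprintf("%s=%.2f", names(x$edit_rates), x$edit_rates),
                    collapse = ", ")))
  cat(sprintf("  samples: %s; RNA depth %g, DNA depth %g, reads %d bp\n",
              paste(sprintf("%s x%d", names(x$groups), x$groups),
                    collapse = ", "),
              x$rna_depth, x$dna_depth, x$read_length))
  invisible(x)
}
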