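# Master list, degree recall, variation classification, annotation and
# validation FDR arithmetic.

call_row <- function(chrom, pos, ref, alt, sample = "s1",
                     status = "called") {
  tibble::tibble(sample = sample, chrom = chrom, pos = pos, ref = ref,
                 alt = alt, depth = 50L, alt_count = 20L,
                 mismatch_type = paste0(ref, ">", alt), filter_trail = "",
                 status = status, cluster_id = "c1")
}

test_that("the master list is a union keyed by site and allele", {
  calls <- dplyr::bind_rows(
    call_row("chr1", 70L, "T", "C", sample = "a"),
    call_row("chr1", 70L, "T", "C", sample = "b"),  # same site, dedup
    call_row("chr1", 20L, "C", "T", sample = "b")   # only in one sample
  )
  master <- build_master_list(calls)
  expect_equal(nrow(master), 2L)
  expect_true(all(c("chr1:20", "chr1:70") %in%
                    paste0(master$chrom, ":", master$pos)))
  expect_equal(master$canonical, c(FALSE, TRUE))
  expect_equal(nrow(build_master_list(calls[0, ])), 0L)
  conflicting <- dplyr::bind_rows(
    call_row("chr1", 70L, "T", "C", sample = "a"),
    call_row("chr1", 70L, "A", "G", sample = "b")
  )
  expect_error(build_master_list(conflicting), "conflicting reference")
})

test_that("region annotation applies CDS > UTR > intron with conflicts", {
  models <- toy_models()
  sites <- tibble::tibble(chrom = "chr1", pos = c(20L, 8L, 65L, 95L, 45L))
  ann <- annotate_region(sites, models)
  expect_equal(ann$region, c("3UTR", "CDS", "3UTR", "5UTR", "intergenic"))
  expect_equal(ann$gene_id[1:4], c("geneA", "geneA", "geneB", "geneB"))
  # an intron and a transcript disagreement
  models2 <- dplyr::bind_rows(
    models,
    tibble::tibble(chrom = "chr1", source = "toy", feature = "exon",
                   start = c(1L, 20L), end = c(10L, 30L), score = ".",
                   strand = "+", frame = ".", gene_id = "geneA",
                   transcript_id = "geneA.t2")
  )
  # pos 15 is exonic (CDS) in t1 but intronic in t2 -> conflicting
  ann2 <- annotate_region(tibble::tibble(chrom = "chr1", pos = 15L), models2)
  expect_equal(ann2$region, "conflicting")
})

test_that("codon consequences translate on the coding strand", {
  genome <- toy_genome()
  models <- toy_models()
  # plus-strand CDS reads ATG AAA CAA TGA at positions 4..15
  sites <- tibble::tibble(
    chrom = "chr1",
    pos = c(9L, 10L, 8L),
    ref = c("A", "C", "A"),
    alt = c("G", "T", "G")
  )
  cons <- codon_consequence(sites, models, genome)
  expect_equal(cons$ref_aa, c("K", "Q", "K"))
  expect_equal(cons$alt_aa, c("K", "*", "R"))
  expect_equal(cons$class, c("synonymous", "nonsense", "missense"))
  # minus-strand gene: coding A at coding position 5 sits at genomic 87,
  # reference strand T>C reads as A>G on the transcript -> K/R
  minus <- tibble::tibble(chrom = "chr1", pos = 87L, ref = "T", alt = "C")
  mcons <- codon_consequence(minus, models, genome)
  expect_equal(mcons$ref_aa, "K")
  expect_equal(mcons$alt_aa, "R")
  expect_equal(mcons$class, "missense")
  outside <- tibble::tibble(chrom = "chr1", pos = 20L, ref = "C", alt = "T")
  expect_error(codon_consequence(outside, models, genome), "not inside")
})

test_that("degree recall reproduces planted rates and simple ratios", {
  genome <- toy_genome()
  # reads over geneB 3'UTR carrying C or T at position 70 (T>C editing)
  mk <- function(n, base, sample) {
    s <- substring(as.character(genome[[1]]), 66, 75)
    substr(s, 5, 5) <- base
    make_reads(pos = rep(66L, n), seq = s, sample = sample,
               qname = sprintf("%s_%s_%d", sample, base, seq_len(n)),
               mate_pos = seq_len(n) * 10L)
  }
  reads <- dplyr::bind_rows(mk(30, "C", "a"), mk(10, "T", "a"),
                            mk(5, "C", "b"), mk(15, "T", "b"),
                            mk(2, "C", "c"), mk(1, "T", "c")) |>
    dplyr::arrange(sample, chrom, pos, qname)
  master <- tibble::tibble(chrom = "chr1", pos = 70L, ref = "T", alt = "C",
                           mismatch_type = "T>C", canonical = TRUE)
  prof <- recall_degrees(master, reads, genome)
  expect_equal(prof$degree[prof$sample == "a"], 30 / 40)
  expect_equal(prof$degree[prof$sample == "b"], 5 / 20)
  # below recall_min_depth -> missing
  expect_true(is.na(prof$degree[prof$sample == "c"]))
  # a sample with zero alt reads gives exactly 0
  zero <- recall_degrees(master, mk(10, "T", "z"), genome)
  expect_identical(zero$degree, 0)
  gm <- group_mean_degrees(prof, tibble::tibble(sample = c("a", "b", "c"),
                                                group = c("g", "g", "g")))
  expect_equal(gm$g, mean(c(0.75, 0.25)))  # missing replicate ignored
})

test_that("variation classification follows the 15%/5% thresholds", {
  means <- tibble::tibble(
    chrom = "chr1", pos = 1:5,
    control = c(0.389, 0.50, 0.50, 0.50, 0.50),
    gentamicin = c(0.664, 0.60, 0.53, 0.80, 0.70),
    neomycin = c(0.676, 0.52, 0.52, 0.20, 0.70)
  )
  cls <- classify_variation(means)
  expect_equal(cls$label,
               c("high", "intermediate", "low", "high", "high"))
  expect_equal(cls$direction, c("up", "n/a", "n/a", "discordant", "up"))
  # partition identity: up + down + discordant = high
  smry <- variation_summary(cls)
  expect_equal(smry$n_up + smry$n_down + smry$n_discordant, smry$n_high)
  # threshold monotonicity: raising high_thresh never adds a high site
  for (thr in c(0.2, 0.25, 0.3)) {
    stricter <- classify_variation(means, high_thresh = thr)
    expect_true(all(which(stricter$label == "high") %in%
                      which(cls$label == "high")))
  }
  expect_error(classify_variation(means[, 1:3], treatments = character(0)),
               "no treatment")
})

test_that("recalled group means recover planted condition rates", {
  cfg <- sim_config(seed = 17, n_chromosomes = 1L, chrom_length = 20000L,
                    n_genes = 4L, n_edit_clusters = 3L,
                    sites_per_cluster = 3L,
                    edit_rates = c(control = 0.5, gentamicin = 0.62,
                                   neomycin = 0.6),
                    n_het_snps = 4L, n_hom_snps = 4L,
                    n_homopolymer_decoys = 2L, n_repeat_decoys = 2L,
                    expr_frac_down = 0, expr_frac_up = 0, rna_depth = 400)
  sim <- simulate_editome(cfg)
  master <- sim$truth$editing |>
    dplyr::transmute(chrom, pos, ref, alt)
  prof <- recall_degrees(master, sim$rna, sim$genome)
  gm <- group_mean_degrees(prof, default_groups())
  expect_true(all(abs(gm$control - 0.5) < 0.05))
  expect_true(all(gm$control >= 0 & gm$control <= 1))
  expect_true(all(abs(gm$gentamicin - 0.62) < 0.05))
})

test_that("validation FDR arithmetic matches the worked tallies", {
  expect_equal(round(validation_fdr(169, 9), 2), 5.33)
  expect_equal(round(validation_fdr(13, 11), 1), 84.6)
  expect_equal(validation_fdr(10, 0), 0)
  expect_error(validation_fdr(0, 0), "positive")
  expect_error(validation_fdr(10, 11), "n_failed")
  expect_equal(truncated_percent(333, 762), 43)
})
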