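# Read preprocessing, pileup counting, candidate detection, filtration and
# cluster calling.

test_that("trimming removes the 5' bases and quality-filters reads", {
  fq <- tibble::tibble(
    id = c("good", "bad", "short"),
    seq = c(strrep("A", 100), strrep("C", 100), strrep("G", 5)),
    qual = c(strrep("J", 100), strrep("#", 100), strrep("J", 5))  # Q41 / Q2
  )
  expect_warning(out <- trim_and_filter_reads(fq), "shorter than trim length")
  expect_equal(out$id, "good")
  expect_equal(nchar(out$seq), 90L)
  expect_equal(attr(out, "dropped_quality"), 1L)
  expect_equal(attr(out, "dropped_short"), 1L)
  # identity case: no trimming, no cutoff
  ident <- trim_and_filter_reads(fq[1, ], trim_n = 0L, qual_cutoff = 0)
  expect_equal(ident$seq, fq$seq[1])
})

test_that("duplicate marking keeps the best read, independent of order", {
  quals <- vapply(1:5, function(i) {
    paste(rawToChar(as.raw(33L + 30L + i)) |> strrep(4), collapse = "")
  }, character(1))
  reads <- make_reads(pos = rep(10L, 5), seq = "ACGT", qual = NULL,
                      mate_pos = 60L)
  reads$qual <- quals                     # read 5 has the top quality sum
  # survivor is the same under every input permutation (brute force)
  for (perm in list(1:5, 5:1, c(3, 1, 5, 2, 4), c(2, 4, 1, 5, 3))) {
    marked <- mark_duplicates(reads[perm, ])
    expect_equal(sum(!marked$duplicate), 1L)
    expect_equal(marked$qname[!marked$duplicate], "r005")
  }
  # unique coordinates: nothing flagged
  uniq <- make_reads(pos = c(1L, 20L, 40L), seq = "ACGT")
  expect_false(any(mark_duplicates(uniq)$duplicate))
  # unsorted input is an ordering error
  expect_error(mark_duplicates(uniq[c(3, 1, 2), ]), "sorted")
})

test_that("pileup equals the naive per-read counting oracle exactly", {
  sim <- simulate_editome(sim_config(
    seed = 5, n_chromosomes = 1L, chrom_length = 20000L, n_genes = 4L,
    n_edit_clusters = 4L, sites_per_cluster = 3L, rna_depth = 4
  ))
  reads <- sim$rna[sim$rna$sample == "gentamicin_rep1", ]
  expect_lte(nrow(reads), 1000L)
  reads <- mark_duplicates(reads)
  cols <- pileup(reads, sim$genome)
  oracle <- naive_pileup_oracle(reads, sim$genome)
  got <- sum(cols$A + cols$C + cols$G + cols$T)
  expect_equal(got, sum(unlist(oracle)))
  for (i in sample.int(nrow(cols), 50)) {
    for (b in c("A", "C", "G", "T")) {
      key <- paste(cols$chrom[i], cols$pos[i], b)
      expect_equal(cols[[b]][i], oracle[[key]] %||% 0L,
                   label = paste("column", key))
    }
  }
  expect_true(all(cols$depth == cols$A + cols$C + cols$G + cols$T))
})

test_that("pileup honours mapping quality, duplicates and bounds", {
  reads <- make_reads(pos = rep(1L, 12), seq = "AAAA",
                      mapq = c(rep(30L, 9), rep(10L, 3)),
                      qname = sprintf("q%02d", 1:12))
  reads$mate_pos <- 1:12 * 100L    # all distinct fragments
  genome <- toy_genome()
  cols <- pileup(reads, genome)
  expect_equal(cols$depth[cols$pos == 1], 9L)
  all30 <- pileup(make_reads(pos = rep(1L, 12), seq = "GGCA",
                             qname = sprintf("u%02d", 1:12),
                             mate_pos = 1:12), genome)
  expect_equal(all30$depth[all30$pos == 1], 12L)
  expect_equal(all30$G[all30$pos == 1], 12L)
  # zero surviving coverage emits no column
  low <- pileup(make_reads(pos = 1L, seq = "AAAA", mapq = 5L), genome)
  expect_equal(nrow(low), 0L)
  expect_error(pileup(make_reads(pos = 119L, seq = "AAAA"), genome),
               "beyond chromosome end")
})

test_that("candidate thresholds are inclusive and tie-breaks deterministic", {
  col <- function(depth, alt_count, ref = "A", alt = "G") {
    counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    counts[ref] <- depth - alt_count
    counts[alt] <- alt_count
    tibble::tibble(chrom = "chr1", pos = 100L, ref = ref, depth = depth,
                   A = counts["A"], C = counts["C"], G = counts["G"],
                   T = counts["T"], mean_mapq = 60)
  }
  expect_equal(nrow(detect_candidates(col(10L, 2L))), 1L)     # both boundary
  expect_equal(nrow(detect_candidates(col(9L, 5L))), 0L)      # low coverage
  expect_equal(nrow(detect_candidates(col(100L, 1L))), 0L)    # low support
  expect_equal(nrow(detect_candidates(col(200L, 2L))), 0L)    # low frequency
  # tie between C and T alt counts resolves to C (A < C < G < T)
  tie <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", depth = 20L,
                        A = 10L, C = 5L, G = 0L, T = 5L, mean_mapq = 60)
  got <- detect_candidates(tie)
  expect_equal(got$alt, "C")
  expect_equal(got$mismatch_type, "A>C")
})

test_that("DNA variant calling separates het, hom and noise", {
  col <- function(pos, depth, alt_count) {
    tibble::tibble(chrom = "chr1", pos = pos, ref = "A", depth = depth,
                   A = depth - alt_count, C = 0L, G = alt_count, T = 0L,
                   mean_mapq = 60)
  }
  vars <- call_dna_variants(dplyr::bind_rows(
    col(1L, 30L, 30L),    # fraction 1.0 -> hom
    col(2L, 30L, 15L),    # fraction 0.5 -> het
    col(3L, 100L, 2L)     # fraction 0.02 -> sequencing noise, no call
  ))
  expect_equal(vars$pos, c(1L, 2L))
  expect_equal(vars$zygosity, c("hom", "het"))
})

test_that("the filtration cascade annotates trails and is order-insensitive", {
  genome <- toy_genome()
  models <- toy_models()
  cands <- tibble::tibble(
    sample = "s1",
    chrom = "chr1",
    pos = c(20L, 25L, 45L, 65L, 95L, 70L),
    ref = c("C", "C", "G", "T", "A", "T"),
    alt = c("T", "T", "A", "C", "G", "C"),
    depth = 50L, alt_count = 20L,
    mismatch_type = c("C>T", "C>T", "G>A", "T>C", "A>G", "T>C")
  )
  dna_vars <- tibble::tibble(chrom = "chr1", pos = 20L, ref = "C", alt = "T",
                             zygosity = "het")
  snps <- tibble::tibble(chrom = "chr1", pos = 25L, ref = "C", alt = "T",
                         zygosity = "het")
  repeats <- tibble::tibble(chrom = "chr1", start = 64L, end = 66L,
                            kind = "simple_repeat")
  out <- filtration_cascade(cands, dna_vars, snps, models, genome, repeats)
  trail <- setNames(out$filter_trail, out$pos)
  expect_match(trail[["20"]], "dna_variant")
  expect_match(trail[["25"]], "known_snp")
  expect_match(trail[["45"]], "intergenic")   # between the two genes
  expect_match(trail[["65"]], "simple_repeat")
  expect_match(trail[["95"]], "homopolymer")  # inside the AAAAAAAAA run
  expect_equal(trail[["70"]], "")             # clean 3'UTR site survives
  expect_equal(out$status[out$pos == 70L], "survivor")

  # order-insensitivity: survivors identical for any filter application order
  # (each filter is a pure positional predicate; emulate reordering by
  # applying single-resource cascades in both orders)
  only_dna <- filtration_cascade(cands, dna_vars, snps[0, ], models, genome,
                                 repeats[0, ])
  only_rep <- filtration_cascade(cands, dna_vars[0, ], snps[0, ], models,
                                 genome, repeats)
  seq1 <- intersect(only_dna$pos[only_dna$filter_trail == ""],
                    only_rep$pos[only_rep$filter_trail == ""])
  seq2 <- intersect(only_rep$pos[only_rep$filter_trail == ""],
                    only_dna$pos[only_dna$filter_trail == ""])
  both <- filtration_cascade(cands, dna_vars, snps[0, ], models, genome,
                             repeats)
  expect_setequal(seq1, seq2)
  expect_setequal(both$pos[both$filter_trail == ""],
                  intersect(seq1, both$pos))
})

test_that("cluster calling matches a single-linkage oracle and honours type", {
  surv <- function(pos, type, frac = 0.5, depth = 100L) {
    tibble::tibble(
      sample = "s1", chrom = "chr1", pos = pos,
      ref = substr(type, 1, 1), alt = substr(type, 3, 3),
      depth = depth, alt_count = as.integer(round(frac * depth)),
      mismatch_type = type, filter_trail = "", status = "survivor",
      cluster_id = NA_character_
    )
  }
  # 100, 150, 260: gaps 50 and 110, both <= 200 -> one cluster, all called
  trio <- cluster_call(surv(c(100L, 150L, 260L), "A>G"))
  expect_true(all(trio$status == "called"))
  expect_equal(length(unique(trio$cluster_id)), 1L)
  expect_equal(unique(single_linkage_oracle(c(100, 150, 260), 200)), 1L)

  # different mismatch types never co-cluster
  mixed <- cluster_call(dplyr::bind_rows(surv(100L, "A>G", frac = 0.05),
                                         surv(110L, "C>T", frac = 0.05)))
  expect_true(all(mixed$status == "filtered"))
  expect_true(all(mixed$filter_trail == "no_cluster_support"))

  # lone site below the rescue fraction is filtered; above it, called
  expect_equal(cluster_call(surv(500L, "A>G", frac = 0.05))$status, "filtered")
  expect_equal(cluster_call(surv(500L, "A>G", frac = 0.25))$status, "called")

  # randomised agreement with the brute-force single-linkage oracle
  # (alt fraction kept below the lone-site rescue so cluster support decides)
  withr::with_seed(99, {
    for (rep in 1:5) {
      pos <- sort(sample.int(5000L, 40L))
      got <- cluster_call(surv(pos, "A>G", frac = 0.05), window_bp = 150L)
      oracle <- single_linkage_oracle(pos, 150)
      sizes <- as.vector(table(oracle)[oracle])
      expect_equal(got$status[order(got$pos)] == "called", sizes >= 2)
    }
  })
})

test_that("raising thresholds never adds a called site", {
  sim <- simulate_editome(sim_config(seed = 13, n_chromosomes = 1L,
                                     chrom_length = 20000L, n_genes = 4L,
                                     n_edit_clusters = 4L,
                                     sites_per_cluster = 3L, rna_depth = 40))
  dna_vars <- call_dna_variants(pileup(mark_duplicates(sim$dna), sim$genome))
  r1 <- sim$rna[sim$rna$sample == "control_rep1", ]
  base <- call_editing_sites(r1, sim$genome, sim$models, sim$repeats,
                             sim$truth$snps, dna_vars)
  called_base <- paste(base$chrom[base$status == "called"],
                       base$pos[base$status == "called"])
  for (args in list(list(min_depth = 20L), list(min_alt = 5L),
                    list(min_depth = 15L, min_alt = 4L))) {
    stricter <- do.call(call_editing_sites, c(
      list(r1, sim$genome, sim$models, sim$repeats, sim$truth$snps, dna_vars),
      args
    ))
    called_strict <- paste(stricter$chrom[stricter$status == "called"],
                           stricter$pos[stricter$status == "called"])
    expect_true(all(called_strict %in% called_base))
  }
})

test_that("mismatch spectrum fractions are exact", {
  mk <- function(n, type) {
    tibble::tibble(sample = "s", chrom = "chr1", pos = seq_len(n),
                   ref = substr(type, 1, 1), alt = substr(type, 3, 3),
                   depth = 10L, alt_count = 5L, mismatch_type = type,
                   filter_trail = "", status = "called", cluster_id = "c")
  }
  spec <- mismatch_spectrum(dplyr::bind_rows(mk(80, "A>G"), mk(20, "C>T")))
  expect_equal(spec$canonical_fraction, 0.8)
  all_tc <- mismatch_spectrum(mk(10, "T>C"))
  expect_equal(all_tc$canonical_fraction, 1.0)
  mixed <- mismatch_spectrum(dplyr::bind_rows(
    mk(10, "G>A"), mk(10, "C>T"), mk(5, "A>C")
  ))
  expect_equal(mixed$noncanonical_ga_ct_share, 0.8)
  empty <- mismatch_spectrum(mk(0, "A>G"))
  expect_true(is.na(empty$canonical_fraction))
})

test_that("cluster characterization matches brute-force grouping", {
  mk <- function(pos) {
    tibble::tibble(sample = "s", chrom = "chr1", pos = pos, ref = "A",
                   alt = "G", depth = 10L, alt_count = 5L,
                   mismatch_type = "A>G", filter_trail = "",
                   status = "called", cluster_id = "c")
  }
  expect_equal(cluster_characterization(mk(c(100L, 150L, 190L))), 1.0)
  # 100,150,400: max chain at gap<=100 has 2 members -> nothing reaches 3
  expect_equal(cluster_characterization(mk(c(100L, 150L, 400L))), 0.0)
  expect_equal(cluster_characterization(mk(500L)), 0.0)
  # randomised agreement with an explicit chain-grouping oracle
  withr::with_seed(42, {
    for (rep in 1:5) {
      pos <- sort(sample.int(3000L, 25L))
      grp <- cumsum(c(TRUE, diff(pos) > 100))
      frac_oracle <- mean((table(grp)[grp]) >= 3)
      expect_equal(cluster_characterization(mk(pos)), frac_oracle)
    }
  })
})
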