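# Fragment counting, FPKM, fold-change calls, normalization, correlation.

test_that("fragments count once per pair and skip ambiguous positions", {
  models <- toy_models()
  reads <- dplyr::bind_rows(
    make_reads(pos = 5L, seq = "ACGT", qname = "frag1"),
    make_reads(pos = 20L, seq = "ACGT", qname = "frag1"),  # mate, same pair
    make_reads(pos = 65L, seq = "ACGT", qname = "frag2"),
    make_reads(pos = 45L, seq = "ACGT", qname = "frag3")   # intergenic
  )
  counts <- count_fragments(reads, models)
  expect_equal(counts$fragments[counts$gene_id == "geneA"], 1L)
  expect_equal(counts$fragments[counts$gene_id == "geneB"], 1L)
  una <- attr(counts, "unassigned")
  expect_equal(una$unassigned, 1L)
  # an overlapping second gene makes a position ambiguous
  models2 <- dplyr::bind_rows(models, tibble::tibble(
    chrom = "chr1", source = "toy", feature = "exon", start = 1L, end = 30L,
    score = ".", strand = "+", frame = ".", gene_id = "geneC",
    transcript_id = "geneC.t1"
  ))
  counts2 <- count_fragments(reads, models2)
  expect_equal(attr(counts2, "unassigned")$ambiguous, 1L)
  expect_equal(counts2$fragments[counts2$gene_id == "geneA"], 0L)
})

test_that("FPKM follows the formula and its scaling properties", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"), sample = "s1",
                           fragments = c(100L, 0L))
  lengths <- tibble::tibble(gene_id = c("g1", "g2"), length = c(1000L, 500L))
  totals <- tibble::tibble(sample = "s1", total = 1e6)
  fpkm <- compute_fpkm(counts, lengths, totals)
  expect_equal(fpkm$fpkm[fpkm$gene_id == "g1"], 100)
  expect_equal(fpkm$fpkm[fpkm$gene_id == "g2"], 0)
  # doubling total fragments halves every FPKM
  half <- compute_fpkm(counts, lengths,
                       tibble::tibble(sample = "s1", total = 2e6))
  expect_equal(half$fpkm, fpkm$fpkm / 2)
  # multiplying fragments and totals by the same constant is invariant
  scaled <- compute_fpkm(dplyr::mutate(counts, fragments = fragments * 7L),
                         lengths,
                         tibble::tibble(sample = "s1", total = 7e6))
  expect_equal(scaled$fpkm, fpkm$fpkm)
  expect_error(compute_fpkm(counts, dplyr::mutate(lengths, length = 0L),
                            totals), "positive")
})

test_that("printed FPKM pairs reproduce their log2 fold changes to 2 dp", {
  tbl <- example_deafness_expression()
  # high-expression rows are robust to the table's rounding of inputs
  hi <- tbl[tbl$control_fpkm > 100, ]
  expect_gte(nrow(hi), 4L)
  expect_equal(round(log2(hi$gentamicin_fpkm / hi$control_fpkm), 2),
               hi$log2fc_gentamicin, tolerance = 1e-12)
  expect_equal(round(log2(hi$neomycin_fpkm / hi$control_fpkm), 2),
               hi$log2fc_neomycin, tolerance = 1e-12)
})

test_that("fold-change classification needs both arms beyond the fold", {
  fpkm <- tidyr::expand_grid(
    gene_id = c("down_both", "down_one", "flat", "up_both"),
    sample = c("c1", "c2", "g1", "n1")
  ) |>
    dplyr::mutate(fpkm = dplyr::case_when(
      gene_id == "down_both" & startsWith(sample, "c") ~ 30,
      gene_id == "down_both" ~ 10,
      gene_id == "down_one" & sample == "g1" ~ 5,
      gene_id == "down_one" ~ 20,
      gene_id == "up_both" & startsWith(sample, "c") ~ 10,
      gene_id == "up_both" ~ 40,
      TRUE ~ 10
    ))
  groups <- tibble::tibble(sample = c("c1", "c2", "g1", "n1"),
                           group = c("control", "control", "gentamicin",
                                     "neomycin"))
  cls <- fold_change_classify(fpkm, groups)
  got <- setNames(cls$regulation, cls$gene_id)
  expect_equal(got[["down_both"]], "down")
  expect_equal(got[["down_one"]], "none")
  expect_equal(got[["flat"]], "none")
  expect_equal(got[["up_both"]], "up")
})

test_that("normalization rows are zero-mean and constants map to zero", {
  fpkm <- tidyr::expand_grid(gene_id = c("g1", "g2"),
                             sample = c("s1", "s2", "s3")) |>
    dplyr::mutate(fpkm = c(5, 5, 5, 1, 10, 100))
  norm <- normalize_expression(fpkm)
  m <- as.matrix(norm[, -1])
  expect_equal(unname(rowMeans(m)), c(0, 0))
  expect_equal(unname(m[1, ]), c(0, 0, 0))    # constant gene
  zeros <- normalize_expression(
    tibble::tibble(gene_id = "g", sample = c("a", "b", "c"), fpkm = 0)
  )
  expect_equal(unname(as.matrix(zeros[, -1])[1, ]), c(0, 0, 0))
})

test_that("Pearson correlation matches the closed form and handles edge cases", {
  classes <- tibble::tibble(
    chrom = "chr1", pos = 1:10, gene_id = sprintf("g%d", 1:10),
    label = "high",
    delta_gentamicin = c(0.21, -0.3, 0.45, 0.18, -0.2, 0.3, 0.5, -0.4,
                         0.25, 0.33)
  )
  expr <- tibble::tibble(
    gene_id = sprintf("g%d", 1:10),
    log2fc_gentamicin = c(0.5, -0.7, 1.0, 0.2, -0.1, 0.9, 1.4, -1.2,
                          0.4, 0.8)
  )
  res <- editing_expression_correlation(classes, expr, "gentamicin")
  x <- classes$delta_gentamicin
  y <- expr$log2fc_gentamicin
  r_closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_closed, tolerance = 1e-12)
  # Fisher-z interval around the estimate
  expect_equal(res$ci_low, tanh(atanh(r_closed) - 1.96 / sqrt(7)))
  expect_equal(res$ci_high, tanh(atanh(r_closed) + 1.96 / sqrt(7)))
  # independent check of the point estimate/p against cor.test
  ct <- cor.test(x, y)
  expect_equal(res$p_value, ct$p.value)
  # y = 2x exactly -> r = 1
  expr2 <- dplyr::mutate(expr, log2fc_gentamicin = 2 * x)
  expect_equal(editing_expression_correlation(classes, expr2,
                                              "gentamicin")$r, 1)
  # constant x is degenerate
  const <- dplyr::mutate(classes, delta_gentamicin = 0.2)
  expect_error(editing_expression_correlation(const, expr, "gentamicin"),
               "zero variance")
  expect_error(editing_expression_correlation(classes[1:2, ], expr,
                                              "gentamicin"),
               "fewer than 3")
  # broom-style accessors
  td <- tidy(res)
  expect_equal(td$estimate, res$r)
  expect_equal(glance(res)$n, 10L)
})
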