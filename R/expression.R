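# Gene-expression quantification (FPKM), fold-change regulation calls,
# normalization, and the editing-expression correlation.

#' Count fragments per gene and sample
#'
#' A fragment is all reads sharing a read name within a sample; it is
#' counted once, for the unique gene whose exons contain its leftmost
#' mapped position. Fragments touching exons of more than one gene are
#' dropped as ambiguous; fragments outside every exon are unassigned. Both
#' tallies are reported in the `unassigned` attribute.
#'
#' @param reads aligned-read tibble over one or more samples.
#' @param models gene-model tibble.
#' @return long tibble `gene_id`, `sample`, `fragments` (all genes x all
#'   samples, zero-filled); attribute `unassigned` is a per-sample tibble of
#'   `ambiguous` and `unassigned` fragment counts.
#' @export
count_fragments <- function(reads, models) {
  exons <- models[models$feature == "exon", c("chrom", "start", "end",
                                              "gene_id")]
  frags <- reads |>
    dplyr::group_by(.data$sample, .data$qname) |>
    dplyr::summarise(chrom = .data$chrom[1], pos = min(.data$pos),
                     .groups = "drop")
  hit_gene <- rep(NA_character_, nrow(frags))
  multi <- rep(FALSE, nrow(frags))
  for (ch in unique(frags$chrom)) {
    fi <- which(frags$chrom == ch)
    ex <- exons[exons$chrom == ch, ]
    for (k in seq_len(nrow(ex))) {
      inside <- fi[frags$pos[fi] >= ex$start[k] & frags$pos[fi] <= ex$end[k]]
      if (!length(inside)) next
      g <- ex$gene_id[k]
      prev <- hit_gene[inside]
      multi[inside[!is.na(prev) & prev != g]] <- TRUE
      hit_gene[inside[is.na(prev)]] <- g
    }
  }
  frags$gene_id <- hit_gene
  frags$ambiguous <- multi
  unassigned <- frags |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(ambiguous = sum(.data$ambiguous),
                     unassigned = sum(is.na(.data$gene_id)),
                     .groups = "drop")
  counts <- frags |>
    dplyr::filter(!is.na(.data$gene_id), !.data$ambiguous) |>
    dplyr::count(.data$gene_id, .data$sample, name = "fragments")
  full <- tidyr::expand_grid(gene_id = sort(unique(exons$gene_id)),
                             sample = sort(unique(reads$sample))) |>
    dplyr::left_join(counts, by = c("gene_id", "sample")) |>
    dplyr::mutate(fragments = dplyr::coalesce(.data$fragments, 0L))
  attr(full, "unassigned") <- unassigned
  full
}

#' Transcript lengths from gene models
#'
#' @param models gene-model tibble.
#' @return tibble `gene_id`, `length` (sum of exon lengths of the gene's
#'   transcript).
#' @export
transcript_lengths <- function(models) {
  models |>
    dplyr::filter(.data$feature == "exon") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(length = sum(.data$end - .data$start + 1L),
                     .groups = "drop")
}

#' Compute FPKM
#'
#' FPKM = fragments x 10^3 x 10^6 / (transcript length x total fragments),
#' i.e. fragments per kilobase of transcript per million mapped fragments.
#'
#' @param counts long tibble from [count_fragments()].
#' @param lengths tibble `gene_id`, `length` (bases), e.g.
#'   [transcript_lengths()].
#' @param totals optional tibble `sample`, `total`; defaults to the
#'   per-sample sum of assigned fragments.
#' @return `counts` with `length`, `total` and `fpkm` columns added.
#' @export
compute_fpkm <- function(counts, lengths, totals = NULL) {
  if (any(lengths$length <= 0)) abort("transcript lengths must be positive")
  totals <- totals %||% (counts |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(total = sum(.data$fragments), .groups = "drop"))
  if (any(totals$total <= 0)) abort("total fragment counts must be positive")
  counts |>
    dplyr::inner_join(lengths, by = "gene_id") |>
    dplyr::inner_join(totals, by = "sample") |>
    dplyr::mutate(fpkm = .data$fragments * 1e3 * 1e6 /
                    (.data$length * .data$total))
}

#' Classify expression regulation from fold changes
#'
#' Averages FPKM over each group's replicates, computes
#' `log2(treatment mean / control mean)` per treatment, and labels a gene
#' `down` when every treatment's fold change is at most `1/fold`, `up` when
#' every one is at least `fold`, `none` otherwise. No pseudocount is used:
#' genes with control mean 0 get infinite fold changes (and are excluded
#' from downstream correlation); genes with zero expression everywhere are
#' dropped and counted in the `dropped_zero` attribute.
#'
#' @param fpkm tibble from [compute_fpkm()] (or any tibble with `gene_id`,
#'   `sample`, `fpkm`).
#' @param groups tibble mapping `sample` to `group`.
#' @param control control group name (default `"control"`).
#' @param fold fold-change threshold (default 1.5).
#' @return tibble per gene: `fpkm_<group>` group means, `log2fc_<treatment>`
#'   and `regulation`.
#' @export
fold_change_classify <- function(fpkm, groups, control = "control",
                                 fold = 1.5) {
  gm <- fpkm |>
    dplyr::inner_join(groups, by = "sample") |>
    dplyr::group_by(.data$gene_id, .data$group) |>
    dplyr::summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean_fpkm")
  if (!control %in% names(gm)) abort(sprintf("no '%s' group", control))
  treatments <- setdiff(names(gm), c("gene_id", control))
  if (!length(treatments)) abort("no treatment groups present")
  all_zero <- gm[[control]] == 0 &
    rowSums(as.matrix(gm[treatments]) != 0) == 0
  dropped <- sum(all_zero)
  gm <- gm[!all_zero, ]
  out <- tibble(gene_id = gm$gene_id)
  out[[paste0("fpkm_", control)]] <- gm[[control]]
  fc <- matrix(NA_real_, nrow(gm), length(treatments),
               dimnames = list(NULL, treatments))
  for (t in treatments) {
    out[[paste0("fpkm_", t)]] <- gm[[t]]
    fc[, t] <- log2(gm[[t]] / gm[[control]])
    out[[paste0("log2fc_", t)]] <- fc[, t]
  }
  thr <- log2(fold)
  out$regulation <- dplyr::case_when(
    apply(fc >= thr, 1, all) ~ "up",
    apply(fc <= -thr, 1, all) ~ "down",
    TRUE ~ "none"
  )
  attr(out, "dropped_zero") <- dropped
  out
}

#' Log-transform and zero-mean normalize an expression table
#'
#' Per gene: `log2(fpkm + pseudocount)`, then the gene's mean across samples
#' is subtracted, so every output row has mean zero.
#'
#' @param fpkm long tibble with `gene_id`, `sample`, `fpkm`.
#' @param pseudocount added before the log (default 1).
#' @return wide tibble: `gene_id` plus one centred column per sample.
#' @export
normalize_expression <- function(fpkm, pseudocount = 1) {
  fpkm |>
    dplyr::mutate(logv = log2(.data$fpkm + pseudocount)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(logv = .data$logv - mean(.data$logv)) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "sample", "logv") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "logv")
}

#' Correlate editing-degree changes with expression changes
#'
#' For every high-variation editing site whose gene has a finite expression
#' fold change, pairs the site's editing-degree change (treatment minus
#' control group mean) with the gene's log2 expression fold change for the
#' same treatment, and computes the Pearson correlation with a Fisher-z 95%
#' confidence interval and a two-sided p-value.
#'
#' @param classes output of [classify_variation()] carrying `gene_id`.
#' @param expr output of [fold_change_classify()].
#' @param treatment treatment group to correlate.
#' @param label_filter which variation labels enter the correlation
#'   (default `"high"`, the red-dot cutoff of 15 percentage points).
#' @return an `editing_correlation` object; see [tidy.editing_correlation()].
#' @export
editing_expression_correlation <- function(classes, expr, treatment,
                                           label_filter = "high") {
  dcol <- paste0("delta_", treatment)
  fcol <- paste0("log2fc_", treatment)
  if (!dcol %in% names(classes)) abort(sprintf("no column '%s'", dcol))
  if (!fcol %in% names(expr)) abort(sprintf("no column '%s'", fcol))
  pts <- classes |>
    dplyr::filter(.data$label %in% label_filter) |>
    dplyr::inner_join(expr[, c("gene_id", fcol)], by = "gene_id") |>
    dplyr::transmute(.data$gene_id, x = .data[[dcol]], y = .data[[fcol]]) |>
    dplyr::filter(is.finite(.data$x), is.finite(.data$y))
  n <- nrow(pts)
  if (n < 3L) abort("fewer than 3 usable sites; cannot correlate")
  if (stats::sd(pts$x) == 0 || stats::sd(pts$y) == 0) {
    abort("degenerate input: zero variance in editing deltas or fold changes")
  }
  ct <- stats::cor.test(pts$x, pts$y, method = "pearson")
  r <- unname(ct$estimate)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  structure(
    list(n = n, r = r, ci_low = tanh(z - 1.96 * se),
         ci_high = tanh(z + 1.96 * se), p_value = ct$p.value,
         treatment = treatment, data = pts),
    class = "editing_correlation"
  )
}

#' @export
print.editing_correlation <- function(x, ...) {
  cat(sprintf(
    "<editing_correlation> %s: r = %.3f (95%% CI %.3f-%.3f), p = %.4g, n = %d\n",
    x$treatment, x$r, x$ci_low, x$ci_high, x$p_value, x$n
  ))
  invisible(x)
}

#' Tidy an editing-expression correlation
#'
#' @param x an `editing_correlation`.
#' @param ... unused.
#' @return one-row tibble with `estimate`, `conf.low`, `conf.high`,
#'   `p.value`, `method`.
#' @export
tidy.editing_correlation <- function(x, ...) {
  tibble(estimate = x$r, conf.low = x$ci_low, conf.high = x$ci_high,
         p.value = x$p_value, method = "Pearson (Fisher z CI)")
}

#' Glance at an editing-expression correlation
#'
#' @param x an `editing_correlation`.
#' @param ... unused.
#' @return one-row tibble with `n`, `r`, `p.value`, `treatment`.
#' @export
glance.editing_correlation <- function(x, ...) {
  tibble(n = x$n, r = x$r, p.value = x$p_value, treatment = x$treatment)
}

#' Scatter plot of editing change versus expression change
#'
#' @param object an `editing_correlation`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.editing_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = "#D62839", alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30", linewidth = 0.5) +
    ggplot2::labs(
      x = sprintf("editing degree change (%s - control)", object$treatment),
      y = sprintf("log2 fold change (%s / control)", object$treatment),
      subtitle = sprintf("r = %.2f (95%% CI %.2f to %.2f), p = %.3g, n = %d",
                         object$r, object$ci_low, object$ci_high,
                         object$p_value, object$n)
    ) +
    ggplot2::theme_minimal()
}
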