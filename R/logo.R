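# Two-sample sequence-logo statistics: flanking-sequence composition
# contrasted between two sets of editing sites, one Fisher test per
# (position, nucleotide) cell.

#' Construct a flank set from sequences
#'
#' @param sequences character vector of equal, odd-length nucleotide strings
#'   centred on the edited base.
#' @return a `flank_set`: tibble with column `seq` and a `window` attribute
#'   (half-width W).
#' @export
flank_set <- function(sequences) {
  len <- unique(nchar(sequences))
  if (length(len) != 1L || len %% 2L == 0L) {
    abort("flank sequences must share one odd length (2W + 1)")
  }
  structure(tibble(seq = toupper(sequences)),
            window = (len - 1L) %/% 2L,
            class = c("flank_set", class(tibble())))
}

#' Extract flanking sequences around editing sites
#'
#' Slices `2W + 1` reference bases centred on each site. Sites in
#' minus-strand genes are reverse-complemented so that the centre reads as
#' the canonical edited base (A of an A>G event) and "downstream" means 3'
#' of the edited adenosine. Sites within `W` of a contig edge, or with no
#' resolvable gene strand, are dropped and counted in attributes
#' `dropped_edge` / `dropped_strandless`.
#'
#' @param sites tibble with `chrom`, `pos`, and either a `strand` column or
#'   a `gene_id` resolvable through `models`.
#' @param genome [Biostrings::DNAStringSet] reference.
#' @param models gene-model tibble used to look up gene strands when
#'   `sites$strand` is absent.
#' @param W flank half-width in bases (default 10).
#' @return a [flank_set()].
#' @export
extract_flanks <- function(sites, genome, models = NULL, W = 10L) {
  strand <- sites[["strand"]]
  if (is.null(strand)) {
    if (is.null(models)) abort("need sites$strand or gene models")
    spans <- transcript_spans(models)
    strand <- vapply(seq_len(nrow(sites)), function(i) {
      hit <- spans[spans$chrom == sites$chrom[i] &
                     spans$start <= sites$pos[i] &
                     spans$end >= sites$pos[i], ]
      if (nrow(hit)) hit$strand[1] else NA_character_
    }, character(1))
  }
  strandless <- is.na(strand)
  if (any(strandless)) {
    warn(sprintf("%d site(s) with no gene strand dropped", sum(strandless)))
  }
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  at_edge <- unname(sites$pos - W < 1L | sites$pos + W > lens[sites$chrom])
  keep <- which(!strandless & !at_edge)
  seqs <- vapply(keep, function(i) {
    s <- genome_slice(genome, sites$chrom[i], sites$pos[i] - W,
                      sites$pos[i] + W)
    if (strand[i] == "-") revcomp(s) else s
  }, character(1), USE.NAMES = FALSE)
  fs <- if (length(seqs)) flank_set(seqs) else
    structure(tibble(seq = character(0)), window = as.integer(W),
              class = c("flank_set", class(tibble())))
  attr(fs, "dropped_edge") <- sum(at_edge, na.rm = TRUE)
  attr(fs, "dropped_strandless") <- sum(strandless)
  fs
}

flank_matrix <- function(fs) {
  matrix(unlist(strsplit(fs$seq, "", fixed = TRUE), use.names = FALSE),
         nrow = nrow(fs), byrow = TRUE)
}

#' Two-sample sequence logo statistics
#'
#' For every flanking position (-W..W, the centre excluded — it is the
#' edited base by construction) and nucleotide, tests whether the
#' nucleotide's frequency differs between the two sets, by default with
#' Fisher's exact test on the 2x2 count table. `diff > 0` marks enrichment
#' in set 1, `diff < 0` depletion.
#'
#' @param set1,set2 [flank_set()]s with the same window.
#' @param alpha significance threshold on the (optionally corrected)
#'   p-value (default 0.05).
#' @param test `"fisher"` (default) or `"binomial"` (two-sided two-proportion
#'   test).
#' @param correction `"none"` (default, mirroring a raw p-value logo) or
#'   `"bonferroni"`.
#' @return a `two_sample_logo` tibble with columns `position` (relative to
#'   the edited base), `nucleotide`, `freq1`, `freq2`, `diff`, `p_value`,
#'   `significant`; attributes `alpha`, `n1`, `n2`, `window`.
#' @export
two_sample_logo <- function(set1, set2, alpha = 0.05,
                            test = c("fisher", "binomial"),
                            correction = c("none", "bonferroni")) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  W <- attr(set1, "window")
  if (!identical(W, attr(set2, "window"))) {
    abort("flank sets have different windows")
  }
  n1 <- nrow(set1); n2 <- nrow(set2)
  if (n1 == 0L || n2 == 0L) abort("both flank sets must be non-empty")
  if (min(n1, n2) < 5L) {
    warn("fewer than 5 sequences in a set; logo statistics are low-powered")
  }
  m1 <- flank_matrix(set1)
  m2 <- flank_matrix(set2)
  positions <- setdiff(seq.int(-W, W), 0L)
  grid <- tidyr::expand_grid(position = positions, nucleotide = BASES)
  res <- purrr::pmap_dfr(grid, function(position, nucleotide) {
    col <- W + 1L + position
    c1 <- sum(m1[, col] == nucleotide)
    c2 <- sum(m2[, col] == nucleotide)
    p <- if (test == "fisher") {
      stats::fisher.test(matrix(c(c1, n1 - c1, c2, n2 - c2), nrow = 2L))$p.value
    } else {
      suppressWarnings(
        stats::prop.test(c(c1, c2), c(n1, n2), correct = FALSE)$p.value
      )
    }
    tibble(position = position, nucleotide = nucleotide,
           freq1 = c1 / n1, freq2 = c2 / n2,
           diff = c1 / n1 - c2 / n2, p_value = p)
  })
  if (correction == "bonferroni") {
    res$p_value <- pmin(1, res$p_value * nrow(res))
  }
  res$significant <- res$p_value < alpha
  structure(res, alpha = alpha, n1 = n1, n2 = n2, window = W,
            low_power = min(n1, n2) < 5L,
            class = c("two_sample_logo", class(tibble())))
}

#' @export
print.two_sample_logo <- function(x, ...) {
  cat(sprintf(
    "<two_sample_logo> W=%d, n1=%d, n2=%d, alpha=%g; %d significant cell(s)\n",
    attr(x, "window"), attr(x, "n1"), attr(x, "n2"), attr(x, "alpha"),
    sum(x$significant)
  ))
  NextMethod()
}

#' Plot a two-sample logo
#'
#' Significant cells only: letters above the axis are enriched in set 1,
#' letters below are depleted, letter height is the frequency difference.
#'
#' @param object a `two_sample_logo`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.two_sample_logo <- function(object, ...) {
  sig <- dplyr::filter(as_tibble(object), .data$significant)
  ggplot2::ggplot(sig, ggplot2::aes(x = .data$position, y = .data$diff,
                                    label = .data$nucleotide,
                                    colour = .data$nucleotide)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_text(fontface = "bold", size = 5, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(A = "#109648", C = "#255C99",
                                            G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(x = "position relative to edited base",
                  y = "frequency difference (set1 - set2)") +
    ggplot2::theme_minimal()
}
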