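# Additional result plots.

#' Bar plot of the mismatch-type spectrum
#'
#' @param spectrum output of [mismatch_spectrum()].
#' @return a ggplot object.
#' @export
plot_mismatch_spectrum <- function(spectrum) {
  spec <- spectrum$spectrum
  ggplot2::ggplot(spec, ggplot2::aes(
    x = stats::reorder(.data$mismatch_type, -.data$n),
    y = .data$fraction, fill = .data$canonical
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#255C99",
                                          `FALSE` = "grey65"),
                               labels = c(`TRUE` = "canonical (A>G/T>C)",
                                          `FALSE` = "non-canonical"),
                               name = NULL) +
    ggplot2::labs(x = "mismatch type", y = "fraction of called sites") +
    ggplot2::theme_minimal()
}

#' Editing-degree change along the genome
#'
#' One point per site: position on the x axis, the treatment-minus-control
#' change in group-mean editing degree on the y axis, faceted by
#' chromosome.
#'
#' @param classes output of [classify_variation()].
#' @param treatment treatment whose delta column is plotted.
#' @return a ggplot object.
#' @export
plot_editing_deltas <- function(classes, treatment) {
  dcol <- paste0("delta_", treatment)
  if (!dcol %in% names(classes)) abort(sprintf("no column '%s'", dcol))
  ggplot2::ggplot(classes, ggplot2::aes(
    x = .data$pos, y = .data[[dcol]],
    colour = .data[[dcol]] > 0
  )) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.7, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D62839",
                                            `FALSE` = "#255C99")) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position", y = sprintf("editing change (%s - control)",
                                              treatment)) +
    ggplot2::theme_minimal()
}
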