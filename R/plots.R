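#' Plot the saturation-slope distribution
#'
#' Histogram of per-gene regression slopes, filled by retention status.
#' Least-saturated genes sit at the most negative slopes.
#'
#' @param records Saturation records (after [retain_by_slope()]).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_saturation <- function(records, bins = 30) {
  records <- dplyr::filter(records, !is.na(.data$slope))
  ggplot2::ggplot(records, ggplot2::aes(
    x = .data$slope, fill = .data$retained
  )) +
    ggplot2::geom_histogram(bins = bins, colour = "grey30") +
    ggplot2::labs(
      x = "saturation slope (identity % per corrected distance)",
      y = "genes", fill = "retained"
    ) +
    ggplot2::theme_minimal()
}

#' Oxford dot plot of pairwise macrosynteny
#'
#' One point per one-to-one ortholog, faceted by chromosome pair; blocks
#' of conserved macrosynteny appear as dense panels.
#'
#' @param dotplot_data Output of [synteny_dotplot_data()].
#' @return A ggplot object.
#' @export
plot_synteny_dotplot <- function(dotplot_data) {
  ggplot2::ggplot(dotplot_data, ggplot2::aes(
    x = .data$pos_a, y = .data$pos_b
  )) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$chr_b),
      cols = ggplot2::vars(.data$chr_a),
      scales = "free", switch = "both"
    ) +
    ggplot2::labs(x = "genome A position", y = "genome B position") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text = ggplot2::element_blank(),
      panel.spacing = ggplot2::unit(0.5, "pt"),
      strip.text = ggplot2::element_text(size = 5)
    )
}

#' @describeIn concatenate_alignments `autoplot()` shows per-taxon
#'   occupancy of the supermatrix.
#' @method autoplot supermatrix
#' @param object A `supermatrix`.
#' @export
autoplot.supermatrix <- function(object, ...) {
  ggplot2::ggplot(object$occupancy, ggplot2::aes(
    x = stats::reorder(.data$taxon, .data$occupancy), y = .data$occupancy
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of non-gap sites") +
    ggplot2::theme_minimal()
}

#' Plot adequacy Z-scores
#'
#' Bar chart of `|Z|` per statistic; smaller is a better model fit.
#'
#' @param adequacy Tibble from [ppa_assess()] (optionally row-bound over
#'   models, with an extra grouping column passed as `fill`).
#' @param fill Optional column name used as fill aesthetic.
#' @return A ggplot object.
#' @export
plot_adequacy <- function(adequacy, fill = NULL) {
  p <- ggplot2::ggplot(adequacy, ggplot2::aes(
    x = .data$statistic, y = .data$abs_z
  ))
  p <- if (is.null(fill)) {
    p + ggplot2::geom_col(fill = "grey40", position = "dodge")
  } else {
    p + ggplot2::geom_col(
      ggplot2::aes(fill = .data[[fill]]), position = "dodge"
    )
  }
  p +
    ggplot2::labs(x = NULL, y = "|Z| (smaller = better fit)") +
    ggplot2::theme_minimal()
}
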