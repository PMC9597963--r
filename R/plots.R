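#' Plot normalized gain importance
#'
#' Horizontal bar chart of the top features by gain fraction, in descending
#' order, matching the convention of importance charts for boosted guide
#' models.
#'
#' @param importance Output of [feature_importance()] (or a fitted model,
#'   which is tidied first).
#' @param top_n How many features to show.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = 20) {
  if (inherits(importance, "guideboost_fit")) {
    importance <- feature_importance(importance)
  }
  d <- dplyr::slice_min(importance, .data$rank, n = top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$gain_fraction,
    y = stats::reorder(.data$feature, .data$gain_fraction)
  )) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "Gain fraction", y = NULL,
      title = "Feature importance (normalized gain)") +
    ggplot2::theme_minimal()
}

#' Plot a per-prediction contribution breakdown
#'
#' Signed bar chart of the largest feature contributions for one guide; the
#' prediction equals the training grand mean plus the sum of all bars.
#'
#' @param contributions Output of [predict_contributions()].
#' @param row Which guide to plot.
#' @param top_n How many features to show (by absolute contribution).
#' @return A ggplot object.
#' @export
plot_contributions <- function(contributions, row = 1L, top_n = 10) {
  d <- top_contributions(contributions, row = row, n = top_n)
  pred <- d$prediction[1]
  base <- d$base_value[1]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$contribution,
    y = stats::reorder(.data$feature, abs(.data$contribution)),
    fill = .data$contribution > 0
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#1b9e77",
      `FALSE` = "#d95f02")) +
    ggplot2::labs(
      x = "Contribution (score units)", y = NULL,
      title = sprintf("Prediction %.2f = base %.2f + contributions",
        pred, base)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.guideboost_fit <- function(object, top_n = 20, ...) {
  plot_importance(feature_importance(object), top_n = top_n)
}
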