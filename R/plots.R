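#' Plot analyte variability across samples
#'
#' Bar chart of the coefficient of variation per analyte from a
#' [summarize_composition()] table, the quickest view of which nutrients
#' vary most across ingredient sources.
#'
#' @param summary Output of [summarize_composition()].
#' @return A ggplot object.
#' @export
plot_composition_variability <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$analyte, .data$cv_pct),
                               y = .data$cv_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "CV (%)",
                  title = "Analyte variability across samples") +
    ggplot2::theme_minimal()
}

#' @describeIn correlate_variables Correlation heatmap with significance
#'   stars.
#' @param object A `feedval_cor` object.
#' @export
autoplot.feedval_cor <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$var2, y = .data$var1,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(formatC(.data$r, format = "f", digits = 2), .data$stars)),
      size = 3) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_prediction_equation Observed-versus-fitted scatter with
#'   the 1:1 line.
#' @export
autoplot.prediction_equation <- function(object, ...) {
  d <- tibble::tibble(observed = object$observed, fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(
      x = paste("Fitted", object$response),
      y = paste("Observed", object$response),
      subtitle = sprintf("R2 = %.2f, RMSE = %.2f, n = %d",
                         object$r2, object$rmse, object$n)) +
    ggplot2::theme_minimal()
}
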