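#' Plot predictor accuracy by exercise
#'
#' Mean absolute percent difference between predicted and actual 1RM, with
#' ± SD error bars, one panel per exercise.
#'
#' @param reports An `rm_accuracy` tibble from [summarize_accuracy()].
#' @return A ggplot.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' plot_accuracy(summarize_accuracy(cohort))
plot_accuracy <- function(reports) {
  stopifnot(is.data.frame(reports))
  df <- reports[!is.na(reports$diff_mean), , drop = FALSE]
  df$predictor <- factor(df$predictor, levels = unique(reports$predictor))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predictor, y = .data$diff_mean)) +
    ggplot2::geom_col(fill = "#6baed6") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$diff_mean - .data$diff_sd),
                   ymax = .data$diff_mean + .data$diff_sd),
      width = 0.25, linewidth = 0.3
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$exercise)) +
    ggplot2::labs(
      x = NULL, y = "absolute difference predicted vs actual 1RM (%)",
      title = "Prediction accuracy by exercise and predictor"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_accuracy
#' @param object An `rm_accuracy` tibble.
#' @param ... Unused.
#' @export
autoplot.rm_accuracy <- function(object, ...) {
  plot_accuracy(object)
}

#' Q-Q diagnostic of paired differences
#'
#' Normal quantile plot of `predicted - actual`, the diagnostic companion to
#' the Shapiro–Wilk gate in [paired_compare()]. Purely visual; it never gates
#' the test selection programmatically.
#'
#' @param predicted,actual Paired numeric vectors, kg.
#' @return A ggplot.
#' @export
plot_paired_qq <- function(predicted, actual) {
  df <- tibble::tibble(difference = predicted - actual)
  ggplot2::ggplot(df, ggplot2::aes(sample = .data$difference)) +
    ggplot2::stat_qq(colour = "#2171b5") +
    ggplot2::stat_qq_line(linetype = "dashed") +
    ggplot2::labs(
      x = "normal quantiles", y = "predicted - actual 1RM (kg)",
      title = "Q-Q plot of paired differences"
    ) +
    ggplot2::theme_minimal()
}
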