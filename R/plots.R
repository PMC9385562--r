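#' Plot the optimizer's objective trace
#'
#' @param object A `mix_lasso_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mix_lasso_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective) - 1L,
                       objective = object$objective)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "iteration", y = "smoothed objective",
                  title = "Smoothing proximal gradient convergence") +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation surface
#'
#' Mean held-out error per grid point, one line per gamma level.
#'
#' @param object A `mixlasso_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mixlasso_cv <- function(object, ...) {
  df <- object$summary
  metric <- object$metric
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data[[metric]],
                                   color = factor(.data$gamma))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = paste("mean held-out", metric),
                  color = expression(gamma)) +
    ggplot2::theme_minimal()
}

#' Plot benchmark accuracy by model and scenario
#'
#' Boxplots of the per-(tissue, drug) mean validation Spearman correlations
#' for mix-lasso and tree lasso, faceted by scenario.
#'
#' @param object A `mixlasso_benchmark`.
#' @param metric `"spearman"` (default) or `"rmse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mixlasso_benchmark <- function(object, metric = "spearman", ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$model, y = .data[[metric]],
                               fill = .data$model)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.6) +
    ggplot2::facet_wrap(~ .data$scenario,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = paste("mean validation", metric)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
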