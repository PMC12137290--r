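#' Plot GA convergence
#'
#' Line plot of best fitness per generation.
#'
#' @param object A `fohem_ga_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fohem_ga_result <- function(object, ...) {
  ggplot2::ggplot(ga_history(object),
                  ggplot2::aes(x = .data$generation, y = .data$best_fitness)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Generation", y = "Best fitness",
                  title = "GA convergence") +
    ggplot2::theme_minimal()
}

#' Plot a feature-importance report
#'
#' Horizontal bars, most important feature on top.
#'
#' @param object A `fohem_importance` report.
#' @param top_n Show only the `top_n` largest (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fohem_importance <- function(object, top_n = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (!is.null(top_n)) d <- utils::head(d, top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance,
                                  y = stats::reorder(.data$feature,
                                                     .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Permutation importance (MSE increase)", y = NULL,
                  title = "Global feature importance") +
    ggplot2::theme_minimal()
}

#' Plot the membership functions of a fuzzy variable
#'
#' @param var A [fuzzy_variable()].
#' @param n Grid points (default 400).
#' @return A ggplot object with one curve per fuzzy set.
#' @export
plot_membership <- function(var, n = 400) {
  stopifnot(inherits(var, "fohem_variable"))
  grid <- seq(var$universe[1], var$universe[2], length.out = n)
  d <- purrr::map_dfr(names(var$sets), function(lab) {
    tibble::tibble(x = grid, mu = mf_eval(var$sets[[lab]], grid), set = lab)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$mu,
                                  color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = var$name, y = "membership",
                  title = paste("Membership functions:", var$name)) +
    ggplot2::theme_minimal()
}

#' Plot observed versus predicted yields
#'
#' @param data Dataset tibble with a `yield` column.
#' @param y_pred Predictions aligned with `data`.
#' @return A ggplot object, faceted by treatment with location as color.
#' @export
plot_predictions <- function(data, y_pred) {
  d <- tibble::tibble(observed = data$yield, predicted = y_pred,
                      treatment = data$treatment, location = data$location)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                  color = .data$location)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "Observed yield (t/ha)", y = "Predicted yield (t/ha)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
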