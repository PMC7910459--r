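#' Plot a population fit
#'
#' Observed vs expected log2FC cloud with the fitted population trend.
#'
#' @param object A `population_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot population_fit
#' @export
autoplot.population_fit <- function(object, ...) {
  grid <- tibble(x = seq(object$range[1], object$range[2], length.out = 200))
  grid$y <- predict(object, grid$x)
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_line(data = grid, colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "expected log2FC (Bliss sum of singles)",
                  y = "observed log2FC",
                  title = sprintf("Population trend (%s, span %.2f, degree %d)",
                                  object$method, object$span, object$degree)) +
    ggplot2::theme_minimal()
}

#' Plot the residual variance profile across expected-effect bins
#'
#' Per-bin residual variance (raw and, where present, variance-adjusted)
#' against mean expected log2FC — a visual check of the heteroscedasticity
#' correction.
#'
#' @param rt A residual tibble (after [variance_adjust()] for the adjusted
#'   panel).
#' @return A ggplot.
#' @export
plot_variance_profile <- function(rt) {
  df <- as_tibble(rt) %>%
    filter(!is.na(.data$bin_index)) %>%
    group_by(.data$comparison_id, .data$bin_index) %>%
    summarise(mid = mean(.data$expected_log2fc),
              raw = var(.data$residual),
              adjusted = var(.data$adjusted_residual),
              .groups = "drop") %>%
    tidyr::pivot_longer(c("raw", "adjusted"), names_to = "scale",
                        values_to = "variance")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$variance,
                                   colour = .data$scale,
                                   group = interaction(.data$comparison_id,
                                                       .data$scale))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "bin mean expected log2FC", y = "residual variance",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of pair results
#'
#' Mean variance-adjusted residual against -log10 Bonferroni-adjusted t
#' p-value, hits highlighted.
#'
#' @param object A `pair_results` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pair_results
#' @export
autoplot.pair_results <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(neglogp = -log10(pmax(.data$t_p_adj, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_adjusted_residual,
                                   y = .data$neglogp,
                                   colour = .data$is_hit)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean variance-adjusted residual",
                  y = "-log10 adjusted t p-value", colour = "hit") +
    ggplot2::theme_minimal()
}
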