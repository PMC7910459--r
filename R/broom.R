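#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a population fit
#'
#' @param x A `population_fit`.
#' @param ... Unused.
#' @return Tibble with one row per fitted point: `expected_log2fc`,
#'   `observed_log2fc`, `.fitted`, `.resid`.
#' @method tidy population_fit
#' @export
tidy.population_fit <- function(x, ...) {
  fitted <- predict(x, x$points$x)
  tibble(expected_log2fc = x$points$x,
         observed_log2fc = x$points$y,
         .fitted = fitted,
         .resid = x$points$y - fitted)
}

#' One-row summary of a population fit
#'
#' @param x A `population_fit`.
#' @param ... Unused.
#' @return Tibble: `method`, `n`, `span`, `degree`, `sigma` (residual s.d.),
#'   `range_min`, `range_max`.
#' @method glance population_fit
#' @export
glance.population_fit <- function(x, ...) {
  res <- x$points$y - predict(x, x$points$x)
  tibble(method = x$method, n = x$n, span = x$span,
         degree = as.integer(x$degree), sigma = sd(res),
         range_min = x$range[1], range_max = x$range[2])
}

#' Tidy pair results
#'
#' @param x A `pair_results` tibble.
#' @param ... Unused.
#' @return The underlying tibble, ordered by adjusted t p-value.
#' @method tidy pair_results
#' @export
tidy.pair_results <- function(x, ...) {
  as_tibble(x) %>% arrange(.data$t_p_adj, .data$rra_p_adj)
}

#' One-row summary of pair results
#'
#' @param x A `pair_results` tibble.
#' @param ... Unused.
#' @return Tibble: `n_pairs`, `n_hits`, `n_significant_t`,
#'   `n_significant_rra`, `n_filtered_essential`, `n_insufficient`.
#' @method glance pair_results
#' @export
glance.pair_results <- function(x, ...) {
  tibble(n_pairs = nrow(x),
         n_hits = sum(x$is_hit),
         n_significant_t = sum(x$significant_t, na.rm = TRUE),
         n_significant_rra = sum(x$significant_rra, na.rm = TRUE),
         n_filtered_essential = sum(x$filter_reason == "essential_gene_in_pair"),
         n_insufficient = sum(x$filter_reason == "insufficient_residuals"))
}
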