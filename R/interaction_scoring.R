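#' Bliss-expectation log2 fold change for paired constructs
#'
#' Under Bliss independence the expected log2FC of a paired construct is the
#' sum of the observed log2FCs of its two guides measured in single-targeting
#' constructs (each guide paired with the non-targeting control) in the same
#' comparison. Paired constructs whose own observation, or either single-guide
#' observation, is missing or low-count-flagged are excluded and reported in
#' the `"excluded"` attribute.
#'
#' @param fc Fold-change tibble from [compute_log2fc()].
#' @param lib A [guide_library()].
#' @param comparison_id The comparison to evaluate.
#' @return Tibble `construct_id`, `gene_pair`, `expected_log2fc`,
#'   `observed_log2fc`, with attribute `excluded` (tibble `construct_id`,
#'   `reason`).
#' @export
expected_log2fc <- function(fc, lib, comparison_id) {
  stopifnot(inherits(lib, "guide_library"))
  fc1 <- fc[fc$comparison_id == comparison_id, ]
  if (nrow(fc1) == 0) {
    abort(sprintf("comparison '%s' absent from fold-change table",
                  comparison_id))
  }
  ann <- construct_annotation(lib)
  obs <- setNames(fc1$observed_log2fc, fc1$construct_id)
  ok <- setNames(!fc1$low_count_flag, fc1$construct_id)

  singles <- ann %>% filter(.data$kind == "single_targeting")
  # observed single-guide effect, indexed by the targeting guide
  single_obs <- setNames(unname(obs[singles$construct_id]), singles$su6_guide)
  single_ok <- setNames(
    unname(ok[singles$construct_id]) %in% TRUE &
      !is.na(unname(obs[singles$construct_id])),
    singles$su6_guide)

  paired <- ann %>% filter(.data$kind == "paired")
  paired <- paired %>%
    mutate(observed_log2fc = unname(obs[.data$construct_id]),
           own_ok = unname(ok[.data$construct_id]) %in% TRUE &
             !is.na(.data$observed_log2fc),
           s1_ok = unname(single_ok[.data$hu6_guide]) %in% TRUE,
           s2_ok = unname(single_ok[.data$su6_guide]) %in% TRUE,
           expected_log2fc = unname(single_obs[.data$hu6_guide]) +
             unname(single_obs[.data$su6_guide]))
  excluded <- paired %>%
    filter(!(.data$own_ok & .data$s1_ok & .data$s2_ok)) %>%
    mutate(reason = dplyr::case_when(
      !.data$own_ok ~ "paired_observation_missing_or_low_count",
      !.data$s1_ok ~ "hu6_single_missing_or_low_count",
      TRUE ~ "su6_single_missing_or_low_count")) %>%
    select("construct_id", "reason")
  out <- paired %>%
    filter(.data$own_ok, .data$s1_ok, .data$s2_ok) %>%
    select("construct_id", "gene_pair", "expected_log2fc", "observed_log2fc")
  attr(out, "excluded") <- excluded
  out
}

#' Fit the population trend of observed on expected log2FC
#'
#' Locally weighted polynomial regression (tricube weights) of observed on
#' expected log2FC, modelling how the construct population behaves as a
#' whole; genuine genetic interactions appear as departures from this trend.
#' With fewer than 30 points the fit falls back to an ordinary least-squares
#' line (with a warning). Predictions beyond the fitted range use linear
#' extension from the boundary.
#'
#' @param points Data frame with columns `expected_log2fc` and
#'   `observed_log2fc` (or `expected` / `observed`).
#' @param span LOESS span (fraction of points in each local neighbourhood).
#' @param degree Local polynomial degree, 1 or 2.
#' @param robust_iterations Robustifying reweight iterations (0 = plain
#'   least squares within each neighbourhood).
#' @param surface `"interpolate"` (fast kd-tree interpolation, default) or
#'   `"direct"` (exact evaluation).
#' @return A `population_fit` object; use [predict()] to evaluate it.
#' @export
fit_population_loess <- function(points, span = 0.75, degree = 2,
                                 robust_iterations = 3,
                                 surface = c("interpolate", "direct")) {
  surface <- match.arg(surface)
  points <- as_tibble(points)
  if (!"expected_log2fc" %in% names(points) && "expected" %in% names(points)) {
    points <- points %>% rename(expected_log2fc = "expected")
  }
  if (!"observed_log2fc" %in% names(points) && "observed" %in% names(points)) {
    points <- points %>% rename(observed_log2fc = "observed")
  }
  x <- points$expected_log2fc
  y <- points$observed_log2fc
  if (length(x) < 2 || diff(range(x)) == 0) {
    abort("degenerate design: all expected values identical")
  }
  if (span <= 0 || span > 1) abort("span must be in (0, 1]")
  if (!degree %in% c(1, 2)) abort("degree must be 1 or 2")
  if (length(x) < 30) {
    warn(sprintf(
      "only %d points; falling back to an ordinary least-squares line",
      length(x)))
    model <- lm(y ~ x, data = tibble(x = x, y = y))
    method <- "lm"
  } else {
    fam <- if (robust_iterations > 0) "symmetric" else "gaussian"
    model <- loess(y ~ x, data = tibble(x = x, y = y), span = span,
                   degree = degree, family = fam,
                   control = loess.control(surface = surface,
                                           iterations = robust_iterations + 1))
    method <- "loess"
  }
  rng <- range(x)
  structure(
    list(model = model, method = method, span = span, degree = degree,
         range = rng, n = length(x), points = tibble(x = x, y = y)),
    class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("<population_fit> %s on %d points (span %.2f, degree %d), range [%.3g, %.3g]\n",
              x$method, x$n, x$span, x$degree, x$range[1], x$range[2]))
  invisible(x)
}

#' Evaluate a population fit
#'
#' @param object A `population_fit`.
#' @param newdata Numeric vector of expected log2FC values.
#' @param ... Unused.
#' @return Numeric vector of fitted observed log2FC; values outside the
#'   fitted range are linearly extended from the boundary slope.
#' @export
predict.population_fit <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  if (object$method == "lm") {
    return(unname(predict(object$model, tibble(x = x))))
  }
  out <- rep(NA_real_, length(x))
  lo <- object$range[1]
  hi <- object$range[2]
  inside <- x >= lo & x <= hi
  if (any(inside)) {
    out[inside] <- unname(predict(object$model, tibble(x = x[inside])))
  }
  if (any(!inside)) {
    eps <- max(1e-4, diff(object$range) * 1e-4)
    f_lo <- unname(predict(object$model, tibble(x = c(lo, lo + eps))))
    f_hi <- unname(predict(object$model, tibble(x = c(hi - eps, hi))))
    slope_lo <- (f_lo[2] - f_lo[1]) / eps
    slope_hi <- (f_hi[2] - f_hi[1]) / eps
    below <- !inside & x < lo
    above <- !inside & x > hi
    out[below] <- f_lo[1] + slope_lo * (x[below] - lo)
    out[above] <- f_hi[2] + slope_hi * (x[above] - hi)
  }
  out
}

#' Residuals of paired constructs from the population trend
#'
#' For each comparison separately: computes the Bliss expectation per paired
#' construct ([expected_log2fc()]), fits the population trend
#' ([fit_population_loess()]), interpolates the fitted value at each
#' construct's expected log2FC, and records `residual = observed - fitted`.
#' Negative residuals mean the pair is more lethal than the population trend
#' predicts (the synthetic-lethal direction).
#'
#' @param fc Fold-change tibble from [compute_log2fc()].
#' @param lib A [guide_library()].
#' @param comparisons Optional subset of comparison ids (default: all in
#'   `fc`).
#' @inheritParams fit_population_loess
#' @return A residual tibble (class `resid_tbl`): `construct_id`,
#'   `gene_pair`, `comparison_id`, `expected_log2fc`, `observed_log2fc`,
#'   `fitted_log2fc`, `residual`, `adjusted_residual` (NA until
#'   [variance_adjust()]), `bin_index` (NA). The per-comparison fits are kept
#'   in the `"fits"` attribute.
#' @export
compute_residuals <- function(fc, lib, comparisons = NULL, span = 0.75,
                              degree = 2, robust_iterations = 3,
                              surface = c("interpolate", "direct")) {
  surface <- match.arg(surface)
  comparisons <- comparisons %||% unique(fc$comparison_id)
  fits <- list()
  rows <- purrr::map(comparisons, function(cid) {
    ex <- expected_log2fc(fc, lib, cid)
    fit <- fit_population_loess(ex, span = span, degree = degree,
                                robust_iterations = robust_iterations,
                                surface = surface)
    fits[[cid]] <<- fit
    fitted <- predict(fit, ex$expected_log2fc)
    ex %>%
      mutate(comparison_id = cid, fitted_log2fc = fitted,
             residual = .data$observed_log2fc - fitted,
             adjusted_residual = NA_real_, bin_index = NA_integer_) %>%
      select("construct_id", "gene_pair", "comparison_id",
             "expected_log2fc", "observed_log2fc", "fitted_log2fc",
             "residual", "adjusted_residual", "bin_index")
  })
  out <- list_rbind(rows)
  class(out) <- c("resid_tbl", class(out))
  attr(out, "fits") <- fits
  out
}

#' Variance smoothing of heteroscedastic residuals
#'
#' Residual spread grows with the magnitude of the expected effect. Within
#' each comparison, constructs are ranked by expected log2FC and cut into
#' consecutive bins of `bin_size`; a final short bin (< `bin_size / 4`) is
#' merged into its neighbour. Each residual is divided by its bin's variance
#' (`divisor = "variance"`, the default) or standard deviation
#' (`divisor = "sd"`; the variant that actually studentizes the spread to 1).
#'
#' @param rt Residual tibble from [compute_residuals()].
#' @param bin_size Constructs per bin (>= 10).
#' @param divisor `"variance"` or `"sd"`.
#' @return The residual tibble with `adjusted_residual` and `bin_index`
#'   (1-based, per comparison) filled in.
#' @export
variance_adjust <- function(rt, bin_size = 200,
                            divisor = c("variance", "sd")) {
  divisor <- match.arg(divisor)
  if (bin_size < 10) abort("bin_size must be >= 10")
  adjust_one <- function(df, cid) {
    ord <- order(df$expected_log2fc)
    n <- nrow(df)
    n_bins <- max(1L, floor(n / bin_size))
    bin_of_rank <- pmin(ceiling(seq_len(n) / bin_size), n_bins + 1L)
    # merge a final short bin into its neighbour
    tail_size <- sum(bin_of_rank == n_bins + 1L)
    if (tail_size > 0 && tail_size < bin_size / 4) {
      bin_of_rank[bin_of_rank == n_bins + 1L] <- n_bins
    } else if (tail_size > 0) {
      n_bins <- n_bins + 1L
    }
    bin <- integer(n)
    bin[ord] <- bin_of_rank
    df$bin_index <- bin
    for (b in seq_len(max(bin))) {
      idx <- bin == b
      v <- var(df$residual[idx])
      if (!is.finite(v) || v == 0) {
        abort(sprintf(
          "bin %d of comparison '%s' has zero residual variance", b, cid))
      }
      denom <- if (divisor == "variance") v else sqrt(v)
      df$adjusted_residual[idx] <- df$residual[idx] / denom
    }
    df
  }
  out <- rt %>%
    group_by(.data$comparison_id) %>%
    group_modify(~ adjust_one(.x, .y$comparison_id)) %>%
    ungroup() %>%
    select(all_of(names(rt)))
  class(out) <- c("resid_tbl", class(out))
  attr(out, "fits") <- attr(rt, "fits")
  out
}

#' Write / read a residual table as TSV
#'
#' @param rt Residual tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residuals <- function(rt, path) {
  readr::write_tsv(as_tibble(rt), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_residuals
#' @export
read_residuals <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      construct_id = readr::col_character(),
      gene_pair = readr::col_character(),
      comparison_id = readr::col_character(),
      bin_index = readr::col_integer(),
      .default = readr::col_double()),
    progress = FALSE)
  class(out) <- c("resid_tbl", class(out))
  out
}
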