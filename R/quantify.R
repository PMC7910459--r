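#' Normalize a count matrix for sequencing depth
#'
#' `median_ratio` follows the median-of-ratios idea standard in count-based
#' screens: each column is divided by the median, over constructs with no
#' zero count, of the ratio of its count to the construct's geometric mean
#' across samples. `total_count` rescales every column to the mean column
#' total. The pseudocount is added after scaling so downstream log-ratios are
#' finite.
#'
#' @param cm A `count_matrix`.
#' @param method `"median_ratio"` (default) or `"total_count"`.
#' @param pseudocount Positive value added after scaling.
#' @return A `normalized_counts` object: list with `values` (wide tibble of
#'   doubles including the pseudocount), `samples`, `raw` (the input
#'   `count_matrix`), `method`, `pseudocount`.
#' @export
normalize_counts <- function(cm, method = c("median_ratio", "total_count"),
                             pseudocount = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  method <- match.arg(method)
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  m <- as.matrix(cm$counts[, -1])
  zero_col <- colSums(m) == 0
  if (any(zero_col)) {
    abort(sprintf("sample '%s' has all-zero counts",
                  colnames(m)[zero_col][1]))
  }
  if (method == "total_count") {
    target <- mean(colSums(m))
    scaled <- sweep(m, 2, colSums(m) / target, "/")
  } else {
    pos <- rowSums(m == 0) == 0
    if (!any(pos)) {
      abort("median_ratio normalization needs at least one construct with no zero counts")
    }
    gm <- exp(rowMeans(log(m[pos, , drop = FALSE])))
    sf <- apply(m[pos, , drop = FALSE] / gm, 2, median)
    scaled <- sweep(m, 2, sf, "/")
  }
  structure(
    list(values = bind_cols(cm$counts[, 1],
                            as_tibble(scaled + pseudocount)),
         samples = cm$samples, raw = cm,
         method = method, pseudocount = pseudocount),
    class = "normalized_counts")
}

#' Enumerate replicate-crossed screen-vs-baseline comparisons
#'
#' Forms the full cross product of screen replicates at one timepoint against
#' all baseline replicates, so triplicate screens against triplicate
#' baselines yield nine comparisons per construct.
#'
#' @param samples Tibble with `sample_id`, `role`, `replicate`,
#'   `timepoint_days` (e.g. `cm$samples`).
#' @param timepoint Screen timepoint (days) to compare.
#' @return Tibble `comparison_id`, `screen_sample`, `baseline_sample`.
#' @export
make_comparisons <- function(samples, timepoint) {
  samples <- as_tibble(samples)
  scr <- samples %>%
    filter(.data$role == "screen", .data$timepoint_days == timepoint)
  base <- samples %>% filter(.data$role == "baseline")
  if (nrow(scr) == 0) {
    abort(sprintf("no screen samples at timepoint %s", timepoint))
  }
  if (nrow(base) == 0) abort("no baseline samples")
  expand_grid(screen_sample = scr$sample_id,
              baseline_sample = base$sample_id) %>%
    mutate(comparison_id = paste0(.data$screen_sample, ".vs.",
                                  .data$baseline_sample)) %>%
    select("comparison_id", "screen_sample", "baseline_sample")
}

#' Per-construct log2 fold changes for a set of comparisons
#'
#' For each comparison, `observed_log2fc = log2(normalized screen) -
#' log2(normalized baseline)` on the pseudocounted normalized values.
#' Constructs whose raw baseline count falls below `min_baseline_count` are
#' flagged (`low_count_flag`), not dropped, so the scoring stage can report
#' exclusions.
#'
#' @param norm A `normalized_counts` object.
#' @param comparisons Tibble from [make_comparisons()].
#' @param min_baseline_count Raw baseline count threshold for flagging.
#' @return Tibble `construct_id`, `comparison_id`, `observed_log2fc`,
#'   `low_count_flag`.
#' @export
compute_log2fc <- function(norm, comparisons, min_baseline_count = 30) {
  stopifnot(inherits(norm, "normalized_counts"))
  comparisons <- as_tibble(comparisons)
  vals <- norm$values
  raw <- norm$raw$counts
  known <- names(vals)[-1]
  unknown <- setdiff(c(comparisons$screen_sample,
                       comparisons$baseline_sample), known)
  if (length(unknown) > 0) {
    abort(sprintf("comparison references unknown sample '%s'", unknown[1]))
  }
  purrr::pmap(comparisons, function(comparison_id, screen_sample,
                                    baseline_sample) {
    tibble(
      construct_id = vals$construct_id,
      comparison_id = comparison_id,
      observed_log2fc = log2(vals[[screen_sample]]) -
        log2(vals[[baseline_sample]]),
      low_count_flag = raw[[baseline_sample]] < min_baseline_count)
  }) %>% list_rbind()
}
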