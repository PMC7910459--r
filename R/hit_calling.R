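#' Per-pair t statistic on variance-adjusted residuals
#'
#' The statistic is `t = mean(r) / sqrt(var(r) / (n - 1))` with `var` the
#' unbiased sample variance — note the `n - 1` in the denominator, which this
#' screen-scoring scheme uses in place of the conventional `n`. The p-value
#' is two-sided from the t distribution with `n - 1` degrees of freedom.
#' With fewer than 3 residuals or zero variance the pair is flagged rather
#' than tested.
#'
#' @param residuals Numeric vector of one pair's variance-adjusted residuals.
#' @return One-row tibble `n`, `mean`, `t_stat`, `t_p`, `flagged`.
#' @export
pair_t_test <- function(residuals) {
  r <- residuals[is.finite(residuals)]
  n <- length(r)
  if (n < 3 || var(r) == 0) {
    return(tibble(n = n, mean = if (n > 0) mean(r) else NA_real_,
                  t_stat = NA_real_, t_p = NA_real_, flagged = TRUE))
  }
  t_stat <- mean(r) / sqrt(var(r) / (n - 1))
  tibble(n = n, mean = mean(r), t_stat = t_stat,
         t_p = 2 * pt(-abs(t_stat), df = n - 1), flagged = FALSE)
}

#' Raw per-pair interaction statistics (t test and alpha-RRA)
#'
#' Runs both branches of the dual test on a variance-adjusted residual
#' table: the per-pair t statistic ([pair_t_test()]) and alpha-RRA on the
#' pooled ranks ([alpha_rra()]).
#'
#' @param rt Residual tibble after [variance_adjust()].
#' @inheritParams rra_score
#' @return Tibble with one row per gene pair: `gene_pair`, `gene_a`,
#'   `gene_b`, `n_residuals`, `mean_adjusted_residual`, `t_stat`, `t_p`,
#'   `rra_rho`, `rra_p`, `filter_reason` (`"insufficient_residuals"` where
#'   the t test is undefined, else `"none"`).
#' @export
test_pairs <- function(rt, alpha = 0.1, n_perm = 10000, seed = 1L) {
  tt <- rt %>%
    filter(is.finite(.data$adjusted_residual)) %>%
    group_by(.data$gene_pair) %>%
    group_modify(~ pair_t_test(.x$adjusted_residual)) %>%
    ungroup()
  rra <- alpha_rra(rt, alpha = alpha, n_perm = n_perm, seed = seed)
  out <- tt %>%
    inner_join(rra, by = "gene_pair") %>%
    transmute(
      gene_pair = .data$gene_pair,
      n_residuals = .data$n_residuals,
      mean_adjusted_residual = .data$mean,
      t_stat = .data$t_stat, t_p = .data$t_p,
      rra_rho = .data$rra_rho, rra_p = .data$rra_p,
      filter_reason = ifelse(.data$flagged, "insufficient_residuals", "none"))
  bind_cols(out, split_pair_key(out$gene_pair)) %>%
    relocate("gene_a", "gene_b", .after = "gene_pair")
}

#' Multiple-testing correction and hit calling
#'
#' Adjusts both tests' p-values across the tested pair universe (Bonferroni
#' by default; Benjamini-Hochberg available) and calls a pair a hit only if
#' it is significant by both the t test and alpha-RRA, its mean adjusted
#' residual is negative (more lethal than expected), and it carries no
#' filter flag. Taking the overlap of the two tests enforces both size and
#' consistency of the interaction effect.
#'
#' @param pair_stats Tibble from [test_pairs()].
#' @param method `"bonferroni"` (default) or `"BH"`.
#' @param threshold Adjusted-p significance threshold (default 0.1).
#' @return A `pair_results` tibble adding `t_p_adj`, `rra_p_adj`,
#'   `significant_t`, `significant_rra`, `is_hit`.
#' @export
adjust_and_call <- function(pair_stats, method = c("bonferroni", "BH"),
                            threshold = 0.1) {
  method <- match.arg(method)
  out <- pair_stats %>%
    mutate(
      t_p_adj = p.adjust(.data$t_p, method = method),
      rra_p_adj = p.adjust(.data$rra_p, method = method),
      significant_t = !is.na(.data$t_p_adj) & .data$t_p_adj < threshold,
      significant_rra = !is.na(.data$rra_p_adj) & .data$rra_p_adj < threshold,
      is_hit = .data$significant_t & .data$significant_rra &
        .data$mean_adjusted_residual < 0 & .data$filter_reason == "none")
  class(out) <- c("pair_results", class(out))
  out
}

#' Call genes depleted in isolation (single-construct depletion caller)
#'
#' A simplified depletion caller on the single-targeting constructs: the
#' alpha-RRA machinery is applied to their log2 fold changes grouped by
#' target gene, Bonferroni-corrected over genes; genes below `threshold`
#' with negative mean log2FC are flagged as lethal in isolation
#' (provenance `internal_day14`). Genes from an externally supplied list
#' (e.g. an independent essentiality screen) are merged with provenance
#' `external_list`.
#'
#' @param fc Fold-change tibble from [compute_log2fc()] for the depletion
#'   timepoint (typically day 14).
#' @param lib A [guide_library()].
#' @inheritParams rra_score
#' @param threshold Adjusted-p threshold (default 0.1).
#' @param external Character vector of externally known essential genes.
#' @return Tibble `gene`, `provenance`; full per-gene statistics in the
#'   `"stats"` attribute.
#' @export
call_single_gene_depletion <- function(fc, lib, alpha = 0.1, n_perm = 10000,
                                       threshold = 0.1,
                                       external = character(), seed = 1L) {
  ann <- construct_annotation(lib)
  singles <- ann %>% filter(.data$kind == "single_targeting")
  df <- fc %>%
    inner_join(singles %>% select("construct_id", "target_gene"),
               by = "construct_id") %>%
    filter(!.data$low_count_flag, is.finite(.data$observed_log2fc))
  if (nrow(df) == 0) abort("no usable single-targeting observations")
  # rank at guide level: each construct collapsed to its mean log2FC across
  # comparisons, so the replicate-crossed comparisons are not treated as
  # independent observations
  df <- df %>%
    group_by(.data$construct_id, .data$target_gene) %>%
    summarise(observed_log2fc = mean(.data$observed_log2fc),
              .groups = "drop")
  stats <- rra_score(df$observed_log2fc, df$target_gene, alpha = alpha,
                     n_perm = n_perm, seed = seed) %>%
    rename(gene = "group") %>%
    mutate(p_adj = p.adjust(.data$p, method = "bonferroni"))
  mean_lfc <- df %>%
    group_by(gene = .data$target_gene) %>%
    summarise(mean_log2fc = mean(.data$observed_log2fc), .groups = "drop")
  stats <- stats %>% left_join(mean_lfc, by = "gene")
  internal <- stats %>%
    filter(.data$p_adj < threshold, .data$mean_log2fc < 0) %>%
    transmute(gene = .data$gene, provenance = "internal_day14")
  ext <- tibble(gene = unique(external), provenance = "external_list")
  out <- bind_rows(internal, ext) %>% distinct(.data$gene, .keep_all = TRUE)
  attr(out, "stats") <- stats
  out
}

#' Exclude pairs containing genes lethal in isolation
#'
#' Lethal guides placed under the hU6 promoter in a paired construct tend to
#' produce spuriously significant residuals, so any pair containing a gene
#' lethal on its own is removed from the hit list (statistics are retained
#' for reporting).
#'
#' @param results A `pair_results` tibble from [adjust_and_call()].
#' @param essential Tibble `gene`, `provenance` from
#'   [call_single_gene_depletion()] (or any data frame with a `gene`
#'   column).
#' @return The results with affected pairs' `is_hit` forced `FALSE` and
#'   `filter_reason = "essential_gene_in_pair"`.
#' @export
filter_hits <- function(results, essential) {
  ess <- unique(as_tibble(essential)$gene)
  hit_ess <- results$gene_a %in% ess | results$gene_b %in% ess
  out <- results %>%
    mutate(
      filter_reason = ifelse(hit_ess & .data$filter_reason == "none",
                             "essential_gene_in_pair", .data$filter_reason),
      is_hit = .data$is_hit & !hit_ess)
  class(out) <- unique(c("pair_results", class(out)))
  out
}

#' Interaction residual of a competitive growth assay
#'
#' Scores the four-population co-culture validation assay. Each transduced
#' population's phenotype is its log2 depletion relative to the untransduced
#' population between the two timepoints:
#' `phenotype(P) = log2((frac_P(t1) / frac_untr(t1)) /
#' (frac_P(t0) / frac_untr(t0)))`. The residual is the observed
#' double-positive phenotype minus the sum of the two single-positive
#' phenotypes; negative values mean the pair is more lethal than additive.
#'
#' @param fractions Data frame with columns `population` (exactly
#'   `untransduced`, `single_a`, `single_b`, `double`), `frac_t0`,
#'   `frac_t1`; fractions at each timepoint must sum to 1 (tolerance 1e-6).
#' @return The residual (numeric scalar) with attribute `phenotypes`
#'   (named vector for `single_a`, `single_b`, `double`).
#' @export
competitive_assay_residual <- function(fractions) {
  fractions <- as_tibble(fractions)
  pops <- c("untransduced", "single_a", "single_b", "double")
  if (!setequal(fractions$population, pops) || nrow(fractions) != 4) {
    abort("fractions must contain exactly the populations: untransduced, single_a, single_b, double")
  }
  f0 <- setNames(fractions$frac_t0, fractions$population)[pops]
  f1 <- setNames(fractions$frac_t1, fractions$population)[pops]
  if (abs(sum(f0) - 1) > 1e-6 || abs(sum(f1) - 1) > 1e-6) {
    abort("population fractions must sum to 1 at each timepoint")
  }
  if (any(f0 <= 0) || any(f1 <= 0)) {
    abort("all population fractions must be positive to compute phenotypes")
  }
  phenotype <- function(p) {
    log2((f1[[p]] / f1[["untransduced"]]) / (f0[[p]] / f0[["untransduced"]]))
  }
  ph <- c(single_a = phenotype("single_a"),
          single_b = phenotype("single_b"),
          double = phenotype("double"))
  res <- ph[["double"]] - (ph[["single_a"]] + ph[["single_b"]])
  attr(res, "phenotypes") <- ph
  res
}
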