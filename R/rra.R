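# Core alpha-RRA machinery shared by pair scoring and the single-gene
# depletion caller.

# rho statistic for one group: u are the group's normalized ranks, n the
# group size. Only ranks at or below alpha contribute; the score is the
# minimum Beta(j, n - j + 1) tail probability over the order statistics.
rra_rho <- function(u, alpha) {
  n <- length(u)
  us <- sort(u[u <= alpha])
  k <- length(us)
  if (k == 0) return(1)
  j <- seq_len(k)
  min(pbeta(us, j, n - j + 1))
}

# Permutation null of rho for groups of size n drawn without replacement
# from the pooled normalized ranks u_all.
rra_perm_null <- function(u_all, n, alpha, n_perm) {
  N <- length(u_all)
  vapply(seq_len(n_perm), function(i) {
    rra_rho(u_all[sample.int(N, n)], alpha)
  }, numeric(1))
}

#' Alpha robust rank aggregation over grouped values
#'
#' Ranks all `values` ascending (most negative = rank 1, average ranks for
#' ties), normalizes ranks to (0, 1], and scores each group by the alpha-RRA
#' rho statistic: among the group's normalized ranks at or below `alpha`,
#' the minimum Beta-distribution tail probability over the order statistics.
#' Significance is a permutation tail probability under random reassignment
#' of rank sets of the same size, floored at `1 / (n_perm + 1)`.
#'
#' @param values Numeric vector (lower = stronger depletion signal).
#' @param group Grouping vector (e.g. gene pair or gene) parallel to
#'   `values`.
#' @param alpha Rank fraction considered signal-bearing, in (0, 0.5].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation draw.
#' @return Tibble `group`, `n`, `n_bottom` (ranks at or below alpha), `rho`,
#'   `p`.
#' @export
rra_score <- function(values, group, alpha = 0.1, n_perm = 10000, seed = 1L) {
  if (alpha <= 0 || alpha > 0.5) abort("alpha must be in (0, 0.5]")
  if (n_perm < 100) {
    abort("n_perm must be >= 100 for an interpretable permutation p-value")
  }
  keep <- is.finite(values)
  values <- values[keep]
  group <- as.character(group)[keep]
  N <- length(values)
  if (N == 0) abort("no finite values to rank")
  u <- rank(values, ties.method = "average") / N

  by_group <- split(u, group)
  stats <- tibble(
    group = names(by_group),
    n = unname(lengths(by_group)),
    n_bottom = unname(vapply(by_group, function(g) sum(g <= alpha),
                             integer(1))),
    rho = unname(vapply(by_group, rra_rho, numeric(1), alpha = alpha)))

  set.seed(seed)
  p <- numeric(nrow(stats))
  for (n_i in sort(unique(stats$n))) {
    null <- rra_perm_null(u, n_i, alpha, n_perm)
    sel <- stats$n == n_i
    p[sel] <- vapply(stats$rho[sel], function(r) {
      (1 + sum(null <= r)) / (n_perm + 1)
    }, numeric(1))
  }
  stats$p <- p
  stats
}

#' Alpha-RRA over a variance-adjusted residual table
#'
#' Pools the variance-adjusted residuals of all paired constructs across all
#' comparisons, ranks them ascending, and aggregates per gene pair — so a
#' 5x5-guide pair with triplicate screens and baselines contributes up to
#' 225 residuals to its rank set.
#'
#' @param rt Residual tibble after [variance_adjust()].
#' @inheritParams rra_score
#' @return Tibble `gene_pair`, `n_residuals`, `n_bottom`, `rra_rho`, `rra_p`.
#' @export
alpha_rra <- function(rt, alpha = 0.1, n_perm = 10000, seed = 1L) {
  if (all(is.na(rt$adjusted_residual))) {
    abort("adjusted residuals missing; run variance_adjust() first")
  }
  rra_score(rt$adjusted_residual, rt$gene_pair, alpha = alpha,
            n_perm = n_perm, seed = seed) %>%
    rename(gene_pair = "group", n_residuals = "n",
           rra_rho = "rho", rra_p = "p")
}
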