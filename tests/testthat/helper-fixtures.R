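# Shared fixtures, built in code at test time.

control_guide <- function() {
  tibble::tibble(guide_id = "Fluc", gene = "CONTROL",
                 spacer = "GTGTTGGGCGCGTTATTTAT", is_control = TRUE)
}

# deterministic spacers for tiny fixtures (valid alphabet, unique)
fixed_spacer <- function(i) {
  base <- c("A", "C", "G", "T")
  digits <- (i %/% 4^(0:3)) %% 4    # base-4 expansion: unique per i < 256
  # each digit repeated 5x -> pairwise Hamming distance >= 5, so one
  # substitution can never make two fixture spacers ambiguous
  paste(rep(base[1 + digits], each = 5), collapse = "")
}

make_guides <- function(gene, n, offset = 0) {
  tibble::tibble(
    guide_id = sprintf("%s_g%d", gene, seq_len(n)),
    gene = gene,
    spacer = vapply(seq_len(n) + offset, fixed_spacer, character(1)),
    is_control = FALSE)
}

# a minimal two-gene library with full construct enumeration
tiny_library <- function(n_a = 2, n_b = 2) {
  ctrl <- control_guide()
  ga <- make_guides("AAA", n_a, offset = 1)
  gb <- make_guides("BBB", n_b, offset = 1 + n_a)
  cs <- enumerate_constructs(ga, gb, ctrl)
  guide_library(dplyr::bind_rows(ctrl, ga, gb),
                tibble::tibble(gene_a = "AAA", gene_b = "BBB",
                               category = "other"),
                cs, control_guide_id = "Fluc")
}

# simulate a screen and take it through fold changes + adjusted residuals
quick_screen <- function(sim, bin_size = 200, divisor = "variance",
                         timepoint = 28, ...) {
  st <- simulate_truth(sim)
  cm <- simulate_counts(st$library, st$effects, sim)
  norm <- normalize_counts(cm)
  fc <- compute_log2fc(norm, make_comparisons(cm$samples, timepoint))
  rt <- variance_adjust(compute_residuals(fc, st$library, ...),
                        bin_size = bin_size, divisor = divisor)
  list(truth = st, cm = cm, fc = fc, rt = rt)
}

# independent brute-force tricube local polynomial regression (the oracle
# for the LOESS cross-check); textbook definition, no shared code path
brute_force_local_fit <- function(x, y, x0, span, degree) {
  n <- length(x)
  q <- floor(span * n)
  vapply(x0, function(xi) {
    d <- abs(x - xi)
    dq <- sort(d)[q]
    w <- (1 - pmin(d / dq, 1)^3)^3
    keep <- w > 0
    X <- outer(x[keep] - xi, 0:degree, `^`)
    beta <- solve(t(X * w[keep]) %*% X, t(X * w[keep]) %*% y[keep])
    beta[1]
  }, numeric(1))
}

# exhaustive alpha-RRA permutation p-value for one group of size n drawn
# from a pooled rank vector (independent of the package implementation)
exhaustive_rra_p <- function(values, group_idx, alpha) {
  N <- length(values)
  u <- rank(values, ties.method = "average") / N
  n <- length(group_idx)
  rho_of <- function(us_all) {
    us <- sort(us_all[us_all <= alpha])
    if (length(us) == 0) return(1)
    j <- seq_along(us)
    min(pbeta(us, j, n - j + 1))
  }
  rho_obs <- rho_of(u[group_idx])
  combos <- utils::combn(N, n)
  rho_all <- apply(combos, 2, function(ix) rho_of(u[ix]))
  list(rho = rho_obs, p = mean(rho_all <= rho_obs))
}
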