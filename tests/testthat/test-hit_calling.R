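test_that("the pair t statistic matches its closed form and degenerates safely", {
  # symmetric residuals: t = 0, p = 1
  r <- pair_t_test(c(-1, 0, 1))
  expect_equal(r$t_stat, 0)
  expect_equal(r$t_p, 1)
  expect_false(r$flagged)
  # zero variance -> flagged, not an error
  r0 <- pair_t_test(c(-1, -1, -1, -1))
  expect_true(r0$flagged)
  expect_true(is.na(r0$t_stat))
  expect_true(pair_t_test(c(-1, 1))$flagged)

  # brute-force recomputation on random vectors (n - 1 in the denominator)
  set.seed(19)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    x <- rnorm(n)
    got <- pair_t_test(x)
    m <- sum(x) / n
    v <- sum((x - m)^2) / (n - 1)
    want_t <- m / sqrt(v / (n - 1))
    expect_equal(got$t_stat, want_t, tolerance = 1e-12)
    expect_equal(got$t_p, 2 * stats::pt(-abs(want_t), n - 1),
                 tolerance = 1e-12)
  }
})

test_that("t p-values are uniform on an iid null once the denominator is accounted for", {
  set.seed(101)
  n <- 225
  p <- vapply(1:4000, function(i) {
    x <- rnorm(n)
    t_ours <- pair_t_test(x)$t_stat
    # our statistic is the conventional one-sample t shrunk by
    # sqrt((n-1)/n); undo that before computing the reference p
    2 * stats::pt(-abs(t_ours * sqrt(n / (n - 1))), n - 1)
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("rra_score recovers closed-form and exhaustive reference values", {
  # a single residual that is the most negative of N = 1000: rho = u = 0.001
  vals <- c(-10, rnorm(999, 5, 0.1))
  grp <- c("hit", sprintf("other%03d", rep(1:111, length.out = 999)))
  sc <- rra_score(vals, grp, alpha = 0.1, n_perm = 100, seed = 1)
  expect_equal(sc$rho[sc$group == "hit"], 0.001)

  # no residual in the bottom alpha fraction -> rho = 1, p ~ 1
  vals2 <- c(rnorm(50, -5), 1, 2)
  grp2 <- c(rep("low", 50), "top", "top")
  sc2 <- rra_score(vals2, grp2, alpha = 0.1, n_perm = 200, seed = 1)
  expect_equal(sc2$rho[sc2$group == "top"], 1)
  expect_gt(sc2$p[sc2$group == "top"], 0.5)

  expect_error(rra_score(rnorm(10), rep("a", 10), n_perm = 50), "n_perm")

  # exhaustive oracle: N = 8 pooled values, the pair owns 2 of them
  set.seed(77)
  vals3 <- c(-3, -2.5, rnorm(6))
  grp3 <- c("pair", "pair", sprintf("x%d", 1:6))
  oracle <- exhaustive_rra_p(vals3, 1:2, alpha = 0.25)
  got <- rra_score(vals3, grp3, alpha = 0.25, n_perm = 1e5, seed = 3)
  grow <- got[got$group == "pair", ]
  expect_equal(grow$rho, oracle$rho, tolerance = 1e-12)
  mc_se <- sqrt(oracle$p * (1 - oracle$p) / 1e5)
  expect_lt(abs(grow$p - oracle$p), 3 * mc_se + 2 / 1e5)
})

test_that("more negative residuals never weaken a pair's evidence", {
  set.seed(55)
  base_vals <- rnorm(200)
  grp <- rep(sprintf("p%02d", 1:20), each = 10)
  for (shift in c(0.5, 1, 2)) {
    v1 <- base_vals
    v2 <- base_vals
    v2[grp == "p01"] <- v2[grp == "p01"] - shift
    s1 <- rra_score(v1, grp, alpha = 0.25, n_perm = 500, seed = 9)
    s2 <- rra_score(v2, grp, alpha = 0.25, n_perm = 500, seed = 9)
    expect_lte(s2$rho[s2$group == "p01"], s1$rho[s1$group == "p01"])
    t1 <- pair_t_test(v1[grp == "p01"])
    t2 <- pair_t_test(v2[grp == "p01"])
    expect_lt(t2$t_stat, t1$t_stat)
  }
})

test_that("Bonferroni adjustment and the dual-test intersection drive hit calls", {
  stats <- tibble::tibble(
    gene_pair = c("A|B", "C|D", "E|F"),
    gene_a = c("A", "C", "E"), gene_b = c("B", "D", "F"),
    n_residuals = 225L,
    mean_adjusted_residual = c(-2, -1, -0.5),
    t_stat = c(-8, -1, -6), t_p = c(0.0005, 0.4, 0.0001),
    rra_rho = c(0.001, 0.0005, 0.5), rra_p = c(0.0002, 0.0001, 0.6),
    filter_reason = "none")
  res <- adjust_and_call(stats, threshold = 0.1)
  m <- 3
  expect_equal(res$t_p_adj, pmin(1, stats$t_p * m))
  # A|B passes both tests; C|D is RRA-only; E|F is t-only
  expect_equal(res$is_hit, c(TRUE, FALSE, FALSE))
  expect_true(all(res$t_p_adj >= res$t_p))
  # m = 1: adjusted equals raw
  res1 <- adjust_and_call(stats[1, ], threshold = 0.1)
  expect_equal(res1$t_p_adj, stats$t_p[1])
  # raw p 0.0005 with m = 100 -> adjusted 0.05, significant at 0.1
  expect_equal(min(1, 0.0005 * 100), 0.05)
  stats100 <- dplyr::bind_rows(purrr::map(1:100, function(i) {
    dplyr::mutate(stats[1, ], gene_pair = sprintf("A%d|B%d", i, i),
                  t_p = ifelse(i == 1, 0.0005, 0.9),
                  rra_p = ifelse(i == 1, 0.0005, 0.9))
  }))
  res100 <- adjust_and_call(stats100, threshold = 0.1)
  expect_equal(res100$t_p_adj[1], 0.05)
  expect_true(res100$significant_t[1])
})

test_that("a strongly lethal gene is flagged by the depletion caller and only then", {
  flagged_sets <- purrr::map(1:10, function(s) {
    sim <- simulation_config(n_pairs = 15, frac_sl = 0, gene_fitness_sd = 0,
                             seed = 400 + s)
    st <- simulate_truth(sim)
    st$effects$gene_fitness$fitness[
      st$effects$gene_fitness$gene == "GA0001"] <- -3
    cm <- simulate_counts(st$library, st$effects, sim)
    fc14 <- compute_log2fc(normalize_counts(cm),
                           make_comparisons(cm$samples, 14))
    ess <- call_single_gene_depletion(fc14, st$library, n_perm = 2000,
                                      seed = s)
    ess$gene
  })
  expect_true(all(vapply(flagged_sets, function(g) "GA0001" %in% g,
                         logical(1))))
  # spurious flags are rare
  n_extra <- sum(lengths(flagged_sets)) - 10
  expect_lte(n_extra, 1)
})

test_that("null screens rarely flag any gene and external lists always propagate", {
  flagged <- purrr::map_int(1:10, function(s) {
    sim <- simulation_config(n_pairs = 15, frac_sl = 0, gene_fitness_sd = 0,
                             seed = 500 + s)
    st <- simulate_truth(sim)
    cm <- simulate_counts(st$library, st$effects, sim)
    fc14 <- compute_log2fc(normalize_counts(cm),
                           make_comparisons(cm$samples, 14))
    ess <- call_single_gene_depletion(fc14, st$library, n_perm = 2000,
                                      seed = s)
    nrow(ess)
  })
  expect_gte(sum(flagged == 0), 9)

  sim <- simulation_config(n_pairs = 5, seed = 6)
  st <- simulate_truth(sim)
  cm <- simulate_counts(st$library, st$effects, sim)
  fc14 <- compute_log2fc(normalize_counts(cm),
                         make_comparisons(cm$samples, 14))
  ess <- call_single_gene_depletion(fc14, st$library, n_perm = 200,
                                    external = "XYZ", seed = 1)
  expect_true("XYZ" %in% ess$gene)
  expect_equal(ess$provenance[ess$gene == "XYZ"], "external_list")
})

test_that("pairs containing essential genes are filtered with the reason recorded", {
  stats <- tibble::tibble(
    gene_pair = c("A|B", "C|D"),
    gene_a = c("A", "C"), gene_b = c("B", "D"),
    n_residuals = 225L, mean_adjusted_residual = c(-2, -2),
    t_stat = -8, t_p = 1e-5, rra_rho = 0.001, rra_p = 1e-4,
    filter_reason = "none")
  res <- adjust_and_call(stats, threshold = 0.1)
  expect_true(all(res$is_hit))
  filt <- filter_hits(res, tibble::tibble(gene = "A",
                                          provenance = "external_list"))
  expect_false(filt$is_hit[filt$gene_pair == "A|B"])
  expect_equal(filt$filter_reason[filt$gene_pair == "A|B"],
               "essential_gene_in_pair")
  expect_true(filt$is_hit[filt$gene_pair == "C|D"])
  # empty essential set leaves results unchanged
  same <- filter_hits(res, tibble::tibble(gene = character(),
                                          provenance = character()))
  expect_equal(as.data.frame(same), as.data.frame(res))
})

test_that("an SL pair with a lethal member is excluded despite its residuals", {
  sim <- simulation_config(n_pairs = 40, frac_sl = 1 / 40,
                           sl_effect_mean = -2, sl_effect_sd = 0,
                           gene_fitness_sd = 0, seed = 61)
  st <- simulate_truth(sim)
  tr <- st$effects$pair_interaction
  sl_key <- paste(tr$gene_a, tr$gene_b, sep = "|")[tr$epsilon < 0]
  sl_gene <- tr$gene_a[tr$epsilon < 0]
  st$effects$gene_fitness$fitness[
    st$effects$gene_fitness$gene == sl_gene] <- -3
  cm <- simulate_counts(st$library, st$effects, sim)
  norm <- normalize_counts(cm)
  fc28 <- compute_log2fc(norm, make_comparisons(cm$samples, 28))
  rt <- variance_adjust(compute_residuals(fc28, st$library), bin_size = 200)
  res <- adjust_and_call(test_pairs(rt, n_perm = 2000, seed = 2))
  fc14 <- compute_log2fc(norm, make_comparisons(cm$samples, 14))
  ess <- call_single_gene_depletion(fc14, st$library, n_perm = 2000, seed = 2)
  expect_true(sl_gene %in% ess$gene)
  final <- filter_hits(res, ess)
  row <- final[final$gene_pair == sl_key, ]
  expect_false(row$is_hit)
  expect_equal(row$filter_reason, "essential_gene_in_pair")
  # the interaction signal itself was present before filtering
  expect_lt(row$mean_adjusted_residual, 0)
})

test_that("competitive growth residuals follow the log-ratio definition", {
  # proportional change in all populations -> residual 0
  fr <- tibble::tibble(
    population = c("untransduced", "single_a", "single_b", "double"),
    frac_t0 = c(0.25, 0.25, 0.25, 0.25),
    frac_t1 = c(0.25, 0.25, 0.25, 0.25))
  expect_equal(as.numeric(competitive_assay_residual(fr)), 0)

  # double depleted 4-fold beyond additive expectation -> residual -2
  # singles halve relative to untransduced; additive double would be 1/4,
  # observed double is 1/16 of its start (relative)
  f0 <- c(unt = 0.25, a = 0.25, b = 0.25, d = 0.25)
  rel1 <- c(unt = 1, a = 0.5, b = 0.5, d = 0.25 / 4)
  f1 <- rel1 * f0
  f1 <- f1 / sum(f1)
  fr2 <- tibble::tibble(
    population = c("untransduced", "single_a", "single_b", "double"),
    frac_t0 = unname(f0), frac_t1 = unname(f1))
  res2 <- competitive_assay_residual(fr2)
  expect_equal(as.numeric(res2), -2, tolerance = 1e-10)
  ph <- attr(res2, "phenotypes")
  expect_equal(unname(ph[c("single_a", "single_b")]), c(-1, -1))

  # construction oracle: additive phenotypes with epsilon = -1
  eps <- -1
  pa <- -0.6
  pb <- -0.9
  rel <- c(unt = 1, a = 2^pa, b = 2^pb, d = 2^(pa + pb + eps))
  f1c <- rel * f0 / sum(rel * f0)
  fr3 <- tibble::tibble(
    population = c("untransduced", "single_a", "single_b", "double"),
    frac_t0 = unname(f0), frac_t1 = unname(f1c))
  expect_equal(as.numeric(competitive_assay_residual(fr3)), eps,
               tolerance = 1e-10)

  bad <- fr
  bad$frac_t1 <- c(0.5, 0.3, 0.2, 0)
  expect_error(competitive_assay_residual(bad), "positive")
  bad2 <- fr
  bad2$frac_t0 <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(competitive_assay_residual(bad2), "sum to 1")
})
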