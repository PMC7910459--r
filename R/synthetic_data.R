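#' Configuration for a synthetic paired-guide screen
#'
#' Collects every parameter of the ground-truthed screen generator. The
#' defaults emulate the design of a dual-promoter combinatorial dropout
#' screen: gene pairs with 3-5 guides per gene, all-versus-all paired
#' constructs plus one single-targeting construct per guide, triplicate
#' Cas9-negative baseline samples harvested at day 7, triplicate screen
#' samples at days 14 and 28, log-normal baseline abundance, guide-efficiency
#' and promoter-position effects, heteroscedastic interaction noise, and
#' negative-binomial sequencing counts.
#'
#' @param n_pairs Number of gene pairs in the library.
#' @param guides_per_gene Guides designed per gene (3-5).
#' @param frac_sl Fraction of pairs carrying a synthetic-lethal interaction
#'   (epsilon < 0).
#' @param gene_fitness_mean,gene_fitness_sd Normal distribution of per-gene
#'   fitness effects f (log2 fold-change units per fully efficient knockout
#'   over the full 28-day screen).
#' @param sl_effect_mean,sl_effect_sd Normal distribution of the interaction
#'   term epsilon for SL pairs (log2FC units; negative = synthetic lethal).
#' @param guide_eff_min,guide_eff_max Uniform range of per-guide cutting
#'   efficiency e in \[0, 1\].
#' @param promoter_hu6,promoter_su6 Promoter activity multipliers (the hU6
#'   promoter is modelled as at least as strong as the synthetic U6).
#' @param sigma0,sigma1 Heteroscedastic residual noise: per-construct,
#'   per-sample log2FC noise has s.d. `sigma0 + sigma1 * |true log2FC|`.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of relative
#'   baseline construct abundance.
#' @param depth Mean sequencing reads per construct per sample (coverage).
#' @param dispersion Negative-binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`).
#' @param n_baseline,n_screen Replicates per role (default triplicates).
#' @param timepoints Screen harvest days (baseline is fixed at day 7).
#' @param seed Integer seed; every draw in the generator flows from it.
#'
#' @return A `simulation_config` object (validated named list).
#' @export
simulation_config <- function(n_pairs = 200,
                              guides_per_gene = 3,
                              frac_sl = 0.05,
                              gene_fitness_mean = 0,
                              gene_fitness_sd = 0.5,
                              sl_effect_mean = -1.5,
                              sl_effect_sd = 0,
                              guide_eff_min = 0.6,
                              guide_eff_max = 1,
                              promoter_hu6 = 1,
                              promoter_su6 = 0.9,
                              sigma0 = 0.15,
                              sigma1 = 0.1,
                              baseline_meanlog = 0,
                              baseline_sdlog = 0.5,
                              depth = 500,
                              dispersion = 0.05,
                              n_baseline = 3,
                              n_screen = 3,
                              timepoints = c(14, 28),
                              seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs),
              guides_per_gene = as.integer(guides_per_gene),
              frac_sl = frac_sl,
              gene_fitness_mean = gene_fitness_mean,
              gene_fitness_sd = gene_fitness_sd,
              sl_effect_mean = sl_effect_mean,
              sl_effect_sd = sl_effect_sd,
              guide_eff_min = guide_eff_min,
              guide_eff_max = guide_eff_max,
              promoter_hu6 = promoter_hu6,
              promoter_su6 = promoter_su6,
              sigma0 = sigma0, sigma1 = sigma1,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              depth = depth, dispersion = dispersion,
              n_baseline = as.integer(n_baseline),
              n_screen = as.integer(n_screen),
              timepoints = as.integer(timepoints),
              seed = as.integer(seed))
  if (cfg$n_pairs < 1) abort("n_pairs must be >= 1")
  if (cfg$guides_per_gene < 3 || cfg$guides_per_gene > 5) {
    abort("guides_per_gene must be in [3, 5]")
  }
  if (cfg$frac_sl < 0 || cfg$frac_sl > 1) abort("frac_sl must be in [0, 1]")
  if (cfg$depth <= 0) abort("depth must be > 0")
  if (cfg$dispersion <= 0) abort("dispersion must be > 0")
  if (cfg$n_baseline < 1 || cfg$n_screen < 1) {
    abort("replicate counts must be >= 1")
  }
  if (cfg$guide_eff_min < 0 || cfg$guide_eff_max > 1 ||
      cfg$guide_eff_min > cfg$guide_eff_max) {
    abort("guide efficiency range must satisfy 0 <= min <= max <= 1")
  }
  if (cfg$promoter_hu6 <= 0 || cfg$promoter_su6 <= 0) {
    abort("promoter multipliers must be > 0")
  }
  if (cfg$sigma0 < 0 || cfg$sigma1 < 0) abort("noise parameters must be >= 0")
  structure(cfg, class = "simulation_config")
}

random_spacers <- function(n, width = 20) {
  # unique random spacers; collisions at 4^20 are effectively impossible but
  # regenerate defensively anyway
  repeat {
    sp <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = "")
    }, character(1))
    if (!anyDuplicated(sp) && !FLUC_SPACER %in% sp) return(sp)
  }
}

#' Draw a ground-truthed library and effect set
#'
#' Builds a guide library via [enumerate_constructs()] for `n_pairs` disjoint
#' gene pairs and draws the latent effects the count simulation uses: per-gene
#' fitness, per-pair interaction epsilon (negative for the SL fraction),
#' per-guide efficiency, promoter multipliers and the heteroscedastic noise
#' parameters. All draws are reproducible from `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return List with elements `library` (a [guide_library()]) and `effects`
#'   (a `true_effects` list: tibbles `gene_fitness`, `pair_interaction`,
#'   `guide_efficiency`; named vectors `promoter_multiplier`, `noise`).
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  np <- cfg$n_pairs
  k <- cfg$guides_per_gene
  genes_a <- sprintf("GA%04d", seq_len(np))
  genes_b <- sprintf("GB%04d", seq_len(np))
  genes <- c(rbind(genes_a, genes_b))

  guide_rows <- tibble(
    gene = rep(genes, each = k),
    idx = rep(seq_len(k), times = length(genes))) %>%
    mutate(guide_id = sprintf("%s_g%d", .data$gene, .data$idx)) %>%
    select("guide_id", "gene")
  guides <- bind_rows(
    tibble(guide_id = "Fluc", gene = CONTROL_GENE, spacer = FLUC_SPACER,
           is_control = TRUE),
    guide_rows %>%
      mutate(spacer = random_spacers(nrow(guide_rows)), is_control = FALSE))

  pairs <- tibble(gene_a = pmin(genes_a, genes_b),
                  gene_b = pmax(genes_a, genes_b),
                  category = "other")

  control <- guides[guides$is_control, ]
  constructs <- purrr::map(seq_len(np), function(i) {
    ga <- guides[guides$gene == pairs$gene_a[i], ]
    gb <- guides[guides$gene == pairs$gene_b[i], ]
    enumerate_constructs(ga, gb, control)
  }) %>% list_rbind() %>% distinct()
  # the control+guide single-targeting constructs are unique per guide already
  lib <- guide_library(guides, pairs, constructs,
                       control_guide_id = control$guide_id[1])

  gene_fitness <- tibble(
    gene = genes,
    fitness = rnorm(length(genes), cfg$gene_fitness_mean, cfg$gene_fitness_sd))
  n_sl <- round(cfg$frac_sl * np)
  sl_idx <- if (n_sl > 0) sort(sample.int(np, n_sl)) else integer()
  eps <- numeric(np)
  if (n_sl > 0) {
    eps[sl_idx] <- cfg$sl_effect_mean + cfg$sl_effect_sd * rnorm(n_sl)
    # an "SL" pair is negative by definition; resampling from a wide sd could
    # cross zero, so truncate at a small negative value
    eps[sl_idx] <- pmin(eps[sl_idx], -1e-6)
  }
  pair_interaction <- pairs %>%
    select("gene_a", "gene_b") %>%
    mutate(epsilon = eps, is_sl = eps < 0)
  guide_efficiency <- tibble(
    guide_id = guides$guide_id,
    efficiency = ifelse(
      guides$is_control, 0,
      runif(nrow(guides), cfg$guide_eff_min, cfg$guide_eff_max)))

  effects <- structure(
    list(gene_fitness = gene_fitness,
         pair_interaction = pair_interaction,
         guide_efficiency = guide_efficiency,
         promoter_multiplier = c(hU6 = cfg$promoter_hu6,
                                 sU6 = cfg$promoter_su6),
         noise = c(sigma0 = cfg$sigma0, sigma1 = cfg$sigma1)),
    class = "true_effects")
  list(library = lib, effects = effects)
}

#' Noise-free true log2 fold change of constructs
#'
#' The generative counterpart of the Bliss-expectation residual model: a
#' paired construct with guide i (efficiency e_i) under hU6 targeting gene A
#' and guide j under sU6 targeting gene B has true log2FC
#' `e_i * m_hU6 * f_A + e_j * m_sU6 * f_B + e_i * e_j * epsilon_AB`,
#' scaled linearly by `timepoint / 28`. The interaction term requires both
#' genes to be cut, hence the `e_i * e_j` factor. For a single-targeting
#' construct the non-targeting control contributes zero.
#'
#' @param lib A [guide_library()].
#' @param effects A `true_effects` object from [simulate_truth()].
#' @param construct_ids Constructs to evaluate (default: all in `lib`).
#' @param timepoint Screen day (baseline samples use 0 fitness drift).
#' @return Tibble `construct_id`, `true_log2fc`.
#' @export
construct_true_log2fc <- function(lib, effects, construct_ids = NULL,
                                  timepoint = 28) {
  stopifnot(inherits(lib, "guide_library"), inherits(effects, "true_effects"))
  cs <- lib$constructs
  if (!is.null(construct_ids)) {
    unknown <- setdiff(construct_ids, cs$construct_id)
    if (length(unknown) > 0) {
      abort(sprintf("unknown construct '%s'", unknown[1]))
    }
    cs <- cs[match(construct_ids, cs$construct_id), ]
  }
  gene_of <- setNames(lib$guides$gene, lib$guides$guide_id)
  f <- setNames(effects$gene_fitness$fitness, effects$gene_fitness$gene)
  f[CONTROL_GENE] <- 0
  e <- setNames(effects$guide_efficiency$efficiency,
                effects$guide_efficiency$guide_id)
  eps <- setNames(effects$pair_interaction$epsilon,
                  pair_key(effects$pair_interaction$gene_a,
                           effects$pair_interaction$gene_b))
  m <- effects$promoter_multiplier
  gh <- unname(gene_of[cs$hu6_guide])
  gs <- unname(gene_of[cs$su6_guide])
  eh <- unname(e[cs$hu6_guide])
  es <- unname(e[cs$su6_guide])
  base <- eh * m[["hU6"]] * unname(f[gh]) + es * m[["sU6"]] * unname(f[gs])
  inter <- ifelse(cs$kind == "paired",
                  eh * es * dplyr::coalesce(unname(eps[pair_key(gh, gs)]), 0),
                  0)
  tibble(construct_id = cs$construct_id,
         true_log2fc = (base + inter) * (timepoint / 28))
}

#' Simulate a negative-binomial count matrix for a screen
#'
#' Baseline relative abundance per construct is drawn once from a log-normal
#' and shared across all samples. Baseline (Cas9-negative, day 7) sample
#' means equal that abundance scaled to the target depth; screen sample means
#' multiply it by `2^(true log2FC + noise)` where the noise s.d. grows with
#' the magnitude of the true effect (heteroscedastic by construction). Counts
#' are negative-binomial with dispersion `cfg$dispersion`.
#'
#' @param lib,effects Output of [simulate_truth()].
#' @param cfg The same [simulation_config()].
#' @return A `count_matrix` object: list with `counts` (wide tibble,
#'   `construct_id` + one integer column per sample), `samples` (tibble
#'   `sample_id`, `role`, `replicate`, `timepoint_days`) and `unassigned`
#'   (named integer, zero for simulated counts).
#' @export
simulate_counts <- function(lib, effects, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  cs <- lib$constructs
  n <- nrow(cs)
  w <- rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
  mu0 <- cfg$depth * w / mean(w)
  size <- 1 / cfg$dispersion

  samples <- bind_rows(
    tibble(sample_id = sprintf("baseline_r%d", seq_len(cfg$n_baseline)),
           role = "baseline", replicate = seq_len(cfg$n_baseline),
           timepoint_days = 7L),
    expand_grid(timepoint_days = cfg$timepoints,
                replicate = seq_len(cfg$n_screen)) %>%
      mutate(sample_id = sprintf("screen_d%d_r%d", .data$timepoint_days,
                                 .data$replicate),
             role = "screen") %>%
      select("sample_id", "role", "replicate", "timepoint_days"))

  true_by_tp <- lapply(unique(cfg$timepoints), function(tp) {
    construct_true_log2fc(lib, effects, timepoint = tp)$true_log2fc
  })
  names(true_by_tp) <- as.character(unique(cfg$timepoints))

  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    if (samples$role[j] == "baseline") {
      mu <- mu0
    } else {
      lfc <- true_by_tp[[as.character(samples$timepoint_days[j])]]
      noise_sd <- cfg$sigma0 + cfg$sigma1 * abs(lfc)
      mu <- mu0 * 2^(lfc + rnorm(n, 0, noise_sd))
    }
    counts[, j] <- as.integer(rnbinom(n, mu = mu, size = size))
  }
  new_count_matrix(
    counts = bind_cols(tibble(construct_id = cs$construct_id),
                       as_tibble(counts)),
    samples = samples,
    unassigned = setNames(rep(0L, nrow(samples)), samples$sample_id))
}

new_count_matrix <- function(counts, samples, unassigned) {
  stopifnot(identical(names(counts)[1], "construct_id"),
            all(samples$sample_id %in% names(counts)[-1]))
  structure(list(counts = as_tibble(counts), samples = as_tibble(samples),
                 unassigned = unassigned),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d constructs x %d samples (%d baseline, %d screen); %d unassigned reads\n",
              nrow(x$counts), nrow(x$samples),
              sum(x$samples$role == "baseline"),
              sum(x$samples$role == "screen"),
              sum(x$unassigned)))
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' Two sheets: counts (`construct_id` + one column per sample) and sample
#' metadata (`sample_id`, `role`, `replicate`, `timepoint_days`,
#' `unassigned`).
#'
#' @param cm A `count_matrix`.
#' @param counts_path,samples_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_count_matrix <- function(cm, counts_path, samples_path) {
  stopifnot(inherits(cm, "count_matrix"))
  readr::write_tsv(cm$counts, counts_path, progress = FALSE)
  readr::write_tsv(
    cm$samples %>%
      mutate(unassigned = unname(cm$unassigned[.data$sample_id])),
    samples_path, progress = FALSE)
  invisible(counts_path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  counts <- readr::read_tsv(
    counts_path,
    col_types = readr::cols(construct_id = readr::col_character(),
                            .default = readr::col_integer()),
    progress = FALSE)
  samples <- readr::read_tsv(
    samples_path,
    col_types = readr::cols(sample_id = readr::col_character(),
                            role = readr::col_character(),
                            replicate = readr::col_integer(),
                            timepoint_days = readr::col_integer(),
                            unassigned = readr::col_integer()),
    progress = FALSE)
  unassigned <- setNames(
    if ("unassigned" %in% names(samples)) samples$unassigned
    else rep(0L, nrow(samples)),
    samples$sample_id)
  samples$unassigned <- NULL
  new_count_matrix(counts, samples, unassigned)
}

#' Write the ground-truth effect tables of a simulation
#'
#' @param effects A `true_effects` object.
#' @param dir Output directory; writes `gene_fitness.tsv` and
#'   `pair_interaction.tsv`.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(effects, dir) {
  stopifnot(inherits(effects, "true_effects"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(effects$gene_fitness, file.path(dir, "gene_fitness.tsv"),
                   progress = FALSE)
  readr::write_tsv(effects$pair_interaction,
                   file.path(dir, "pair_interaction.tsv"), progress = FALSE)
  invisible(dir)
}
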