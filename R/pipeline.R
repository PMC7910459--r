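#' Declarative configuration for a full screen analysis run
#'
#' Collects paths and every stage parameter for [run_pipeline()], validating
#' each against its stage's preconditions before any work starts.
#'
#' @param outdir Output directory (created if absent).
#' @param library_path,counts_path,samples_path Optional input TSVs; when
#'   all are `NULL` a synthetic screen is simulated from `sim`.
#' @param sim A [simulation_config()] used when no counts are supplied.
#' @param normalization,pseudocount,min_baseline_count Quantification
#'   parameters (see [normalize_counts()], [compute_log2fc()]).
#' @param timepoint_screen Screen timepoint scored for interactions.
#' @param timepoint_essential Timepoint used for the lethal-in-isolation
#'   filter.
#' @param span,degree,bin_size,divisor Scoring parameters (see
#'   [compute_residuals()], [variance_adjust()]).
#' @param alpha,n_perm,threshold,essential_list Hit-calling parameters (see
#'   [test_pairs()], [adjust_and_call()], [call_single_gene_depletion()]).
#' @param seed Seed for the permutation nulls.
#' @param run_essential_filter Toggle for the lethal-in-isolation stage.
#' @return A `run_config` object.
#' @export
run_config <- function(outdir = tempfile("pairscreen_run_"),
                       library_path = NULL, counts_path = NULL,
                       samples_path = NULL,
                       sim = simulation_config(),
                       normalization = "median_ratio", pseudocount = 1,
                       min_baseline_count = 30,
                       timepoint_screen = 28, timepoint_essential = 14,
                       span = 0.75, degree = 2, bin_size = 200,
                       divisor = "variance",
                       alpha = 0.1, n_perm = 10000, threshold = 0.1,
                       essential_list = character(),
                       seed = 1L, run_essential_filter = TRUE) {
  if (bin_size < 10) abort("bin_size must be >= 10")
  if (alpha <= 0 || alpha > 0.5) abort("alpha must be in (0, 0.5]")
  if (n_perm < 100) abort("n_perm must be >= 100")
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  if (!divisor %in% c("variance", "sd")) {
    abort("divisor must be 'variance' or 'sd'")
  }
  if (!normalization %in% c("median_ratio", "total_count")) {
    abort("normalization must be 'median_ratio' or 'total_count'")
  }
  if (!degree %in% c(1, 2)) abort("degree must be 1 or 2")
  if (span <= 0 || span > 1) abort("span must be in (0, 1]")
  given <- c(library_path, counts_path, samples_path)
  if (length(given) > 0 && !all(file.exists(given))) {
    abort(sprintf("input path does not exist: %s",
                  given[!file.exists(given)][1]))
  }
  structure(
    list(outdir = outdir, library_path = library_path,
         counts_path = counts_path, samples_path = samples_path,
         sim = sim, normalization = normalization,
         pseudocount = pseudocount,
         min_baseline_count = min_baseline_count,
         timepoint_screen = timepoint_screen,
         timepoint_essential = timepoint_essential,
         span = span, degree = degree, bin_size = bin_size,
         divisor = divisor, alpha = alpha, n_perm = n_perm,
         threshold = threshold, essential_list = essential_list,
         seed = as.integer(seed),
         run_essential_filter = run_essential_filter),
    class = "run_config")
}

write_stage_output <- function(write_fn, path, sidecar) {
  partial <- paste0(path, ".partial")
  ok <- FALSE
  on.exit(if (!ok && file.exists(partial)) NULL, add = TRUE)
  write_fn(partial)
  file.rename(partial, path)
  ok <- TRUE
  jsonlite::write_json(sidecar, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full screen-analysis pipeline
#'
#' Executes `simulate (optional) -> fold changes -> residual scoring ->
#' hit calling -> report` with the parameters in a [run_config()]. Every
#' output TSV gets a JSON provenance sidecar recording the stage parameters,
#' the seed, and MD5 checksums of its inputs; identical configuration and
#' inputs give identical outputs.
#'
#' @param cfg A [run_config()].
#' @return List with `manifest` (tibble `stage`, `path`, `md5`), `results`
#'   (the final `pair_results` tibble), `essential`, `residuals`, and
#'   `report_path`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  manifest <- list()
  note <- function(stage, path) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, path = path,
      md5 = unname(tools::md5sum(path)))
  }
  params <- unclass(cfg)[c("normalization", "pseudocount",
                           "min_baseline_count", "timepoint_screen",
                           "timepoint_essential", "span", "degree",
                           "bin_size", "divisor", "alpha", "n_perm",
                           "threshold", "seed")]

  truth <- NULL
  if (is.null(cfg$counts_path)) {
    sim_out <- run_stage("simulate", {
      st <- simulate_truth(cfg$sim)
      cm <- simulate_counts(st$library, st$effects, cfg$sim)
      list(lib = st$library, effects = st$effects, cm = cm)
    })
    lib <- sim_out$lib
    cm <- sim_out$cm
    truth <- sim_out$effects
    lib_path <- file.path(cfg$outdir, "library.tsv")
    write_stage_output(function(p) write_library(lib, p), lib_path,
                       c(params, list(stage = "simulate",
                                      sim_seed = cfg$sim$seed)))
    note("simulate", lib_path)
    cpath <- file.path(cfg$outdir, "counts.tsv")
    spath <- file.path(cfg$outdir, "samples.tsv")
    write_stage_output(function(p) {
      write_count_matrix(cm, p, spath)
    }, cpath, c(params, list(stage = "simulate", sim_seed = cfg$sim$seed)))
    note("simulate", cpath)
    write_truth(truth, cfg$outdir)
    note("simulate", file.path(cfg$outdir, "pair_interaction.tsv"))
  } else {
    lib <- run_stage("load", load_library(cfg$library_path))
    cm <- run_stage("load",
                    read_count_matrix(cfg$counts_path, cfg$samples_path))
  }
  input_md5 <- if (!is.null(cfg$counts_path)) {
    unname(tools::md5sum(c(cfg$library_path, cfg$counts_path)))
  } else {
    unname(tools::md5sum(file.path(cfg$outdir, "counts.tsv")))
  }

  fc_all <- run_stage("fc", {
    norm <- normalize_counts(cm, method = cfg$normalization,
                             pseudocount = cfg$pseudocount)
    tps <- unique(c(cfg$timepoint_screen,
                    if (cfg$run_essential_filter) cfg$timepoint_essential))
    tps <- tps[tps %in% cm$samples$timepoint_days[cm$samples$role == "screen"]]
    lapply(setNames(tps, tps), function(tp) {
      compute_log2fc(norm, make_comparisons(cm$samples, tp),
                     min_baseline_count = cfg$min_baseline_count)
    })
  })
  fc <- fc_all[[as.character(cfg$timepoint_screen)]]
  if (is.null(fc)) {
    abort(sprintf("pipeline stage 'fc' failed: no screen samples at timepoint %s",
                  cfg$timepoint_screen))
  }
  fc_path <- file.path(cfg$outdir, "fold_changes.tsv")
  write_stage_output(function(p) readr::write_tsv(fc, p, progress = FALSE),
                     fc_path,
                     c(params, list(stage = "fc", input_md5 = input_md5)))
  note("fc", fc_path)

  rt <- run_stage("score", {
    compute_residuals(fc, lib, span = cfg$span, degree = cfg$degree) %>%
      variance_adjust(bin_size = cfg$bin_size, divisor = cfg$divisor)
  })
  rt_path <- file.path(cfg$outdir, "residuals.tsv")
  write_stage_output(function(p) write_residuals(rt, p), rt_path,
                     c(params, list(stage = "score", input_md5 = input_md5)))
  note("score", rt_path)

  results <- run_stage("call", {
    stats <- test_pairs(rt, alpha = cfg$alpha, n_perm = cfg$n_perm,
                        seed = cfg$seed)
    adjust_and_call(stats, threshold = cfg$threshold)
  })
  essential <- tibble(gene = character(), provenance = character())
  if (cfg$run_essential_filter &&
      as.character(cfg$timepoint_essential) %in% names(fc_all)) {
    essential <- run_stage("call", call_single_gene_depletion(
      fc_all[[as.character(cfg$timepoint_essential)]], lib,
      alpha = cfg$alpha, n_perm = cfg$n_perm, threshold = cfg$threshold,
      external = cfg$essential_list, seed = cfg$seed))
  } else if (length(cfg$essential_list) > 0) {
    essential <- tibble(gene = unique(cfg$essential_list),
                        provenance = "external_list")
  }
  results <- filter_hits(results, essential)
  res_path <- file.path(cfg$outdir, "results.tsv")
  write_stage_output(function(p) readr::write_tsv(results, p,
                                                  progress = FALSE),
                     res_path,
                     c(params, list(stage = "call", input_md5 = input_md5)))
  note("call", res_path)
  ess_path <- file.path(cfg$outdir, "essential_genes.tsv")
  write_stage_output(function(p) readr::write_tsv(essential, p,
                                                  progress = FALSE),
                     ess_path,
                     c(params, list(stage = "call", input_md5 = input_md5)))
  note("call", ess_path)

  report_path <- file.path(cfg$outdir, "report.txt")
  run_stage("report", write_report(results, truth = truth,
                                   path = report_path))
  note("report", report_path)

  list(manifest = list_rbind(manifest), results = results,
       essential = essential, residuals = rt, report_path = report_path)
}

#' Summarize screen results in a human-readable report
#'
#' Writes pairs tested, hits called and filter tallies; when simulation
#' ground truth is supplied, adds a confusion summary (sensitivity and
#' empirical false-discovery proportion) against the pairs simulated with a
#' negative interaction.
#'
#' @param results A `pair_results` tibble.
#' @param truth Optional `true_effects` from [simulate_truth()].
#' @param path Output text file.
#' @return List of the summary quantities, invisibly.
#' @export
write_report <- function(results, truth = NULL, path) {
  n_pairs <- nrow(results)
  n_hits <- sum(results$is_hit)
  filt <- table(results$filter_reason)
  lines <- c(
    "pairscreen results summary",
    "==========================",
    sprintf("pairs tested:          %d", n_pairs),
    sprintf("hits (t & RRA, neg.):  %d", n_hits),
    sprintf("filtered (essential):  %d",
            sum(results$filter_reason == "essential_gene_in_pair")),
    sprintf("flagged insufficient:  %d",
            sum(results$filter_reason == "insufficient_residuals")))
  summary <- list(pairs_tested = n_pairs, hits = n_hits,
                  filtered = as.list(filt))
  if (!is.null(truth)) {
    sl <- truth$pair_interaction %>% filter(.data$epsilon < 0)
    sl_keys <- pair_key(sl$gene_a, sl$gene_b)
    called <- results$gene_pair[results$is_hit]
    tp <- sum(called %in% sl_keys)
    fp <- length(called) - tp
    sens <- if (length(sl_keys) > 0) tp / length(sl_keys) else NA_real_
    fdp <- if (length(called) > 0) fp / length(called) else 0
    lines <- c(lines, "",
               sprintf("true SL pairs:         %d", length(sl_keys)),
               sprintf("recovered (TP):        %d", tp),
               sprintf("false positives:       %d", fp),
               sprintf("sensitivity:           %s",
                       ifelse(is.na(sens), "NA", sprintf("%.3f", sens))),
               sprintf("empirical FDP:         %.3f", fdp))
    summary <- c(summary, list(true_sl = length(sl_keys), tp = tp, fp = fp,
                               sensitivity = sens, fdp = fdp))
  }
  writeLines(lines, path)
  invisible(summary)
}
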