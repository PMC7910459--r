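test_that("FASTQ emission and counting round-trip exactly", {
  cfg <- simulation_config(n_pairs = 3, depth = 30, n_baseline = 1,
                           n_screen = 1, timepoints = 28, seed = 8)
  st <- simulate_truth(cfg)
  cm <- simulate_counts(st$library, st$effects, cfg)
  r1 <- withr::local_tempfile(fileext = "_R1.fastq")
  r2 <- withr::local_tempfile(fileext = "_R2.fastq")
  sample_id <- cm$samples$sample_id[1]
  simulate_fastq(cm, st$library, r1, r2, sample_id = sample_id, seed = 4)
  # read-pair conservation
  n_reads <- length(readLines(r1)) / 4
  expect_equal(n_reads, sum(cm$counts[[sample_id]]))
  got <- count_reads(r1, r2, st$library, max_mismatch = 0,
                     sample_id = sample_id)
  want <- cm$counts[, c("construct_id", sample_id)]
  merged <- dplyr::left_join(want, got$counts, by = "construct_id",
                             suffix = c(".want", ".got"))
  expect_equal(merged[[3]], merged[[2]])
  expect_equal(unname(got$unassigned), 0L)
})

test_that("foreign and ambiguous read pairs are counted unassigned", {
  lib <- tiny_library(2, 2)
  # hand-built FASTQ: one valid pair, one combination absent from the
  # library (two hU6-side guides), one unmatchable read
  sp <- setNames(lib$guides$spacer, lib$guides$guide_id)
  embed <- function(s) substr(paste0("GTGGAAAGGA", s,
                                     "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGC"),
                              1, 40)
  paired1 <- lib$constructs[lib$constructs$kind == "paired", ][1, ]
  r1_seqs <- c(embed(sp[[paired1$hu6_guide]]), embed(sp[["AAA_g1"]]),
               embed(strrep("A", 20)))
  r2_seqs <- c(embed(sp[[paired1$su6_guide]]), embed(sp[["AAA_g2"]]),
               embed(sp[["BBB_g1"]]))
  write_fq <- function(seqs, path) {
    writeLines(as.vector(rbind(sprintf("@r%d", seq_along(seqs)), seqs,
                               "+", strrep("I", 40))), path)
  }
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  write_fq(r1_seqs, r1)
  write_fq(r2_seqs, r2)
  got <- count_reads(r1, r2, lib, max_mismatch = 0)
  expect_equal(sum(got$counts[[2]]), 1L)
  expect_equal(got$counts[[2]][got$counts$construct_id == paired1$construct_id], 1L)
  expect_equal(unname(got$unassigned), 2L)
  # conservation: assigned + unassigned = input pairs
  expect_equal(sum(got$counts[[2]]) + unname(got$unassigned), 3L)

  # one substitution is tolerated at max_mismatch = 1
  r1b_seq <- r1_seqs[1]
  substr(r1b_seq, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                     substr(r1b_seq, 15, 15))[1]
  r1b <- withr::local_tempfile(fileext = ".fastq")
  write_fq(r1b_seq, r1b)
  r2b <- withr::local_tempfile(fileext = ".fastq")
  write_fq(r2_seqs[1], r2b)
  got0 <- count_reads(r1b, r2b, lib, max_mismatch = 0)
  expect_equal(sum(got0$counts[[2]]), 0L)
  got1 <- count_reads(r1b, r2b, lib, max_mismatch = 1)
  expect_equal(sum(got1$counts[[2]]), 1L)
})

test_that("desynchronized or empty FASTQ inputs are handled", {
  lib <- tiny_library()
  fq1 <- withr::local_tempfile(fileext = ".fastq")
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", strrep("A", 40), "+", strrep("I", 40)), fq1)
  file.create(fq2)
  expect_error(count_reads(fq1, fq2, lib), "desynchronized")
  empty1 <- withr::local_tempfile(fileext = ".fastq")
  empty2 <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty1, empty2)
  got <- count_reads(empty1, empty2, lib)
  expect_true(all(got$counts[[2]] == 0L))
  expect_equal(unname(got$unassigned), 0L)
})

test_that("normalization behaves under scaling and matches hand computation", {
  counts <- tibble::tibble(
    construct_id = c("c1", "c2", "c3"),
    s1 = c(10L, 20L, 40L),
    s2 = c(20L, 40L, 80L))
  samples <- tibble::tibble(sample_id = c("s1", "s2"),
                            role = c("baseline", "screen"),
                            replicate = c(1L, 1L),
                            timepoint_days = c(7L, 28L))
  cm <- pairscreen:::new_count_matrix(counts, samples,
                                      c(s1 = 0L, s2 = 0L))
  # total_count: column scaled x2 is restored to equality
  norm <- normalize_counts(cm, method = "total_count", pseudocount = 1)
  expect_equal(norm$values$s1, norm$values$s2)

  # median_ratio hand computation: gm = sqrt(s1*s2) per row;
  # sf_j = median(count_ij / gm_i)
  norm2 <- normalize_counts(cm, method = "median_ratio", pseudocount = 1)
  gm <- sqrt(counts$s1 * counts$s2)
  sf1 <- median(counts$s1 / gm)
  sf2 <- median(counts$s2 / gm)
  expect_equal(norm2$values$s1, counts$s1 / sf1 + 1)
  expect_equal(norm2$values$s2, counts$s2 / sf2 + 1)
  # identical columns normalize identically
  cm_id <- pairscreen:::new_count_matrix(
    tibble::tibble(construct_id = c("c1", "c2"), s1 = c(5L, 9L),
                   s2 = c(5L, 9L)),
    samples, c(s1 = 0L, s2 = 0L))
  norm3 <- normalize_counts(cm_id)
  expect_equal(norm3$values$s1, norm3$values$s2)

  cm_zero <- pairscreen:::new_count_matrix(
    tibble::tibble(construct_id = c("c1", "c2"), s1 = c(5L, 9L),
                   s2 = c(0L, 0L)),
    samples, c(s1 = 0L, s2 = 0L))
  expect_error(normalize_counts(cm_zero), "all-zero")
  expect_error(normalize_counts(cm, pseudocount = 0), "pseudocount")
})

test_that("comparisons are the replicate cross product at a timepoint", {
  mk <- function(nb, ns, tp = 28L) {
    dplyr::bind_rows(
      tibble::tibble(sample_id = sprintf("b%d", seq_len(nb)),
                     role = "baseline", replicate = seq_len(nb),
                     timepoint_days = 7L),
      tibble::tibble(sample_id = sprintf("s%d", seq_len(ns)),
                     role = "screen", replicate = seq_len(ns),
                     timepoint_days = tp))
  }
  expect_equal(nrow(make_comparisons(mk(3, 3), 28)), 9)
  expect_equal(nrow(make_comparisons(mk(1, 1), 28)), 1)
  expect_equal(nrow(make_comparisons(mk(3, 2), 28)), 6)
  expect_error(make_comparisons(mk(3, 3), 14), "no screen samples")
  expect_error(make_comparisons(mk(3, 3)[4:6, ], 28), "no baseline")
})

test_that("log2 fold changes match direct recomputation and flag low counts", {
  counts <- tibble::tibble(
    construct_id = sprintf("c%d", 1:4),
    b1 = c(100L, 400L, 25L, 1000L),
    s1 = c(100L, 100L, 50L, 4000L))
  samples <- tibble::tibble(sample_id = c("b1", "s1"),
                            role = c("baseline", "screen"),
                            replicate = c(1L, 1L),
                            timepoint_days = c(7L, 28L))
  cm <- pairscreen:::new_count_matrix(counts, samples, c(b1 = 0L, s1 = 0L))
  norm <- normalize_counts(cm, method = "total_count", pseudocount = 1e-6)
  cmp <- make_comparisons(samples, 28)
  fc <- compute_log2fc(norm, cmp, min_baseline_count = 30)
  # spreadsheet recomputation (total_count scaling to the mean total)
  tot <- mean(c(sum(counts$b1), sum(counts$s1)))
  nb <- counts$b1 / (sum(counts$b1) / tot) + 1e-6
  ns <- counts$s1 / (sum(counts$s1) / tot) + 1e-6
  expect_equal(fc$observed_log2fc, log2(ns) - log2(nb))
  expect_equal(fc$low_count_flag, c(FALSE, FALSE, TRUE, FALSE))

  # screen == baseline -> 0; screen = baseline / 4 -> -2 as pseudocount -> 0
  cm_eq <- pairscreen:::new_count_matrix(
    tibble::tibble(construct_id = c("c1", "c2", "c3"),
                   b1 = c(100L, 100L, 400L), s1 = c(100L, 100L, 100L)),
    samples, c(b1 = 0L, s1 = 0L))
  norm_eq <- normalize_counts(cm_eq, method = "median_ratio",
                              pseudocount = 1e-9)
  # the two stable constructs pin the median-ratio size factors at 1, so
  # c1 stays flat and c3 is a clean 4-fold dropout
  fc_eq <- compute_log2fc(norm_eq, cmp, min_baseline_count = 1)
  expect_equal(fc_eq$observed_log2fc[1], 0, tolerance = 1e-6)
  expect_equal(fc_eq$observed_log2fc[3], -2, tolerance = 1e-6)

  # antisymmetry under swapping screen and baseline
  rev_cmp <- tibble::tibble(comparison_id = "rev",
                            screen_sample = "b1", baseline_sample = "s1")
  fc_rev <- compute_log2fc(norm, rev_cmp, min_baseline_count = 0)
  expect_equal(fc_rev$observed_log2fc, -fc$observed_log2fc)

  expect_error(
    compute_log2fc(norm, tibble::tibble(comparison_id = "x",
                                        screen_sample = "nope",
                                        baseline_sample = "b1")),
    "unknown sample")
})
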