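# Fixed amplicon context for simulated reads: both reads are forward reads,
# each carrying one spacer at a constant offset inside constant vector
# sequence (no reverse complement of read 2).
FASTQ_PREFIX <- "GTGGAAAGGA"        # 10 nt upstream vector context
FASTQ_SUFFIX <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGC"  # scaffold-side filler
FASTQ_OFFSET <- nchar(FASTQ_PREFIX)
FASTQ_READ_LENGTH <- 40L

#' Emit paired FASTQ files for one sample of a count matrix
#'
#' For every construct, writes exactly `count` read pairs: read 1 carries the
#' hU6 spacer and read 2 the sU6 spacer, each embedded at a fixed offset
#' (10 nt) in constant vector context, mimicking a two-forward-read
#' sequencing strategy. Read order is shuffled reproducibly under `seed`.
#'
#' @param cm A `count_matrix`.
#' @param lib The [guide_library()] the counts refer to.
#' @param out_r1,out_r2 Output FASTQ paths.
#' @param sample_id Which sample's column to emit (default: first sample).
#' @param seed Integer seed for the read shuffle.
#' @return Invisible named vector of the two paths.
#' @export
simulate_fastq <- function(cm, lib, out_r1, out_r2,
                           sample_id = cm$samples$sample_id[1], seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"), inherits(lib, "guide_library"))
  if (!sample_id %in% names(cm$counts)) {
    abort(sprintf("sample '%s' not present in count matrix", sample_id))
  }
  counts <- cm$counts[[sample_id]]
  spacer <- setNames(lib$guides$spacer, lib$guides$guide_id)
  cs <- lib$constructs[match(cm$counts$construct_id,
                             lib$constructs$construct_id), ]
  if (anyNA(cs$construct_id)) {
    abort("count matrix contains constructs absent from the library")
  }
  embed <- function(sp) {
    full <- paste0(FASTQ_PREFIX, sp, FASTQ_SUFFIX)
    substr(full, 1L, FASTQ_READ_LENGTH)
  }
  idx <- rep.int(seq_along(counts), counts)
  set.seed(seed)
  idx <- idx[sample.int(length(idx))]
  r1 <- embed(unname(spacer[cs$hu6_guide]))[idx]
  r2 <- embed(unname(spacer[cs$su6_guide]))[idx]
  ids <- sprintf("read%07d", seq_along(idx))
  qual <- Biostrings::BStringSet(
    rep(strrep("I", FASTQ_READ_LENGTH), length(idx)))
  w1 <- Biostrings::DNAStringSet(r1)
  w2 <- Biostrings::DNAStringSet(r2)
  names(w1) <- ids
  names(w2) <- ids
  Biostrings::writeXStringSet(w1, out_r1, format = "fastq", qualities = qual)
  Biostrings::writeXStringSet(w2, out_r2, format = "fastq", qualities = qual)
  invisible(c(r1 = out_r1, r2 = out_r2))
}

# Match anchored spacer extracts against a named spacer->guide map.
# Returns guide_id per read, NA when unmatched or ambiguous.
match_spacers <- function(seqs, spacer_map, max_mismatch) {
  lens <- sort(unique(nchar(names(spacer_map))), decreasing = TRUE)
  hit <- rep(NA_character_, length(seqs))
  ambiguous <- rep(FALSE, length(seqs))
  for (L in lens) {
    sub <- substr(seqs, FASTQ_OFFSET + 1L, FASTQ_OFFSET + L)
    cand <- unname(spacer_map[sub])
    clash <- !is.na(hit) & !is.na(cand)
    ambiguous[clash] <- TRUE    # a shorter spacer is a prefix of a longer one
    take <- is.na(hit) & !is.na(cand)
    hit[take] <- cand[take]
  }
  if (max_mismatch >= 1L) {
    todo <- which(is.na(hit))
    if (length(todo) > 0) {
      by_len <- split(names(spacer_map), nchar(names(spacer_map)))
      sp_mats <- lapply(by_len, function(sp) {
        vapply(strsplit(sp, ""), identity, character(nchar(sp[1])))
      })
      for (i in todo) {
        found <- character()
        for (L in names(by_len)) {
          Ln <- as.integer(L)
          ext <- substr(seqs[i], FASTQ_OFFSET + 1L, FASTQ_OFFSET + Ln)
          if (nchar(ext) < Ln) next
          rc <- strsplit(ext, "")[[1]]
          mm <- colSums(sp_mats[[L]] != rc)
          found <- c(found, unname(spacer_map[by_len[[L]][mm <= max_mismatch]]))
        }
        if (length(found) == 1) {
          hit[i] <- found
        } else if (length(found) > 1) {
          ambiguous[i] <- TRUE
        }
      }
    }
  }
  hit[ambiguous] <- NA_character_
  hit
}

#' Count paired reads against a guide library
#'
#' Assigns each read pair to a construct by anchored spacer matching: read 1
#' must match the hU6-slot spacer and read 2 the sU6-slot spacer of the same
#' library construct at the fixed amplicon offset, each within
#' `max_mismatch` substitutions. Pairs whose guide combination is absent from
#' the library, or whose match is ambiguous at `max_mismatch = 1`, are
#' counted as unassigned; assigned + unassigned always equals the number of
#' input read pairs.
#'
#' @param r1,r2 Paths to the synchronized paired FASTQ files.
#' @param lib A [guide_library()].
#' @param max_mismatch 0 (exact) or 1 (Hamming distance 1, unambiguous only).
#' @param sample_id,role,replicate,timepoint_days Metadata for the resulting
#'   single-sample count matrix.
#' @return A `count_matrix` with one sample.
#' @export
count_reads <- function(r1, r2, lib, max_mismatch = 0L,
                        sample_id = "sample1", role = "screen",
                        replicate = 1L, timepoint_days = 28L) {
  stopifnot(inherits(lib, "guide_library"))
  if (!max_mismatch %in% c(0L, 1L)) abort("max_mismatch must be 0 or 1")
  s1 <- as.character(Biostrings::readDNAStringSet(r1, format = "fastq"))
  s2 <- as.character(Biostrings::readDNAStringSet(r2, format = "fastq"))
  if (length(s1) != length(s2)) {
    abort(sprintf(
      "desynchronized FASTQ files: %d reads in r1 but %d in r2",
      length(s1), length(s2)))
  }
  spacer_map <- setNames(lib$guides$guide_id, lib$guides$spacer)
  if (anyDuplicated(lib$guides$spacer)) {
    abort("library contains duplicate spacers; counting would be ambiguous")
  }
  g1 <- match_spacers(unname(s1), spacer_map, max_mismatch)
  g2 <- match_spacers(unname(s2), spacer_map, max_mismatch)
  key <- paste0(g1, ":", g2)
  valid <- paste0(lib$constructs$hu6_guide, ":", lib$constructs$su6_guide)
  assigned <- !is.na(g1) & !is.na(g2) & key %in% valid
  tab <- table(factor(key[assigned], levels = valid))
  counts <- tibble(construct_id = lib$constructs$construct_id,
                   !!sample_id := as.integer(tab))
  samples <- tibble(sample_id = sample_id, role = role,
                    replicate = as.integer(replicate),
                    timepoint_days = as.integer(timepoint_days))
  new_count_matrix(counts, samples,
                   setNames(sum(!assigned), sample_id))
}
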