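#' Construct a guide library object
#'
#' A guide library bundles the three tables describing a dual-promoter
#' paired-gRNA library: the guides (spacer sequences and target genes), the
#' gene pairs under study, and every construct (cassette) in the library with
#' its promoter-slot assignment. Constructs are either `paired` (two targeting
#' guides, one per promoter) or `single_targeting` (the non-targeting control
#' guide under the hU6 promoter and a targeting guide under the sU6 promoter,
#' measuring single-gene fitness).
#'
#' @param guides Tibble with columns `guide_id`, `gene`, `spacer`,
#'   `is_control`. Spacers must be 19-20 nt of A/C/G/T; the control guide's
#'   gene must be the reserved symbol `"CONTROL"`.
#' @param pairs Tibble with columns `gene_a`, `gene_b` and optionally
#'   `category` (one of `paralogue`, `mutual_exclusivity`, `synlethdb`,
#'   `other`). Pairs are stored in canonical lexicographic order.
#' @param constructs Tibble with columns `construct_id`, `hu6_guide`,
#'   `su6_guide`, `kind`.
#' @param control_guide_id Identifier of the non-targeting control guide.
#'
#' @return A `guide_library` object (a named list of the three tibbles plus
#'   `control_guide_id`).
#' @seealso [enumerate_constructs()], [validate_library()], [load_library()]
#' @export
guide_library <- function(guides, pairs, constructs, control_guide_id) {
  guides <- as_tibble(guides)
  pairs <- as_tibble(pairs)
  constructs <- as_tibble(constructs)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      abort(sprintf("%s table is missing column(s): %s", what,
                    paste(miss, collapse = ", ")))
    }
  }
  need(guides, c("guide_id", "gene", "spacer", "is_control"), "guides")
  need(constructs, c("construct_id", "hu6_guide", "su6_guide", "kind"),
       "constructs")
  need(pairs, c("gene_a", "gene_b"), "pairs")
  if (!"category" %in% names(pairs)) pairs$category <- "other"

  bad <- which(!grepl("^[ACGT]{19,20}$", guides$spacer))
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed spacer in guides row %d (guide_id '%s', field 'spacer'): %s",
      bad[1], guides$guide_id[bad[1]], guides$spacer[bad[1]]))
  }
  if (anyDuplicated(guides$guide_id)) {
    abort(sprintf("duplicate guide_id: %s",
                  guides$guide_id[duplicated(guides$guide_id)][1]))
  }
  if (anyDuplicated(constructs$construct_id)) {
    abort(sprintf("duplicate construct_id: %s",
                  constructs$construct_id[duplicated(constructs$construct_id)][1]))
  }
  unknown <- setdiff(c(constructs$hu6_guide, constructs$su6_guide),
                     guides$guide_id)
  if (length(unknown) > 0) {
    abort(sprintf("construct references undefined guide_id '%s'", unknown[1]))
  }
  if (!control_guide_id %in% guides$guide_id) {
    abort(sprintf("control_guide_id '%s' not present in guides",
                  control_guide_id))
  }
  # canonical unordered storage of pairs
  pairs <- pairs %>%
    mutate(key = pair_key(.data$gene_a, .data$gene_b)) %>%
    mutate(gene_a = pmin(.data$gene_a, .data$gene_b),
           gene_b = pmax(.data$gene_a, .data$gene_b)) %>%
    distinct(.data$key, .keep_all = TRUE) %>%
    select("gene_a", "gene_b", "category")
  if (any(pairs$gene_a == pairs$gene_b)) {
    abort("a gene pair must consist of two distinct genes")
  }

  structure(
    list(guides = guides, pairs = pairs, constructs = constructs,
         control_guide_id = control_guide_id),
    class = "guide_library")
}

#' @export
print.guide_library <- function(x, ...) {
  n_paired <- sum(x$constructs$kind == "paired")
  n_single <- sum(x$constructs$kind == "single_targeting")
  cat(sprintf(
    "<guide_library> %d guides (%d targeting), %d gene pairs, %d constructs (%d paired + %d single-targeting)\n",
    nrow(x$guides), sum(!x$guides$is_control), nrow(x$pairs),
    nrow(x$constructs), n_paired, n_single))
  invisible(x)
}

#' Enumerate constructs for one gene pair
#'
#' Expands the all-versus-all guide pairing for one gene pair: every guide of
#' gene A is placed under the hU6 promoter and combined with every guide of
#' gene B under the sU6 promoter (a single fixed orientation), and each
#' targeting guide is additionally paired with the non-targeting control
#' guide (control under hU6, targeting guide under sU6) to measure
#' single-gene effects.
#'
#' @param guides_a,guides_b Tibbles of guides (columns as in
#'   [guide_library()]) for the two genes; 1-5 guides each.
#' @param control One-row tibble for the control guide (`is_control` TRUE).
#'
#' @return Tibble of `|A| * |B|` paired plus `|A| + |B|` single-targeting
#'   constructs with columns `construct_id`, `hu6_guide`, `su6_guide`,
#'   `kind`, in deterministic (A-major) order.
#' @export
enumerate_constructs <- function(guides_a, guides_b, control) {
  guides_a <- as_tibble(guides_a)
  guides_b <- as_tibble(guides_b)
  control <- as_tibble(control)
  if (nrow(guides_a) < 1 || nrow(guides_b) < 1) {
    abort("each gene needs at least one guide")
  }
  if (nrow(guides_a) > 5 || nrow(guides_b) > 5) {
    abort("at most 5 guides per gene are supported")
  }
  if (nrow(control) != 1 || !isTRUE(control$is_control[1])) {
    abort("`control` must be a single guide flagged is_control = TRUE")
  }
  paired <- expand_grid(hu6_guide = guides_a$guide_id,
                        su6_guide = guides_b$guide_id) %>%
    mutate(construct_id = paste0(.data$hu6_guide, ":", .data$su6_guide),
           kind = "paired")
  singles <- tibble(
    hu6_guide = control$guide_id[1],
    su6_guide = c(guides_a$guide_id, guides_b$guide_id)) %>%
    mutate(construct_id = paste0(.data$hu6_guide, ":", .data$su6_guide),
           kind = "single_targeting")
  bind_rows(paired, singles) %>%
    select("construct_id", "hu6_guide", "su6_guide", "kind")
}

#' Validate a guide library against its structural invariants
#'
#' Checks referential integrity, the promoter convention (control guide under
#' hU6 in single-targeting constructs, two targeting guides of a registered
#' pair in paired constructs), completeness of the all-versus-all guide
#' product for every pair, and the presence of exactly one single-targeting
#' construct per targeting guide.
#'
#' @param lib A [guide_library()].
#' @return Tibble of violations with columns `check` and `detail`; zero rows
#'   means the library is valid.
#' @export
validate_library <- function(lib) {
  stopifnot(inherits(lib, "guide_library"))
  v <- list()
  add <- function(check, detail) {
    v[[length(v) + 1]] <<- tibble(check = check, detail = detail)
  }
  g <- lib$guides
  cs <- lib$constructs
  gene_of <- setNames(g$gene, g$guide_id)
  is_ctrl <- setNames(g$is_control, g$guide_id)

  orphan <- g$guide_id[!g$is_control &
                         !g$guide_id %in% c(cs$hu6_guide, cs$su6_guide)]
  for (id in orphan) add("orphan_guide", sprintf("guide '%s' appears in no construct", id))

  single <- cs[cs$kind == "single_targeting", ]
  bad_hu6 <- single$construct_id[!is_ctrl[single$hu6_guide]]
  for (id in bad_hu6) {
    add("promoter_convention",
        sprintf("single-targeting construct '%s' has a targeting guide under hU6", id))
  }
  bad_su6 <- single$construct_id[is_ctrl[single$su6_guide]]
  for (id in bad_su6) {
    add("promoter_convention",
        sprintf("single-targeting construct '%s' has the control guide under sU6", id))
  }
  targeting <- g$guide_id[!g$is_control]
  n_single <- table(factor(single$su6_guide[!is_ctrl[single$su6_guide]],
                           levels = targeting))
  for (id in names(n_single)[n_single == 0]) {
    add("missing_single_targeting",
        sprintf("guide '%s' has no single-targeting construct", id))
  }
  for (id in names(n_single)[n_single > 1]) {
    add("duplicate_single_targeting",
        sprintf("guide '%s' has %d single-targeting constructs", id, n_single[[id]]))
  }

  paired <- cs[cs$kind == "paired", ]
  if (nrow(paired) > 0) {
    pg <- tibble(construct_id = paired$construct_id,
                 gene_h = unname(gene_of[paired$hu6_guide]),
                 gene_s = unname(gene_of[paired$su6_guide]))
    ctrl_in_pair <- pg$construct_id[is_ctrl[paired$hu6_guide] |
                                      is_ctrl[paired$su6_guide]]
    for (id in ctrl_in_pair) {
      add("promoter_convention",
          sprintf("paired construct '%s' contains the control guide", id))
    }
    pg$key <- pair_key(pg$gene_h, pg$gene_s)
    known <- pair_key(lib$pairs$gene_a, lib$pairs$gene_b)
    unknown <- pg[!pg$key %in% known & !pg$construct_id %in% ctrl_in_pair, ]
    for (i in seq_len(nrow(unknown))) {
      add("unregistered_pair",
          sprintf("paired construct '%s' targets (%s, %s), not a registered pair",
                  unknown$construct_id[i], unknown$gene_h[i], unknown$gene_s[i]))
    }
  }

  # completeness of guide x guide product per registered pair
  guides_by_gene <- split(g$guide_id[!g$is_control], g$gene[!g$is_control])
  have <- paste0(paired$hu6_guide, ":", paired$su6_guide)
  for (i in seq_len(nrow(lib$pairs))) {
    ga <- guides_by_gene[[lib$pairs$gene_a[i]]] %||% character()
    gb <- guides_by_gene[[lib$pairs$gene_b[i]]] %||% character()
    combos <- expand_grid(a = ga, b = gb)
    # either orientation satisfies coverage of the (guide_a, guide_b) combo
    ok <- paste0(combos$a, ":", combos$b) %in% have |
      paste0(combos$b, ":", combos$a) %in% have
    for (j in which(!ok)) {
      add("incomplete_product",
          sprintf("pair (%s, %s): no paired construct for guides (%s, %s)",
                  lib$pairs$gene_a[i], lib$pairs$gene_b[i],
                  combos$a[j], combos$b[j]))
    }
  }

  if (length(v) == 0) {
    tibble(check = character(), detail = character())
  } else {
    bind_rows(v)
  }
}

#' Map paired constructs to their gene pair
#'
#' @param lib A [guide_library()].
#' @return Tibble `construct_id`, `gene_pair` (canonical `"A|B"` key) for all
#'   paired constructs, plus `target_gene` for single-targeting constructs
#'   (NA for paired, and vice versa).
#' @export
construct_annotation <- function(lib) {
  gene_of <- setNames(lib$guides$gene, lib$guides$guide_id)
  lib$constructs %>%
    mutate(gene_h = unname(gene_of[.data$hu6_guide]),
           gene_s = unname(gene_of[.data$su6_guide]),
           gene_pair = ifelse(.data$kind == "paired",
                              pair_key(.data$gene_h, .data$gene_s), NA),
           target_gene = ifelse(.data$kind == "single_targeting",
                                .data$gene_s, NA)) %>%
    select("construct_id", "kind", "hu6_guide", "su6_guide",
           "gene_pair", "target_gene")
}

#' Read a guide library from TSV
#'
#' Accepts either a single combined file with a `record_type` column
#' (`guide`, `pair` or `construct` rows) or separate guides and constructs
#' sheets. Column layout: guides need `guide_id`, `gene`, `spacer`,
#' `is_control`; constructs need `construct_id`, `hu6_guide`, `su6_guide`,
#' `kind`; pair rows (optional; inferred from paired constructs when absent)
#' need `gene_a`, `gene_b` and optionally `category`.
#'
#' @param path Path to the combined TSV, or the guides sheet.
#' @param constructs_path Optional path to a separate constructs sheet.
#' @return A [guide_library()].
#' @export
load_library <- function(path, constructs_path = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  read1 <- function(p) {
    readr::read_tsv(p, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  if (is.null(constructs_path)) {
    raw <- read1(path)
    if (!"record_type" %in% names(raw)) {
      abort("combined library file must have a 'record_type' column")
    }
    guides <- raw %>% filter(.data$record_type == "guide")
    constructs <- raw %>% filter(.data$record_type == "construct")
    pair_rows <- raw %>% filter(.data$record_type == "pair")
  } else {
    guides <- read1(path)
    constructs <- read1(constructs_path)
    pair_rows <- tibble()
  }
  for (col in c("guide_id", "gene", "spacer", "is_control")) {
    if (!col %in% names(guides) || all(is.na(guides[[col]]))) {
      abort(sprintf("guides sheet is missing column '%s'", col))
    }
  }
  for (col in c("construct_id", "hu6_guide", "su6_guide", "kind")) {
    if (!col %in% names(constructs) || all(is.na(constructs[[col]]))) {
      abort(sprintf("constructs sheet is missing column '%s'", col))
    }
  }
  guides <- guides %>%
    transmute(guide_id = .data$guide_id, gene = .data$gene,
              spacer = .data$spacer,
              is_control = tolower(.data$is_control) %in% c("true", "t", "1"))
  constructs <- constructs %>%
    select("construct_id", "hu6_guide", "su6_guide", "kind")
  if (anyDuplicated(constructs)) {
    dup <- constructs$construct_id[duplicated(constructs)][1]
    abort(sprintf("duplicate construct row: '%s'", dup))
  }
  ctrl <- guides$guide_id[guides$is_control]
  if (length(ctrl) != 1) {
    abort(sprintf("library must contain exactly one control guide (found %d)",
                  length(ctrl)))
  }
  gene_of <- setNames(guides$gene, guides$guide_id)
  if (nrow(pair_rows) > 0 && all(c("gene_a", "gene_b") %in% names(pair_rows))) {
    pairs <- tibble(
      gene_a = pair_rows$gene_a,
      gene_b = pair_rows$gene_b,
      category = if ("category" %in% names(pair_rows)) {
        dplyr::coalesce(pair_rows$category, "other")
      } else "other")
  } else {
    paired <- constructs[constructs$kind == "paired", ]
    unknown <- setdiff(c(paired$hu6_guide, paired$su6_guide), guides$guide_id)
    if (length(unknown) > 0) {
      abort(sprintf("construct references undefined guide_id '%s'", unknown[1]))
    }
    pairs <- tibble(gene_a = unname(gene_of[paired$hu6_guide]),
                    gene_b = unname(gene_of[paired$su6_guide]),
                    category = "other") %>% distinct()
  }
  guide_library(guides, pairs, constructs, control_guide_id = ctrl)
}

#' Write a guide library to a combined TSV
#'
#' Inverse of [load_library()]: the output round-trips to an identical
#' library.
#'
#' @param lib A [guide_library()].
#' @param path Output path (tab-separated, UTF-8, header row).
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "guide_library"))
  g <- lib$guides %>%
    mutate(record_type = "guide",
           is_control = ifelse(.data$is_control, "true", "false"))
  p <- lib$pairs %>% mutate(record_type = "pair")
  cs <- lib$constructs %>% mutate(record_type = "construct")
  out <- bind_rows(g, p, cs) %>%
    select("record_type", "guide_id", "gene", "spacer", "is_control",
           "gene_a", "gene_b", "category",
           "construct_id", "hu6_guide", "su6_guide", "kind")
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
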