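# Core seed domain: extraction, viability lookup, classification, ranking,
# cross-screen statistics and shRNA seed-viability coupling.

RNA_BASES <- c("A", "C", "G", "U")

#' All 4096 6mer seeds
#'
#' Enumerates the complete seed universe (RNA alphabet) in lexicographic
#' order: every 6-character string over A, C, G, U.
#'
#' @return Character vector of length 4096.
#' @export
#' @examples
#' head(all_seeds())
all_seeds <- function() {
  grid <- expand.grid(rep(list(RNA_BASES), 6), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  sort(do.call(paste0, grid))
}

normalize_rna <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains non-nucleotide characters (first offender: '%s')",
      what, x[bad][1]
    ), class = "seedtox_alphabet_error")
  }
  x
}

assert_seed6 <- function(seed) {
  seed <- normalize_rna(seed, "seed")
  if (any(nchar(seed) != 6L)) {
    abort("a 6mer seed must be exactly 6 nucleotides long",
          class = "seedtox_length_error")
  }
  seed
}

#' Extract the 6mer seed from a guide strand
#'
#' The seed is positions 2-7 (1-based) of the guide strand. DNA input is
#' accepted; T is normalized to U.
#'
#' @param guide Character vector of guide-strand sequences, each at least
#'   7 nt, over the alphabet A/C/G/U/T.
#' @return Character vector of 6mer seeds (RNA alphabet).
#' @export
#' @examples
#' extract_guide_seed("UGGCAGUACAUGUAAACCAAA") # "GGCAGU" (miR-34a-5p seed)
extract_guide_seed <- function(guide) {
  guide <- normalize_rna(guide, "guide")
  if (any(nchar(guide) < 7L)) {
    abort("guide strand must be at least 7 nt to contain a seed (positions 2-7)",
          class = "seedtox_length_error")
  }
  substr(guide, 2L, 7L)
}

#' Reverse-complement seed match sequence
#'
#' Returns the exact target-site sequence a seed pairs with: the reverse
#' complement of the 6mer, read 5'->3', in RNA or DNA space.
#'
#' @param seed Character vector of 6mer seeds.
#' @param alphabet `"DNA"` (default, for scanning mRNA-space sequences) or
#'   `"RNA"`.
#' @return Character vector of 6-character match sequences.
#' @export
#' @examples
#' seed_match_sequence("GGCAGU") # "ACTGCC"
seed_match_sequence <- function(seed, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  seed <- assert_seed6(seed)
  comp <- chartr("ACGU", "UGCA", seed)
  rc <- vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
  if (alphabet == "DNA") rc <- chartr("U", "T", rc)
  rc
}

new_viability_table <- function(tbl, provenance = NA_character_) {
  cell_lines <- setdiff(names(tbl), c("seed", "duplex_id"))
  structure(
    as_tibble(tbl),
    class = unique(c("seed_viability_tbl", class(as_tibble(tbl)))),
    cell_lines = cell_lines,
    complete = nrow(tbl) == 4096L && !anyDuplicated(tbl$seed),
    provenance = provenance
  )
}

validate_viability_tbl <- function(tbl, context = "viability table") {
  if (!"seed" %in% names(tbl)) {
    abort(paste0(context, ": missing 'seed' column"),
          class = "seedtox_format_error")
  }
  tbl$seed <- assert_seed6(tbl$seed)
  if (anyDuplicated(tbl$seed)) {
    dup <- tbl$seed[duplicated(tbl$seed)][1]
    abort(sprintf("%s: duplicate seed '%s'", context, dup),
          class = "seedtox_format_error")
  }
  value_cols <- setdiff(names(tbl), c("seed", "duplex_id"))
  if (length(value_cols) == 0L) {
    abort(paste0(context, ": no cell-line viability columns"),
          class = "seedtox_format_error")
  }
  for (cl in value_cols) {
    if (!is.numeric(tbl[[cl]])) {
      abort(sprintf("%s: non-numeric viability in column '%s'", context, cl),
            class = "seedtox_format_error")
    }
    if (any(tbl[[cl]] < 0, na.rm = TRUE)) {
      abort(sprintf("%s: negative viability in column '%s'", context, cl),
            class = "seedtox_format_error")
    }
  }
  new_viability_table(as_tibble(tbl))
}

#' Read / write a seed viability table
#'
#' The TSV carries one row per seed: a `seed` column (6 characters, T or U
#' accepted), one numeric percent-viability column per cell line (0-100
#' scale; values above 100 permitted, negatives not), and an optional
#' `duplex_id` column. The returned tibble carries the cell-line names and a
#' completeness flag (all 4096 seeds present) as attributes.
#'
#' @param path File path of a tab-separated table with a header row.
#' @return A `seed_viability_tbl` tibble.
#' @export
read_viability_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out <- validate_viability_tbl(tbl, context = path)
  attr(out, "provenance") <- path
  out
}

#' @rdname read_viability_table
#' @param table A `seed_viability_tbl` (or plain data frame with a `seed`
#'   column).
#' @export
write_viability_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Construct a viability table from a data frame
#'
#' @param table Data frame with a `seed` column and one numeric column per
#'   cell line.
#' @param provenance Optional free-text provenance note.
#' @return A validated `seed_viability_tbl`.
#' @export
as_viability_table <- function(table, provenance = NA_character_) {
  out <- validate_viability_tbl(table)
  attr(out, "provenance") <- provenance
  out
}

#' @export
print.seed_viability_tbl <- function(x, ...) {
  cat(sprintf(
    "# Seed viability table: %d seeds%s, cell lines: %s\n",
    nrow(x), if (isTRUE(attr(x, "complete"))) " (complete universe)" else "",
    paste(attr(x, "cell_lines"), collapse = ", ")
  ))
  NextMethod()
}

resolve_cell_lines <- function(table, cell_lines) {
  available <- attr(table, "cell_lines") %||%
    setdiff(names(table), c("seed", "duplex_id"))
  if (is.null(cell_lines)) return(available)
  missing <- setdiff(cell_lines, available)
  if (length(missing)) {
    abort(sprintf("cell line(s) not in table: %s", paste(missing, collapse = ", ")),
          class = "seedtox_lookup_error")
  }
  cell_lines
}

#' Average viability of seeds across cell lines
#'
#' Arithmetic mean of the per-cell-line percent viabilities, the quantity
#' used throughout to summarise a seed's toxicity (lower = more toxic).
#'
#' @param table A `seed_viability_tbl`.
#' @param seeds Seeds to look up; `NULL` (default) returns all.
#' @param cell_lines Subset of cell lines to average; `NULL` uses all.
#' @return Tibble with columns `seed` and `viability`, in the order of
#'   `seeds`.
#' @export
average_viability <- function(table, seeds = NULL, cell_lines = NULL) {
  cl <- resolve_cell_lines(table, cell_lines)
  avg <- rowMeans(as.data.frame(table)[, cl, drop = FALSE])
  out <- tibble(seed = table$seed, viability = avg)
  if (is.null(seeds)) return(out)
  seeds <- assert_seed6(seeds)
  idx <- match(seeds, out$seed)
  if (anyNA(idx)) {
    abort(sprintf("seed(s) absent from table: %s",
                  paste(seeds[is.na(idx)], collapse = ", ")),
          class = "seedtox_lookup_error")
  }
  out[idx, ]
}

#' Classify seed toxicity from percent viability
#'
#' A seed is highly toxic if it reduces viability by 90% or more
#' (viability <= 10%), moderately toxic at 50% or more (viability <= 50%),
#' and non-toxic otherwise.
#'
#' @param viability Numeric vector of percent viabilities (>= 0).
#' @return Factor with levels `highly_toxic`, `moderately_toxic`,
#'   `non_toxic`.
#' @export
#' @examples
#' classify_toxicity(c(9.3, 49.2, 100))
classify_toxicity <- function(viability) {
  if (any(viability < 0, na.rm = TRUE)) {
    abort("viability must be non-negative", class = "seedtox_domain_error")
  }
  cut(viability, breaks = c(-Inf, 10, 50, Inf),
      labels = c("highly_toxic", "moderately_toxic", "non_toxic"),
      right = TRUE)
}

#' Rank seeds from most to least toxic
#'
#' Seeds are ordered by ascending viability (most toxic first); ties are
#' broken lexicographically on the seed string so ranks are deterministic.
#'
#' @param table A `seed_viability_tbl`.
#' @param cell_line A single cell line name, a character vector of cell
#'   lines to average, or `NULL` (default) for the average over all.
#' @return Tibble `seed`, `viability`, `rank` (1-based), sorted by rank.
#' @export
rank_seeds <- function(table, cell_line = NULL) {
  av <- average_viability(table, cell_lines = cell_line)
  av <- av[order(av$viability, av$seed), ]
  av$rank <- seq_len(nrow(av))
  av
}

#' Seeds shared between the extremes of two screens
#'
#' Finds the minimal depth `d` such that the `d` most (or least) toxic
#' seeds of both screens share at least `k` seeds, and returns those
#' shared seeds. This is the construction behind "the 20 seeds with the
#' highest toxicity to both cell lines were found in the top 46 most toxic
#' seeds to both".
#'
#' @param table_a,table_b Two viability tables over the same seed universe.
#' @param k Number of shared seeds sought.
#' @param end `"top"` (most toxic) or `"bottom"` (least toxic).
#' @param cell_lines_a,cell_lines_b Cell-line selections for each table.
#' @return List with `seeds` (the k shared seeds with the best combined
#'   rank, most extreme first) and `depth` (the minimal d).
#' @export
shared_extreme_seeds <- function(table_a, table_b, k = 20,
                                 end = c("top", "bottom"),
                                 cell_lines_a = NULL, cell_lines_b = NULL) {
  end <- match.arg(end)
  ra <- rank_seeds(table_a, cell_lines_a)
  rb <- rank_seeds(table_b, cell_lines_b)
  if (!setequal(ra$seed, rb$seed)) {
    abort("the two tables must cover the same seed universe",
          class = "seedtox_domain_error")
  }
  n <- nrow(ra)
  if (k < 1 || k > n) {
    abort("k must be between 1 and the universe size",
          class = "seedtox_domain_error")
  }
  if (end == "bottom") {
    ra$rank <- n + 1L - ra$rank
    rb$rank <- n + 1L - rb$rank
  }
  rank_a <- setNames(ra$rank, ra$seed)
  rank_b <- setNames(rb$rank, rb$seed)
  worst <- pmax(rank_a, rank_b[names(rank_a)])
  # seed is in top_d(A) intersect top_d(B) iff max(rank_a, rank_b) <= d, so
  # the minimal depth with >= k shared seeds is the k-th smallest worst-rank
  worst_sorted <- sort(worst)
  depth <- as.integer(worst_sorted[k])
  shared <- names(worst)[worst <= depth]
  combined <- rank_a[shared] + rank_b[shared]
  shared <- shared[order(combined, shared)][seq_len(k)]
  list(seeds = shared, depth = depth)
}

#' Pearson correlation between two screens
#'
#' Correlates (averaged) per-seed viabilities of two screens over their
#' shared seed universe, with a two-sided p-value.
#'
#' @inheritParams shared_extreme_seeds
#' @return One-row tibble `r`, `p`, `n`.
#' @export
cross_screen_correlation <- function(table_a, table_b,
                                     cell_lines_a = NULL, cell_lines_b = NULL) {
  va <- average_viability(table_a, cell_lines = cell_lines_a)
  vb <- average_viability(table_b, cell_lines = cell_lines_b)
  joined <- dplyr::inner_join(va, vb, by = "seed", suffix = c("_a", "_b"))
  if (nrow(joined) < 3L) {
    abort("need at least 3 shared seeds for a correlation",
          class = "seedtox_domain_error")
  }
  if (stats::sd(joined$viability_a) == 0 || stats::sd(joined$viability_b) == 0) {
    abort("correlation undefined: a screen has zero variance",
          class = "seedtox_domain_error")
  }
  ct <- cor.test(joined$viability_a, joined$viability_b, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = nrow(joined))
}

#' Couple an shRNA dropout screen to seed viability
#'
#' Each shRNA guide is reduced to its 6mer seed and assigned the average
#' seed viability from the arrayed screen. Reports (i) the Pearson
#' correlation between log10 fold-downregulation and seed viability and
#' (ii) a comparison of seed viability between the shRNAs downregulated
#' more than `threshold`-fold and an equally sized control group whose
#' fold change is closest to 0. Both a two-sided rank-sum p and a
#' two-sided t-test p are reported for the group difference.
#'
#' @param shrnas Tibble with columns `id`, `guide_sequence`, `fold_down`.
#' @param table A `seed_viability_tbl` covering every shRNA seed.
#' @param threshold Fold-downregulation cut defining the toxic group.
#' @param cell_lines Cell lines to average for seed viability.
#' @return Object of class `shrna_seed_analysis`: a list with `per_shrna`
#'   (annotated tibble with `group` membership), `correlation` (r, p, n)
#'   and `group_test` (group means/sizes, `p_ranksum`, `p_ttest`).
#' @export
shrna_seed_analysis <- function(shrnas, table, threshold = 5,
                                cell_lines = NULL) {
  stopifnot(all(c("id", "guide_sequence", "fold_down") %in% names(shrnas)))
  if (any(!is.finite(shrnas$fold_down))) {
    abort("fold_down must be finite", class = "seedtox_domain_error")
  }
  seeds <- extract_guide_seed(shrnas$guide_sequence)
  viab <- average_viability(table, seeds = seeds, cell_lines = cell_lines)
  ann <- dplyr::mutate(as_tibble(shrnas),
                       seed = seeds, viability = viab$viability)

  if (stats::sd(ann$viability) == 0) {
    abort("correlation undefined: all shRNA seeds have identical viability",
          class = "seedtox_domain_error")
  }
  # fold-downregulation is only log-scaled where positive; enriched or
  # unchanged shRNAs (fold <= 0) cannot enter the log-scale correlation
  lf <- suppressWarnings(log10(ann$fold_down))
  fin <- is.finite(lf)
  if (sum(fin) < 3L) {
    abort("need at least 3 shRNAs with positive fold_down for the correlation",
          class = "seedtox_domain_error")
  }
  ct <- cor.test(lf[fin], ann$viability[fin], method = "pearson")

  toxic_idx <- which(ann$fold_down > threshold)
  n_group <- length(toxic_idx)
  if (n_group < 2L || nrow(ann) < 2L * n_group) {
    abort(sprintf(
      "cannot form groups: %d shRNAs above threshold but %d records total",
      n_group, nrow(ann)), class = "seedtox_domain_error")
  }
  control_idx <- setdiff(order(abs(ann$fold_down)), toxic_idx)[seq_len(n_group)]
  ann$group <- "other"
  ann$group[toxic_idx] <- "toxic"
  ann$group[control_idx] <- "control"

  vt <- ann$viability[toxic_idx]
  vc <- ann$viability[control_idx]
  structure(list(
    per_shrna = ann,
    correlation = tibble(r = unname(ct$estimate), p = ct$p.value,
                         n = sum(fin)),
    group_test = tibble(
      n_per_group = n_group,
      mean_viability_toxic = mean(vt),
      mean_viability_control = mean(vc),
      p_ranksum = suppressWarnings(wilcox.test(vt, vc)$p.value),
      p_ttest = t.test(vt, vc)$p.value
    )
  ), class = "shrna_seed_analysis")
}

#' @export
print.shrna_seed_analysis <- function(x, ...) {
  cat("shRNA seed-viability analysis\n")
  cat(sprintf("  %d shRNAs; Pearson r(log10 fold-down, seed viability) = %.3f (p = %.3g)\n",
              x$correlation$n, x$correlation$r, x$correlation$p))
  cat(sprintf("  toxic (n=%d) mean viability %.1f vs control %.1f; rank-sum p = %.3g, t-test p = %.3g\n",
              x$group_test$n_per_group, x$group_test$mean_viability_toxic,
              x$group_test$mean_viability_control,
              x$group_test$p_ranksum, x$group_test$p_ttest))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.shrna_seed_analysis <- function(x, ...) x$per_shrna

#' @exportS3Method generics::glance
glance.shrna_seed_analysis <- function(x, ...) {
  dplyr::bind_cols(x$correlation, x$group_test)
}

#' Normalize raw screen means to a control row
#'
#' Divides every viability column by the value of a named control entry
#' (e.g. a lipid-only or non-targeting row) and rescales to percent.
#'
#' @param raw Tibble with an `id` column and numeric measurement columns.
#' @param control_id The `id` of the control row.
#' @return Tibble with measurement columns scaled so the control is 100.
#' @export
normalize_to_control <- function(raw, control_id) {
  stopifnot("id" %in% names(raw))
  ctrl <- raw[raw$id == control_id, , drop = FALSE]
  if (nrow(ctrl) != 1L) {
    abort(sprintf("control id '%s' must match exactly one row", control_id),
          class = "seedtox_lookup_error")
  }
  num <- vapply(raw, is.numeric, logical(1)) & names(raw) != "id"
  for (cl in names(raw)[num]) {
    raw[[cl]] <- 100 * raw[[cl]] / ctrl[[cl]]
  }
  as_tibble(raw)
}
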