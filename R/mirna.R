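# Seed-toxicity annotation of mature miRNA arms; evolutionary and
# arm-dominance analyses.

#' Collapse miRNA arms with identical mature sequences
#'
#' Arms sharing a mature sequence (gene duplications) are collapsed to
#' one representative so duplicated loci do not weight composition or
#' toxicity distributions. The representative keeps the lexicographically
#' smallest member id; all member ids and the member count are retained.
#'
#' @param arms Tibble with `mirna_id` and `mature_seq` (plus any other
#'   columns, taken from the representative).
#' @return Tibble with one row per distinct sequence, plus `members`
#'   (list-column of ids) and `n_members`.
#' @export
collapse_identical_arms <- function(arms) {
  arms |>
    as_tibble() |>
    dplyr::mutate(mature_seq = normalize_rna(.data$mature_seq, "mature_seq")) |>
    dplyr::arrange(.data$mature_seq, .data$mirna_id) |>
    dplyr::group_by(.data$mature_seq) |>
    dplyr::mutate(members = list(.data$mirna_id),
                  n_members = dplyr::n()) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}

#' Annotate miRNA arms with 6mer seed viability
#'
#' Maps each arm through its seed (positions 2-7 of the mature sequence)
#' to the average percent viability measured for that seed in the screen.
#'
#' @param arms Tibble with `mature_seq` (>= 7 nt).
#' @param table A complete `seed_viability_tbl`.
#' @param cell_lines Cell lines to average (default all).
#' @return `arms` with added `seed` and `viability` columns.
#' @export
annotate_arm_toxicity <- function(arms, table, cell_lines = NULL) {
  arms <- as_tibble(arms)
  arms$seed <- extract_guide_seed(arms$mature_seq)
  arms$viability <-
    average_viability(table, seeds = arms$seed, cell_lines = cell_lines)$viability
  arms
}

#' K-S comparison of seed viability between two arm groups
#'
#' Two-sample two-sided Kolmogorov-Smirnov test on the seed-viability
#' distributions of two miRNA groups (conserved vs poorly conserved,
#' old vs young, miRtron vs non-miRtron, ...).
#'
#' @param group_a,group_b Either numeric viability vectors or tibbles
#'   carrying a `viability` column (e.g. from [annotate_arm_toxicity()]).
#' @return One-row tibble `D`, `p`, `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
group_viability_comparison <- function(group_a, group_b) {
  va <- if (is.data.frame(group_a)) group_a$viability else group_a
  vb <- if (is.data.frame(group_b)) group_b$viability else group_b
  if (length(va) == 0L || length(vb) == 0L) {
    abort("both groups must be non-empty", class = "seedtox_domain_error")
  }
  kt <- suppressWarnings(ks.test(va, vb, alternative = "two.sided"))
  tibble(D = unname(kt$statistic), p = kt$p.value,
         n_a = length(va), n_b = length(vb),
         mean_a = mean(va), mean_b = mean(vb))
}

#' Determine the dominant arm of each miRNA across tissue samples
#'
#' A miRNA counts as expressed in a sample if the sum of its 5p and 3p
#' normalized reads exceeds `min_sum` (zeros are first replaced by 0.01).
#' Within an expressed sample an arm is dominant if its expression is at
#' least 25% greater than the other arm's (>= `dominance_factor` x).
#' The miRNA-level dominant arm is the one dominant in more than half of
#' the expressed samples; if neither is, the call is `ambiguous`.
#' miRNAs with a single annotated arm are called `single`.
#'
#' @param expr Arm expression tibble: columns `mirna_id`, `arm`
#'   (`"5p"`/`"3p"`), then one numeric column per sample (RPM).
#' @param mirna_id Optional subset of miRNAs; default all.
#' @param min_sum Per-sample expression threshold on the arm sum
#'   (default 5, exclusive).
#' @param dominance_factor Per-sample dominance ratio (default 1.25,
#'   inclusive).
#' @return Tibble `mirna_id`, `dominant` (`5p`/`3p`/`single`/`ambiguous`),
#'   `n_expressed_samples`, `n_dominant_5p`, `n_dominant_3p`.
#' @export
determine_dominant_arm <- function(expr, mirna_id = NULL, min_sum = 5,
                                   dominance_factor = 1.25) {
  stopifnot(all(c("mirna_id", "arm") %in% names(expr)))
  expr <- as_tibble(expr)
  ids <- mirna_id %||% unique(expr$mirna_id)
  missing <- setdiff(ids, expr$mirna_id)
  if (length(missing)) {
    abort(sprintf("miRNA(s) absent from expression matrix: %s",
                  paste(missing, collapse = ", ")),
          class = "seedtox_lookup_error")
  }
  samples <- setdiff(names(expr), c("mirna_id", "arm"))
  purrr::map_dfr(ids, function(id) {
    rows <- expr[expr$mirna_id == id, , drop = FALSE]
    if (nrow(rows) < 2L) {
      return(tibble(mirna_id = id, dominant = "single",
                    n_expressed_samples = NA_integer_,
                    n_dominant_5p = NA_integer_, n_dominant_3p = NA_integer_))
    }
    e5 <- as.numeric(rows[rows$arm == "5p", samples])
    e3 <- as.numeric(rows[rows$arm == "3p", samples])
    e5[e5 == 0] <- 0.01
    e3[e3 == 0] <- 0.01
    expressed <- (e5 + e3) > min_sum
    d5 <- expressed & (e5 >= dominance_factor * e3)
    d3 <- expressed & (e3 >= dominance_factor * e5)
    n_exp <- sum(expressed)
    dominant <- if (n_exp > 0 && sum(d5) > n_exp / 2) "5p"
                else if (n_exp > 0 && sum(d3) > n_exp / 2) "3p"
                else "ambiguous"
    tibble(mirna_id = id, dominant = dominant,
           n_expressed_samples = n_exp,
           n_dominant_5p = sum(d5), n_dominant_3p = sum(d3))
  })
}

#' Rank miRNAs by dominant-to-lesser arm seed-viability ratio
#'
#' For every miRNA with an unambiguous dominant arm and both arms
#' annotated, forms the ratio viability(dominant seed) /
#' viability(lesser-expressed seed) — below 1 means the retained guide
#' carries the more toxic seed — ranks miRNAs by descending ratio, and
#' compares the ratios of oncogenic vs tumor-suppressive labelled
#' miRNAs with a two-sided Wilcoxon rank-sum test.
#'
#' @param arms Annotated arm tibble with `mirna_id`, `arm`, `viability`
#'   and optionally `oncogenic_label` (`"oncogenic"`,
#'   `"tumor_suppressive"`, `"none"`).
#' @param dominance Output of [determine_dominant_arm()].
#' @param viability_floor Viabilities below this are floored before the
#'   ratio (default 0.01), mirroring the 0 -> 0.01 expression rule.
#' @return Object of class `arm_ratio_ranking`: list with `ranking`
#'   (tibble `mirna_id`, `dominant`, `viability_dominant`,
#'   `viability_lesser`, `ratio_toxicity`, `rank`, label) and
#'   `label_test` (one-row tibble with the rank-sum `p`).
#' @export
arm_toxicity_ratio_ranking <- function(arms, dominance,
                                       viability_floor = 0.01) {
  arms <- as_tibble(arms)
  calls <- dominance[dominance$dominant %in% c("5p", "3p"), , drop = FALSE]
  wide <- arms |>
    dplyr::select("mirna_id", "arm", "viability") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "viability",
                       names_prefix = "v_")
  ranking <- calls |>
    dplyr::inner_join(wide, by = "mirna_id") |>
    dplyr::filter(!is.na(.data$v_5p), !is.na(.data$v_3p)) |>
    dplyr::mutate(
      viability_dominant = pmax(ifelse(.data$dominant == "5p",
                                       .data$v_5p, .data$v_3p),
                                viability_floor),
      viability_lesser = pmax(ifelse(.data$dominant == "5p",
                                     .data$v_3p, .data$v_5p),
                              viability_floor),
      ratio_toxicity = .data$viability_dominant / .data$viability_lesser
    ) |>
    dplyr::arrange(dplyr::desc(.data$ratio_toxicity), .data$mirna_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(-"v_5p", -"v_3p")
  if ("oncogenic_label" %in% names(arms)) {
    labels <- dplyr::distinct(arms, .data$mirna_id, .data$oncogenic_label)
    ranking <- dplyr::left_join(ranking, labels, by = "mirna_id")
  }
  label_test <- tibble(p = NA_real_, n_oncogenic = 0L, n_suppressive = 0L)
  if ("oncogenic_label" %in% names(ranking)) {
    ro <- ranking$ratio_toxicity[ranking$oncogenic_label == "oncogenic"]
    rs <- ranking$ratio_toxicity[ranking$oncogenic_label == "tumor_suppressive"]
    if (length(ro) && length(rs)) {
      label_test <- tibble(
        p = wilcox.test(ro, rs, exact = FALSE)$p.value,
        n_oncogenic = length(ro), n_suppressive = length(rs))
    }
  }
  structure(list(ranking = ranking, label_test = label_test),
            class = "arm_ratio_ranking")
}

#' @export
print.arm_ratio_ranking <- function(x, ...) {
  cat(sprintf("Arm toxicity-ratio ranking of %d miRNAs\n", nrow(x$ranking)))
  if (!is.na(x$label_test$p)) {
    cat(sprintf("  oncogenic (n=%d) vs tumor-suppressive (n=%d) rank-sum p = %.3g\n",
                x$label_test$n_oncogenic, x$label_test$n_suppressive,
                x$label_test$p))
  }
  print(head(x$ranking, 10))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.arm_ratio_ranking <- function(x, ...) x$ranking

#' @exportS3Method generics::glance
glance.arm_ratio_ranking <- function(x, ...) {
  dplyr::bind_cols(tibble(n_ranked = nrow(x$ranking)), x$label_test)
}

#' Sliding-window seed viability across a miRtron 5' end
#'
#' Extracts the twelve 6-nt windows starting at positions 1-12 of the
#' first 17 nt of a mature sequence (17 - 6 + 1 = 12) and looks up each
#' window's viability in the screen.
#'
#' @param mature_seq A single mature sequence, >= 17 nt.
#' @param table A `seed_viability_tbl`.
#' @param cell_lines Cell lines to average.
#' @return Tibble `start` (1-12), `seed`, `viability`.
#' @export
mirtron_window_profile <- function(mature_seq, table, cell_lines = NULL) {
  mature_seq <- normalize_rna(mature_seq, "mature_seq")
  stopifnot(length(mature_seq) == 1L)
  if (nchar(mature_seq) < 17L) {
    abort("mature sequence must be at least 17 nt for the 12-window profile",
          class = "seedtox_length_error")
  }
  starts <- 1:12
  seeds <- substring(mature_seq, starts, starts + 5L)
  tibble(start = starts, seed = seeds,
         viability = average_viability(table, seeds = seeds,
                                       cell_lines = cell_lines)$viability)
}
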