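# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_vline labs facet_wrap stat_ecdf theme_minimal scale_fill_manual
#' @export
ggplot2::autoplot

#' Plot a boundary metaplot profile
#'
#' Match-coverage profiles are drawn as a single line; nucleotide
#' profiles are one line per base. A vertical line marks the region
#' boundary.
#'
#' @param object A `boundary_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.boundary_profile <- function(object, ...) {
  anchor_lab <- if (object$anchor[1] == "cds_stop") "CDS | 3'UTR"
                else "5'UTR | CDS"
  p <- if (attr(object, "mode") == "nucleotides") {
    ggplot(object, aes(x = .data$offset, y = .data$value,
                       colour = .data$base)) + geom_line(na.rm = TRUE)
  } else {
    ggplot(object, aes(x = .data$offset, y = .data$value)) +
      geom_line(na.rm = TRUE)
  }
  p + geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    labs(x = sprintf("offset around %s boundary (nt)", anchor_lab),
         y = if (attr(object, "mode") == "nucleotides")
               "base frequency" else "fraction of genes covered") +
    theme_minimal()
}

#' Plot a seed position frequency matrix
#'
#' Stacked per-position base frequencies, the frequency-plot view of a
#' seed-composition logo.
#'
#' @param object A `seed_pfm` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.seed_pfm <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), cols = dplyr::all_of(RNA_BASES),
                              names_to = "base", values_to = "freq")
  ggplot(long, aes(x = factor(.data$position), y = .data$freq,
                   fill = .data$base)) +
    geom_col() +
    scale_fill_manual(values = c(A = "#33a02c", C = "#1f78b4",
                                 G = "#ff7f00", U = "#e31a1c")) +
    labs(x = "seed position", y = "frequency",
         title = sprintf("n = %d seeds", attr(object, "n_seeds"))) +
    theme_minimal()
}

#' Ranked seed toxicity curve
#'
#' Viability against toxicity rank (most toxic left), with the
#' moderately- and highly-toxic thresholds marked.
#'
#' @param table A `seed_viability_tbl`.
#' @param cell_line Cell line(s) to average (default all).
#' @return A ggplot.
#' @export
plot_rank_curve <- function(table, cell_line = NULL) {
  ranked <- rank_seeds(table, cell_line)
  ggplot(ranked, aes(x = .data$rank, y = .data$viability)) +
    geom_line() +
    ggplot2::geom_hline(yintercept = c(10, 50), linetype = "dotted") +
    labs(x = "seed rank (most toxic first)", y = "% viability") +
    theme_minimal()
}

#' eCDF comparison of per-gene count ratios
#'
#' Empirical CDFs of the toxic/non-toxic match-count ratio for two gene
#' cohorts in one region, the visual companion of [ecdf_ratio_test()].
#'
#' @param records_a,records_b Outputs of [region_count_table()].
#' @param region Region to plot (default `"utr3"`).
#' @param labels Cohort labels.
#' @return A ggplot.
#' @export
plot_ecdf_comparison <- function(records_a, records_b, region = "utr3",
                                 labels = c("SG", "nonSG")) {
  dat <- dplyr::bind_rows(
    dplyr::mutate(records_a[records_a$region == region, ], cohort = labels[1]),
    dplyr::mutate(records_b[records_b$region == region, ], cohort = labels[2])
  )
  ggplot(dat, aes(x = .data$ratio, colour = .data$cohort)) +
    stat_ecdf() +
    labs(x = "(toxic + 1) / (non-toxic + 1) match-count ratio",
         y = "cumulative fraction of genes") +
    theme_minimal()
}
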