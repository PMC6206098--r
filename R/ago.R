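# Ago-bound small-RNA read processing: length filter, reference matching by
# exact longest common substring, 19-nt 5'-anchored collapsing, fold-change
# grouping and 5' seed-shift detection.

#' Filter reads by length
#'
#' Retains reads between `min` and `max` nt inclusive (defaults 19-26,
#' the small-RNA size window kept for Ago-bound read analysis).
#'
#' @param reads Tibble with columns `sequence`, `count`, `sample`.
#' @param min,max Inclusive length bounds.
#' @return Filtered tibble.
#' @export
filter_read_length <- function(reads, min = 19, max = 26) {
  len <- nchar(reads$sequence)
  reads[len >= min & len <= max, , drop = FALSE]
}

# longest exact common substring of two strings, by diagonal run-lengths;
# returns length and 1-based start positions in each string (leftmost-in-a
# on ties within the pair)
lcs_info <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  n <- length(va)
  m <- length(vb)
  best <- list(len = 0L, pos_a = NA_integer_, pos_b = NA_integer_)
  for (s in (-(m - 1L)):(n - 1L)) {
    ia <- max(1L, s + 1L)
    ib <- ia - s
    len <- min(n - ia, m - ib) + 1L
    eq <- va[ia:(ia + len - 1L)] == vb[ib:(ib + len - 1L)]
    r <- rle(eq)
    runs <- which(r$values)
    if (length(runs)) {
      lens <- r$lengths[runs]
      k <- which.max(lens)
      if (lens[k] > best$len) {
        off <- c(0L, cumsum(r$lengths))[runs[k]]
        best <- list(len = lens[k], pos_a = ia + off, pos_b = ib + off)
      }
    }
  }
  best
}

#' Match reads to reference miRNA arms
#'
#' A read matches a reference when the two share an exact, ungapped
#' common substring of at least `min_stretch` nt (default 16). The
#' reference with the longest such stretch wins; reads whose best
#' stretch length is tied between two or more references are flagged
#' ambiguous and excluded from downstream collapsing. `offset5` is the
#' displacement of the read's 5' end relative to the canonical arm 5'
#' end: +2 means the read starts 2 nt into the reference (5'-shortened).
#'
#' @param reads Tibble with `sequence`, `count`, `sample`.
#' @param references Tibble with `mirna_id`, `mature_seq` (>= 16 nt).
#' @param min_stretch Minimum exact stretch length.
#' @return `reads` with added `mirna_id` (NA if unmatched), `offset5`,
#'   `match_length` and `status` (`matched` / `ambiguous` / `no_match`).
#' @export
match_reads <- function(reads, references, min_stretch = 16) {
  stopifnot(all(c("mirna_id", "mature_seq") %in% names(references)))
  refs <- as_tibble(references)
  refs$mature_seq <- normalize_rna(refs$mature_seq, "mature_seq")
  if (any(nchar(refs$mature_seq) < 16L)) {
    abort("reference arms must be at least 16 nt",
          class = "seedtox_length_error")
  }
  reads <- as_tibble(reads)
  seqs <- normalize_rna(reads$sequence, "read")
  uniq <- unique(seqs)
  lookup <- purrr::map_dfr(uniq, function(s) {
    info <- purrr::map(refs$mature_seq, ~ lcs_info(s, .x))
    lens <- vapply(info, `[[`, integer(1), "len")
    best_len <- max(lens)
    if (best_len < min_stretch) {
      return(tibble(sequence = s, mirna_id = NA_character_,
                    offset5 = NA_integer_, match_length = best_len,
                    status = "no_match"))
    }
    hits <- which(lens == best_len)
    if (length(hits) > 1L) {
      return(tibble(sequence = s, mirna_id = NA_character_,
                    offset5 = NA_integer_, match_length = best_len,
                    status = "ambiguous"))
    }
    b <- info[[hits]]
    tibble(sequence = s, mirna_id = refs$mirna_id[hits],
           offset5 = b$pos_b - b$pos_a, match_length = best_len,
           status = "matched")
  })
  reads$sequence <- seqs
  dplyr::left_join(reads, lookup, by = "sequence")
}

#' Collapse matched reads on their 19-nt 5' anchor
#'
#' Matched reads are trimmed from the 3' end to 19 nt (preserving the
#' biologically decisive 5' end), grouped by miRNA and 5' anchor, and
#' their counts summed per sample. The 6mer seed is positions 2-7 of the
#' anchor.
#'
#' @param matched Output of [match_reads()]; only `status == "matched"`
#'   rows are collapsed.
#' @return Tibble: `mirna_id`, `anchor19`, `offset5`, `seed`, one count
#'   column per sample (`count_<sample>`, 0-filled).
#' @export
collapse_reads <- function(matched) {
  ok <- matched[matched$status %in% "matched", , drop = FALSE]
  if (any(nchar(ok$sequence) < 19L)) {
    abort("internal: matched read shorter than 19 nt reached collapse",
          class = "seedtox_internal_error")
  }
  ok |>
    dplyr::mutate(anchor19 = substr(.data$sequence, 1L, 19L)) |>
    dplyr::group_by(.data$mirna_id, .data$anchor19, .data$sample) |>
    dplyr::summarise(count = sum(.data$count),
                     offset5 = .data$offset5[1], .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       names_prefix = "count_", values_fill = 0L) |>
    dplyr::mutate(seed = extract_guide_seed(.data$anchor19),
                  .after = "offset5") |>
    dplyr::arrange(.data$mirna_id, .data$anchor19)
}

#' Split collapsed reads into fold-change groups
#'
#' Removes records with fewer than `min_reads` collapsed reads in the
#' treated sample, then calls a record up-regulated when
#' treated/control >= `fc` and down-regulated when control/treated >=
#' `fc` (zero counts are replaced by 0.01 before division).
#'
#' @param collapsed Output of [collapse_reads()].
#' @param control_sample,treated_sample Sample names (without the
#'   `count_` prefix).
#' @param fc Fold-change threshold, > 1 (inclusive at the boundary).
#' @param min_reads Minimum treated-sample collapsed reads (default 100).
#' @return List with `up` and `down` (tibbles of collapsed records, with
#'   `fold_change` = treated/control) and `table` (all retained records
#'   with a `direction` column).
#' @export
fold_change_groups <- function(collapsed, control_sample, treated_sample,
                               fc = 1.5, min_reads = 100) {
  if (fc <= 1) {
    abort("fold-change threshold must exceed 1",
          class = "seedtox_config_error")
  }
  ctrl_col <- paste0("count_", control_sample)
  trt_col <- paste0("count_", treated_sample)
  if (!all(c(ctrl_col, trt_col) %in% names(collapsed))) {
    abort(sprintf("samples '%s'/'%s' not found in collapsed table",
                  control_sample, treated_sample),
          class = "seedtox_lookup_error")
  }
  kept <- collapsed[collapsed[[trt_col]] >= min_reads, , drop = FALSE]
  ctrl <- ifelse(kept[[ctrl_col]] == 0, 0.01, kept[[ctrl_col]])
  trt <- ifelse(kept[[trt_col]] == 0, 0.01, kept[[trt_col]])
  kept$fold_change <- trt / ctrl
  kept$direction <- dplyr::case_when(
    kept$fold_change >= fc ~ "up",
    1 / kept$fold_change >= fc ~ "down",
    TRUE ~ "none"
  )
  list(up = kept[kept$direction == "up", , drop = FALSE],
       down = kept[kept$direction == "down", , drop = FALSE],
       table = kept)
}

#' Seed toxicity of up- vs down-regulated Ago-bound populations
#'
#' Looks up the screen viability of each record's 6mer seed and compares
#' the up- and down-regulated groups with a two-sample two-sided K-S
#' test.
#'
#' @param up,down Collapsed-read tibbles (with a `seed` column).
#' @param table A `seed_viability_tbl`.
#' @param cell_lines Cell lines to average.
#' @return One-row tibble `mean_up`, `mean_down`, `D`, `p`, `n_up`,
#'   `n_down`.
#' @export
group_seed_toxicity <- function(up, down, table, cell_lines = NULL) {
  if (nrow(up) == 0L || nrow(down) == 0L) {
    abort("both groups must be non-empty", class = "seedtox_domain_error")
  }
  vu <- average_viability(table, seeds = up$seed,
                          cell_lines = cell_lines)$viability
  vd <- average_viability(table, seeds = down$seed,
                          cell_lines = cell_lines)$viability
  kt <- suppressWarnings(ks.test(vu, vd, alternative = "two.sided"))
  tibble(mean_up = mean(vu), mean_down = mean(vd),
         D = unname(kt$statistic), p = kt$p.value,
         n_up = length(vu), n_down = length(vd))
}

#' Detect 5' seed shifts in collapsed Ago-bound reads
#'
#' Compares each collapsed read's observed seed (positions 2-7 of its
#' 19-nt anchor) with the canonical seed of its matched reference arm
#' and reports both seeds' screen viabilities. A non-zero `offset5`
#' with a changed seed is a 5' isomiR whose toxicity differs from the
#' canonical form.
#'
#' @param collapsed Collapsed-read tibble.
#' @param references Reference arm tibble (`mirna_id`, `mature_seq`).
#' @param table A `seed_viability_tbl`.
#' @param cell_lines Cell lines to average.
#' @return Tibble: `mirna_id`, `anchor19`, `offset5`, `canonical_seed`,
#'   `observed_seed`, `canonical_viability`, `observed_viability`,
#'   `shifted` (logical).
#' @export
detect_seed_shift <- function(collapsed, references, table,
                              cell_lines = NULL) {
  refs <- as_tibble(references)
  refs$canonical_seed <- extract_guide_seed(refs$mature_seq)
  out <- collapsed |>
    dplyr::rename(observed_seed = "seed") |>
    dplyr::left_join(dplyr::select(refs, "mirna_id", "canonical_seed"),
                     by = "mirna_id")
  if (anyNA(out$canonical_seed)) {
    abort("collapsed reads reference arms absent from `references`",
          class = "seedtox_lookup_error")
  }
  out$canonical_viability <-
    average_viability(table, seeds = out$canonical_seed,
                      cell_lines = cell_lines)$viability
  out$observed_viability <-
    average_viability(table, seeds = out$observed_seed,
                      cell_lines = cell_lines)$viability
  out$shifted <- out$offset5 != 0L
  dplyr::select(out, "mirna_id", "anchor19", "offset5", "canonical_seed",
                "observed_seed", "canonical_viability", "observed_viability",
                "shifted", dplyr::starts_with("count_"))
}
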