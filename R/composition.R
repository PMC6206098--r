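# Positional nucleotide composition of seed sets and enrichment testing.

seed_base_matrix <- function(seeds) {
  seeds <- assert_seed6(seeds)
  matrix(unlist(strsplit(seeds, "")), ncol = 6, byrow = TRUE)
}

#' Position frequency matrix of a seed set
#'
#' Fraction of seeds carrying each base at each of the six seed positions,
#' the statistic underlying seed-composition logos.
#'
#' @param seeds Character vector of 6mer seeds (duplicates count).
#' @return A `seed_pfm` tibble with columns `position` (1-6) and `A`, `C`,
#'   `G`, `U`; rows sum to 1. Attribute `n_seeds` records the set size.
#' @export
#' @examples
#' position_frequency_matrix(c("GGGAAA", "GGCAGU"))
position_frequency_matrix <- function(seeds) {
  if (length(seeds) == 0L) {
    abort("cannot compute composition of an empty seed set",
          class = "seedtox_domain_error")
  }
  bm <- seed_base_matrix(seeds)
  freq <- t(apply(bm, 2, function(col) {
    tabulate(factor(col, levels = RNA_BASES), nbins = 4) / length(col)
  }))
  out <- as_tibble(as.data.frame(freq))
  names(out) <- RNA_BASES
  out <- dplyr::bind_cols(tibble(position = 1:6), out)
  structure(out, class = unique(c("seed_pfm", class(out))),
            n_seeds = length(seeds))
}

#' Seeds with high single-nucleotide content
#'
#' All 6mer seeds whose content of one nucleotide strictly exceeds
#' `min_fraction`. At the default 0.8 this is the ">80%" rule selecting
#' seeds with 5 or 6 copies of the base: C(6,5) x 3 + 1 = 19 per
#' nucleotide.
#'
#' @param nucleotide One of `"A"`, `"C"`, `"G"`, `"U"`.
#' @param min_fraction Exclusive lower bound on the base fraction, in
#'   \[0, 1).
#' @return Character vector of seeds, lexicographically sorted.
#' @export
#' @examples
#' length(high_content_seeds("G", 0.8)) # 19
high_content_seeds <- function(nucleotide, min_fraction = 0.8) {
  nucleotide <- normalize_rna(nucleotide, "nucleotide")
  stopifnot(nucleotide %in% RNA_BASES, min_fraction >= 0, min_fraction < 1)
  universe <- all_seeds()
  counts <- stringr::str_count(universe, stringr::fixed(nucleotide))
  universe[counts / 6 > min_fraction]
}

#' Fisher exact test for positional nucleotide enrichment
#'
#' Compares the frequency of a focal nucleotide at one seed position
#' between two seed groups with a two-sided Fisher exact test on the
#' 2x2 table (focal vs non-focal x group).
#'
#' @param group_a,group_b Non-empty character vectors of 6mer seeds.
#' @param position Seed position 1-6 (vectorised).
#' @param focal Focal nucleotide (default `"G"`).
#' @return Tibble with one row per position: counts `a_focal`, `a_other`,
#'   `b_focal`, `b_other` and the two-sided `p`.
#' @export
positional_enrichment_test <- function(group_a, group_b, position = 1:6,
                                       focal = "G") {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("both seed groups must be non-empty", class = "seedtox_domain_error")
  }
  focal <- normalize_rna(focal, "focal nucleotide")
  stopifnot(focal %in% RNA_BASES, all(position %in% 1:6))
  ma <- seed_base_matrix(group_a)
  mb <- seed_base_matrix(group_b)
  purrr::map_dfr(position, function(p) {
    af <- sum(ma[, p] == focal)
    bf <- sum(mb[, p] == focal)
    tab <- matrix(c(af, nrow(ma) - af, bf, nrow(mb) - bf), nrow = 2)
    tibble(position = p, focal = focal,
           a_focal = af, a_other = nrow(ma) - af,
           b_focal = bf, b_other = nrow(mb) - bf,
           p = fisher.test(tab, alternative = "two.sided")$p.value)
  })
}

#' Seed composition across age bins
#'
#' Bins miRNA arms by evolutionary age, computes one position frequency
#' matrix per bin (ordered young to old) and tests the youngest against
#' the oldest bin per position with a Fisher exact test on the focal
#' nucleotide.
#'
#' @param arms Tibble with columns `mature_seq` (or `seed`) and `age_myr`.
#' @param breaks Age bin boundaries in million years; defaults to
#'   `c(0, 10, 100, 800, Inf)`, bracketing the "<10" and ">800" extremes.
#' @param focal Focal nucleotide for the young-vs-old tests.
#' @return List with `matrices` (long tibble: `age_bin`, `position`, one
#'   column per base) and `tests` (per-position Fisher p, youngest vs
#'   oldest bin).
#' @export
composition_by_age_series <- function(arms, breaks = c(0, 10, 100, 800, Inf),
                                      focal = "G") {
  seeds <- if ("seed" %in% names(arms)) assert_seed6(arms$seed)
           else extract_guide_seed(arms$mature_seq)
  bins <- cut(arms$age_myr, breaks = breaks, include.lowest = TRUE)
  keep <- !is.na(bins)
  seeds <- seeds[keep]; bins <- droplevels(bins[keep])
  if (nlevels(bins) < 2L) {
    abort("need at least two non-empty age bins", class = "seedtox_domain_error")
  }
  matrices <- purrr::map_dfr(levels(bins), function(b) {
    pfm <- position_frequency_matrix(seeds[bins == b])
    dplyr::bind_cols(tibble(age_bin = b, n_seeds = attr(pfm, "n_seeds")),
                     as_tibble(pfm))
  })
  young <- seeds[bins == levels(bins)[1]]
  old <- seeds[bins == levels(bins)[nlevels(bins)]]
  tests <- positional_enrichment_test(young, old, focal = focal)
  list(matrices = matrices, tests = tests)
}

#' Write a position frequency matrix as TSV
#'
#' Emits the `position, A, C, G, U` layout consumed by standard logo
#' tools.
#'
#' @param pfm A `seed_pfm` tibble.
#' @param path Output path.
#' @export
write_pfm <- function(pfm, path) {
  readr::write_tsv(as_tibble(pfm), path, progress = FALSE)
  invisible(path)
}
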