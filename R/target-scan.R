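# Seed-match scanning of gene regions, SG vs non-SG eCDF statistics,
# boundary metaplots and the Toxicity Index.

REGION_LEVELS <- c("utr5", "cds", "utr3", "utr3_first1000")

as_dna <- function(x) {
  x <- toupper(x)
  x[is.na(x)] <- ""
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort("region sequences must be DNA over A/C/G/T/N",
          class = "seedtox_alphabet_error")
  }
  x
}

validate_gene_regions <- function(genes) {
  stopifnot(is.data.frame(genes), "gene_id" %in% names(genes))
  genes <- as_tibble(genes)
  for (r in c("utr5", "cds", "utr3")) {
    if (!r %in% names(genes)) genes[[r]] <- ""
    genes[[r]] <- as_dna(genes[[r]])
  }
  genes
}

#' Count exact seed matches in a sequence
#'
#' Counts occurrences of the reverse-complement match sequence of a seed
#' in DNA regions, sliding one base at a time so overlapping occurrences
#' all count. `N` never matches.
#'
#' @param region Character vector of DNA sequences (empty strings give 0).
#' @param seed A single 6mer seed.
#' @return Integer vector of match counts, one per region.
#' @export
#' @examples
#' count_seed_matches("ACTGCCACTGCC", "GGCAGU") # 2
#' count_seed_matches("AAAAAAA", "UUUUUU")      # 2 (overlap counted)
count_seed_matches <- function(region, seed) {
  pattern <- seed_match_sequence(assert_seed6(seed), "DNA")
  subject <- Biostrings::DNAStringSet(as_dna(region))
  Biostrings::vcountPattern(pattern, subject, fixed = TRUE)
}

# counts for many seeds at once: matrix [seed x sequence]
count_matches_pdict <- function(sequences, seeds) {
  patterns <- Biostrings::DNAStringSet(seed_match_sequence(seeds, "DNA"))
  names(patterns) <- seeds
  nonempty <- nchar(sequences) >= 6L
  out <- matrix(0L, nrow = length(seeds), ncol = length(sequences),
                dimnames = list(seeds, NULL))
  if (any(nonempty)) {
    pd <- Biostrings::PDict(patterns)
    out[, nonempty] <- Biostrings::vcountPDict(
      pd, Biostrings::DNAStringSet(sequences[nonempty]))
  }
  out
}

#' Per-gene, per-region toxic vs non-toxic seed match counts
#'
#' Sums exact match counts over a toxic and a non-toxic seed set in each
#' gene's 5'UTR, CDS, full 3'UTR and first 1000 bases of the 3'UTR, and
#' forms the pseudocounted ratio (toxic + eps) / (nontoxic + eps).
#'
#' @param genes Tibble with `gene_id`, `utr5`, `cds`, `utr3` (DNA; may be
#'   empty strings) and optionally `set_label`.
#' @param toxic_seeds,nontoxic_seeds Disjoint, non-empty 6mer seed sets.
#' @param epsilon Pseudocount added to numerator and denominator
#'   (default 1) so genes without matches still have a defined ratio.
#' @return Tibble: `gene_id`, (`set_label`,) `region`, `toxic_count`,
#'   `nontoxic_count`, `ratio`.
#' @export
region_count_table <- function(genes, toxic_seeds, nontoxic_seeds,
                               epsilon = 1) {
  toxic_seeds <- assert_seed6(toxic_seeds)
  nontoxic_seeds <- assert_seed6(nontoxic_seeds)
  if (length(toxic_seeds) == 0L || length(nontoxic_seeds) == 0L ||
      length(intersect(toxic_seeds, nontoxic_seeds)) > 0L) {
    abort("toxic and non-toxic seed sets must be non-empty and disjoint",
          class = "seedtox_config_error")
  }
  genes <- validate_gene_regions(genes)
  region_seq <- list(
    utr5 = genes$utr5, cds = genes$cds, utr3 = genes$utr3,
    utr3_first1000 = substr(genes$utr3, 1L, 1000L)
  )
  out <- purrr::map_dfr(names(region_seq), function(rg) {
    tc <- colSums(count_matches_pdict(region_seq[[rg]], toxic_seeds))
    nc <- colSums(count_matches_pdict(region_seq[[rg]], nontoxic_seeds))
    rec <- tibble(gene_id = genes$gene_id, region = rg,
                  toxic_count = as.integer(tc),
                  nontoxic_count = as.integer(nc),
                  ratio = (tc + epsilon) / (nc + epsilon))
    if ("set_label" %in% names(genes)) {
      rec <- dplyr::mutate(rec, set_label = genes$set_label,
                           .after = "gene_id")
    }
    rec
  })
  out$region <- factor(out$region, levels = REGION_LEVELS)
  out
}

#' Kolmogorov-Smirnov comparison of per-gene count ratios
#'
#' Compares the distribution of per-gene toxic/non-toxic match-count
#' ratios between two gene cohorts (e.g. survival genes vs
#' expression-matched non-survival genes) with a two-sample two-sided
#' K-S test.
#'
#' @param records_a,records_b Outputs of [region_count_table()] for the
#'   two cohorts.
#' @param region Which region's ratios to compare (default `"utr3"`).
#' @return One-row tibble `D`, `p`, `n_a`, `n_b`.
#' @export
ecdf_ratio_test <- function(records_a, records_b, region = "utr3") {
  ra <- records_a$ratio[records_a$region == region]
  rb <- records_b$ratio[records_b$region == region]
  if (length(ra) == 0L || length(rb) == 0L) {
    abort("both cohorts must be non-empty for the chosen region",
          class = "seedtox_domain_error")
  }
  kt <- suppressWarnings(ks.test(ra, rb, alternative = "two.sided"))
  tibble(D = unname(kt$statistic), p = kt$p.value,
         n_a = length(ra), n_b = length(rb))
}

#' Toxicity Index of a seed
#'
#' Ratio of a seed's reverse-complement match occurrences in the 3'UTRs
#' of survival genes versus non-survival genes (pseudocount `epsilon` on
#' both totals). Higher values predict greater toxicity.
#'
#' @param seeds Character vector of 6mer seeds.
#' @param sg_genes,nonsg_genes Gene-region tibbles (`gene_id`, `utr3`,
#'   ...), both non-empty.
#' @param epsilon Pseudocount (default 1).
#' @return Tibble `seed`, `ti`.
#' @export
toxicity_index <- function(seeds, sg_genes, nonsg_genes, epsilon = 1) {
  seeds <- assert_seed6(seeds)
  sg_genes <- validate_gene_regions(sg_genes)
  nonsg_genes <- validate_gene_regions(nonsg_genes)
  if (nrow(sg_genes) == 0L || nrow(nonsg_genes) == 0L) {
    abort("both gene sets must be non-empty", class = "seedtox_domain_error")
  }
  sg_tot <- unname(rowSums(count_matches_pdict(sg_genes$utr3, seeds)))
  ns_tot <- unname(rowSums(count_matches_pdict(nonsg_genes$utr3, seeds)))
  tibble(seed = seeds, ti = (sg_tot + epsilon) / (ns_tot + epsilon))
}

# shared scaffolding for the two boundary metaplots ------------------------

anchor_regions <- function(genes, anchor) {
  switch(anchor,
    cds_start = list(up = genes$utr5, down = genes$cds),
    cds_stop  = list(up = genes$cds,  down = genes$utr3))
}

# offsets are -window..-1 (last bases of the upstream region, -1 adjacent
# to the boundary) and 1..window (1-based positions of the downstream
# region); there is no offset 0
profile_offsets <- function(window) c(-window:-1, 1:window)

offset_index <- function(offset, window) {
  ifelse(offset < 0L, offset + window + 1L, offset + window)
}

#' Metaplot of seed-match coverage around a CDS boundary
#'
#' For each offset around the translational start (`cds_start`:
#' 5'UTR/CDS boundary) or stop (`cds_stop`: CDS/3'UTR boundary), the
#' fraction of genes whose sequence carries a 6-base seed-match footprint
#' overlapping that offset, among genes long enough to cover the offset.
#' Matches are located on the concatenated 5'UTR+CDS+3'UTR so
#' boundary-spanning footprints contribute to both sides. Genes shorter
#' than the window are clipped, not discarded.
#'
#' @param genes Gene-region tibble.
#' @param seed_set 6mer seeds whose matches are plotted.
#' @param anchor `"cds_stop"` (default) or `"cds_start"`.
#' @param window Number of bases profiled on each side (>= 6).
#' @return A `boundary_profile` tibble: `anchor`, `offset`, `value`,
#'   `n_contributing`; `value` is `NA` where no gene contributes.
#' @export
boundary_metaplot_matches <- function(genes, seed_set,
                                      anchor = c("cds_stop", "cds_start"),
                                      window = 500) {
  anchor <- match.arg(anchor)
  stopifnot(window >= 6)
  genes <- validate_gene_regions(genes)
  if (nrow(genes) == 0L) {
    abort("empty gene list", class = "seedtox_domain_error")
  }
  seed_set <- assert_seed6(seed_set)
  offs <- profile_offsets(window)
  n_off <- length(offs)

  full <- paste0(genes$utr5, genes$cds, genes$utr3)
  counts <- count_matches_pdict(full, seed_set) # only to skip matchless genes
  pd <- Biostrings::PDict(
    Biostrings::DNAStringSet(seed_match_sequence(seed_set, "DNA")))
  regs <- anchor_regions(genes, anchor)
  up_len <- nchar(regs$up)
  down_len <- nchar(regs$down)
  # boundary position in the concatenated sequence = global index of the
  # last upstream-region base
  boundary <- if (anchor == "cds_start") nchar(genes$utr5)
              else nchar(genes$utr5) + nchar(genes$cds)

  n_contrib <- integer(n_off)
  hits <- integer(n_off)
  for (i in seq_len(nrow(genes))) {
    cov_up <- min(up_len[i], window)
    cov_down <- min(down_len[i], window)
    if (cov_up > 0) n_contrib[offset_index(-cov_up:-1, window)] <-
      n_contrib[offset_index(-cov_up:-1, window)] + 1L
    if (cov_down > 0) n_contrib[offset_index(1:cov_down, window)] <-
      n_contrib[offset_index(1:cov_down, window)] + 1L
    if (sum(counts[, i]) == 0L || nchar(full[i]) < 6L) next
    subj <- Biostrings::DNAString(full[i])
    starts <- unlist(Biostrings::startIndex(Biostrings::matchPDict(pd, subj)))
    if (length(starts) == 0L) next
    covered <- unique(unlist(lapply(starts, function(s) s:(s + 5L))))
    o <- ifelse(covered > boundary[i], covered - boundary[i],
                covered - boundary[i] - 1L)
    o <- o[o >= -window & o <= window & o != 0L]
    # footprint coverage only counts where the gene itself contributes
    o <- o[(o < 0 & -o <= cov_up) | (o > 0 & o <= cov_down)]
    if (length(o)) {
      idx <- unique(offset_index(o, window))
      hits[idx] <- hits[idx] + 1L
    }
  }
  value <- ifelse(n_contrib > 0, hits / n_contrib, NA_real_)
  structure(
    tibble(anchor = anchor, offset = offs, value = value,
           n_contributing = n_contrib),
    class = unique(c("boundary_profile", class(tibble()))),
    mode = "matches", window = window
  )
}

#' Metaplot of single-nucleotide frequencies around a CDS boundary
#'
#' Per-offset base composition among contributing genes; the four base
#' frequencies sum to 1 at every defined offset.
#'
#' @inheritParams boundary_metaplot_matches
#' @return A `boundary_profile` tibble in long form: `anchor`, `offset`,
#'   `base` (A/C/G/T), `value`, `n_contributing`.
#' @export
boundary_metaplot_nucleotides <- function(genes,
                                          anchor = c("cds_stop", "cds_start"),
                                          window = 500) {
  anchor <- match.arg(anchor)
  stopifnot(window >= 6)
  genes <- validate_gene_regions(genes)
  if (nrow(genes) == 0L) {
    abort("empty gene list", class = "seedtox_domain_error")
  }
  offs <- profile_offsets(window)
  n_off <- length(offs)
  regs <- anchor_regions(genes, anchor)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = n_off, ncol = 4, dimnames = list(NULL, bases))
  for (i in seq_len(nrow(genes))) {
    up <- regs$up[i]; down <- regs$down[i]
    lu <- nchar(up); ld <- nchar(down)
    if (lu > 0) {
      take <- min(lu, window)
      chars <- strsplit(substr(up, lu - take + 1L, lu), "")[[1]]
      idx <- offset_index(-take:-1, window)
      ok <- chars %in% bases
      counts[cbind(idx[ok], match(chars[ok], bases))] <-
        counts[cbind(idx[ok], match(chars[ok], bases))] + 1L
    }
    if (ld > 0) {
      take <- min(ld, window)
      chars <- strsplit(substr(down, 1L, take), "")[[1]]
      idx <- offset_index(1:take, window)
      ok <- chars %in% bases
      counts[cbind(idx[ok], match(chars[ok], bases))] <-
        counts[cbind(idx[ok], match(chars[ok], bases))] + 1L
    }
  }
  n_contrib <- rowSums(counts)
  freq <- counts / ifelse(n_contrib > 0, n_contrib, NA_real_)
  out <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(offset = offs, n_contributing = n_contrib),
                     as_tibble(as.data.frame(freq))),
    cols = dplyr::all_of(bases), names_to = "base", values_to = "value"
  )
  out <- dplyr::mutate(out, anchor = anchor, .before = 1)
  structure(out, class = unique(c("boundary_profile", class(tibble()))),
            mode = "nucleotides", window = window)
}

#' Pick one longest 3'UTR per gene
#'
#' Reduces a transcript-level table to one representative transcript per
#' gene, the one with the longest 3'UTR; ties break on the
#' lexicographically smaller `transcript_id`.
#'
#' @param transcripts Tibble with `gene_id`, `transcript_id`, `utr3`.
#' @return One row per gene.
#' @export
longest_utr_per_gene <- function(transcripts) {
  transcripts |>
    as_tibble() |>
    dplyr::mutate(.len = nchar(.data$utr3)) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$.len),
                   .data$transcript_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::select(-".len")
}

#' Greedy expression matching of two gene cohorts
#'
#' Pairs each gene of cohort A with the still-unused cohort-B gene of
#' nearest expression (RPM), processing A genes from highest expression
#' down. A helper for building expression-matched control cohorts when
#' matched labels are not supplied.
#'
#' @param genes_a,genes_b Tibbles with `gene_id` and `rpm`.
#' @return Tibble `gene_id_a`, `gene_id_b`, `rpm_a`, `rpm_b`.
#' @export
match_expression_pairs <- function(genes_a, genes_b) {
  stopifnot(all(c("gene_id", "rpm") %in% names(genes_a)),
            all(c("gene_id", "rpm") %in% names(genes_b)),
            nrow(genes_b) >= nrow(genes_a))
  a <- dplyr::arrange(as_tibble(genes_a), dplyr::desc(.data$rpm))
  b <- as_tibble(genes_b)
  used <- logical(nrow(b))
  pick <- integer(nrow(a))
  for (i in seq_len(nrow(a))) {
    d <- abs(b$rpm - a$rpm[i])
    d[used] <- Inf
    pick[i] <- which.min(d)
    used[pick[i]] <- TRUE
  }
  tibble(gene_id_a = a$gene_id, gene_id_b = b$gene_id[pick],
         rpm_a = a$rpm, rpm_b = b$rpm[pick])
}
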