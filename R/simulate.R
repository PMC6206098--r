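# Generators for every input class, with planted ground truth exposed for
# parameter-recovery tests. One integer seed drives all generators;
# per-module substreams are derived deterministically from it.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. The defaults
#' define the study conditions the package's recovery tests run under;
#' see the methods vignette for the reasoning behind each value.
#'
#' @param rng_seed Integer master seed; all generators derive their
#'   substreams from it, so identical configs give identical outputs.
#' @param g_weights Six per-position viability penalties (percent) for a
#'   G at seed positions 1-6, decreasing 5' to 3'.
#' @param c6_bonus Additional penalty for a C at seed position 6.
#' @param noise_sd Per-cell-line Gaussian noise on percent viability.
#' @param n_cell_lines Number of screen cell lines to simulate.
#' @param sg_c_content,nonsg_c_content 3'UTR C fraction for the survival
#'   and control cohorts.
#' @param planted_window 1-based 3'UTR positions between which toxic seed
#'   matches are planted in survival genes.
#' @param planted_match_rate Per-gene probability of carrying a planted
#'   match.
#' @param dominance_factor,dominance_sample_frac Planted arm-expression
#'   dominance: the dominant arm is `dominance_factor` x the lesser arm
#'   in `dominance_sample_frac` of samples.
#' @param shift_event List `(mirna_id, offset, fold)` describing the one
#'   planted 5'-shift event in the Ago read sets; `mirna_id = NULL`
#'   plants it in the first reference, and `shift_event = NULL` plants
#'   none.
#' @return Object of class `sim_config` (a list).
#' @export
sim_config <- function(rng_seed = 1L,
                       g_weights = c(28, 24, 18, 12, 8, 5),
                       c6_bonus = 10,
                       noise_sd = 15,
                       n_cell_lines = 2L,
                       sg_c_content = 0.32,
                       nonsg_c_content = 0.24,
                       planted_window = c(42L, 65L),
                       planted_match_rate = 0.9,
                       dominance_factor = 10,
                       dominance_sample_frac = 0.9,
                       shift_event = list(mirna_id = NULL, offset = 2L,
                                          fold = 1.6)) {
  stopifnot(length(g_weights) == 6L, all(g_weights >= 0), noise_sd >= 0,
            n_cell_lines >= 1L, sg_c_content >= 0, sg_c_content <= 1,
            nonsg_c_content >= 0, nonsg_c_content <= 1,
            planted_match_rate >= 0, planted_match_rate <= 1,
            length(planted_window) == 2L,
            planted_window[1] <= planted_window[2])
  structure(list(
    rng_seed = as.integer(rng_seed), g_weights = g_weights,
    c6_bonus = c6_bonus, noise_sd = noise_sd,
    n_cell_lines = as.integer(n_cell_lines),
    sg_c_content = sg_c_content, nonsg_c_content = nonsg_c_content,
    planted_window = as.integer(planted_window),
    planted_match_rate = planted_match_rate,
    dominance_factor = dominance_factor,
    dominance_sample_frac = dominance_sample_frac,
    shift_event = shift_event
  ), class = "sim_config")
}

# deterministic substream seeds, kept within 32-bit integer range
substream_seed <- function(config, module) {
  offset <- match(module, c("viability", "genes", "mirna", "ago"))
  (abs(config$rng_seed) %% 2000000000L) + offset * 10007L
}

# deterministic (noise-free) viability component of the generator:
# toxicity is a position-weighted function of G content plus a C bonus
# at position 6
deterministic_viability <- function(seeds, config) {
  bm <- seed_base_matrix(seeds)
  penalty <- bm == "G"
  det <- 100 - as.numeric(penalty %*% config$g_weights) -
    config$c6_bonus * (bm[, 6] == "C")
  det
}

clamp_viability <- function(x) pmin(pmax(x, 0.1), 120)

#' Simulate a complete 4096-seed viability screen
#'
#' Per cell line, viability(seed) = clamp(100 - sum_p w_p \[seed_p = G\]
#' - c6_bonus \[seed_6 = C\] + noise, 0.1, 120): G content weighted
#' towards the 5' end drives toxicity, with an extra penalty for C at
#' position 6, emulating the composition rules of the arrayed screen.
#'
#' @param config A [sim_config()].
#' @return List with `table` (complete `seed_viability_tbl`, cell lines
#'   named `line1`, `line2`, ...) and `truth` (tibble `seed`,
#'   `deterministic`: the noise-free viability).
#' @export
sim_viability_table <- function(config = sim_config()) {
  seeds <- all_seeds()
  det <- deterministic_viability(seeds, config)
  set.seed(substream_seed(config, "viability"))
  tbl <- tibble(seed = seeds)
  for (i in seq_len(config$n_cell_lines)) {
    tbl[[paste0("line", i)]] <-
      clamp_viability(det + rnorm(length(seeds), sd = config$noise_sd))
  }
  list(table = as_viability_table(tbl, provenance = "simulated screen"),
       truth = tibble(seed = seeds, deterministic = det))
}

random_dna <- function(n, len, probs) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE, prob = probs),
          collapse = "")
  }, "")
}

#' Simulate survival-gene and control gene cohorts
#'
#' 3'UTRs are sampled from per-cohort base compositions (survival genes
#' C-enriched); with probability `planted_match_rate` each survival gene
#' receives one exact match to a generator-toxic seed planted inside the
#' configured early-3'UTR window. RPM values are drawn matched between
#' cohorts.
#'
#' @param config A [sim_config()].
#' @param n_sg,n_nonsg Cohort sizes.
#' @param n_toxic_seeds How many of the generator's most toxic seeds are
#'   used for planting (default 20).
#' @return List with `genes` (tibble `gene_id`, `utr5`, `cds`, `utr3`,
#'   `set_label`, `rpm`) and `planted` (tibble `gene_id`, `seed`,
#'   `position` of each planted match).
#' @export
sim_gene_cohorts <- function(config = sim_config(), n_sg = 500,
                             n_nonsg = 500, n_toxic_seeds = 20) {
  stopifnot(n_sg >= 1, n_nonsg >= 1)
  set.seed(substream_seed(config, "genes"))
  det <- deterministic_viability(all_seeds(), config)
  toxic <- all_seeds()[order(det, all_seeds())][seq_len(n_toxic_seeds)]

  n <- n_sg + n_nonsg
  set_label <- rep(c("SG", "nonSG"), c(n_sg, n_nonsg))
  c_frac <- ifelse(set_label == "SG", config$sg_c_content,
                   config$nonsg_c_content)
  utr3_len <- sample(500:1500, n, replace = TRUE)
  utr5_len <- sample(80:300, n, replace = TRUE)
  cds_len <- sample(300:900, n, replace = TRUE)

  utr3 <- vapply(seq_len(n), function(i) {
    rest <- (1 - c_frac[i]) / 3
    # 3'UTRs are A/U rich; spread the non-C mass with a mild A/T excess
    probs <- c(A = rest * 1.2, C = c_frac[i], G = rest * 0.6, T = rest * 1.2)
    random_dna(1, utr3_len[i], probs / sum(probs))
  }, "")
  utr5 <- random_dna(n, utr5_len, c(A = 0.22, C = 0.28, G = 0.28, T = 0.22))
  cds <- random_dna(n, cds_len, c(A = 0.25, C = 0.26, G = 0.26, T = 0.23))

  win <- config$planted_window
  plant_start_max <- win[2] - 5L
  planted <- tibble(gene_id = character(), seed = character(),
                    position = integer())
  for (i in which(set_label == "SG")) {
    if (runif(1) <= config$planted_match_rate) {
      s <- sample(toxic, 1)
      pos <- sample(win[1]:plant_start_max, 1)
      substr(utr3[i], pos, pos + 5L) <- seed_match_sequence(s, "DNA")
      planted <- dplyr::add_row(planted, gene_id = paste0("gene", i),
                                seed = s, position = pos)
    }
  }
  rpm <- stats::rlnorm(n_sg, log(2000), 0.5)
  rpm <- c(rpm, rpm * stats::rlnorm(n_nonsg, 0, 0.05))[seq_len(n)]

  list(genes = tibble(gene_id = paste0("gene", seq_len(n)),
                      utr5 = utr5, cds = cds, utr3 = utr3,
                      set_label = set_label, rpm = rpm),
       planted = planted)
}

random_rna <- function(n, len, p_g = 0.25) {
  rest <- (1 - p_g) / 3
  vapply(rep(len, length.out = n), function(l) {
    paste(sample(RNA_BASES, l, replace = TRUE,
                 prob = c(rest, rest, p_g, rest)), collapse = "")
  }, "")
}

#' Simulate a mature miRNA annotation and arm expression matrix
#'
#' Generates paired 5p/3p arms with planted arm dominance, evolutionary
#' ages whose seed G content decays with age (young miRNAs G-rich, old
#' ones A/U-rich), miRtron flags (miRtrons G-rich), and
#' oncogenic/tumor-suppressive labels planted so that oncogenic miRNAs
#' retain the non-toxic arm and tumor-suppressive ones the toxic arm.
#'
#' @param config A [sim_config()].
#' @param n Number of miRNAs (>= 2).
#' @param n_samples Number of tissue samples in the expression matrix.
#' @return List with `arms` (tibble `mirna_id`, `arm`, `mature_seq`,
#'   `conservation_group`, `age_myr`, `is_mirtron`, `oncogenic_label`),
#'   `expression` (arm x sample tibble) and `truth` (tibble `mirna_id`,
#'   `dominant_arm`).
#' @export
sim_mirna_annotation <- function(config = sim_config(), n = 50,
                                 n_samples = 20) {
  stopifnot(n >= 2)
  set.seed(substream_seed(config, "mirna"))
  ids <- sprintf("mir-%03d", seq_len(n))
  dominant <- sample(c("5p", "3p"), n, replace = TRUE)
  age <- exp(runif(n, log(1), log(1200)))
  conservation <- as.integer(cut(age, c(0, 10, 100, 800, Inf))) - 2L # -1..2
  is_mirtron <- runif(n) < 0.15
  label <- sample(c("oncogenic", "tumor_suppressive", "none"), n,
                  replace = TRUE, prob = c(0.15, 0.15, 0.7))

  # seed G content: young and miRtron seeds G-rich, old seeds G-depleted
  p_g_age <- ifelse(age < 10, 0.45, ifelse(age > 800, 0.08, 0.25))
  make_arm_seq <- function(p_g_seed) {
    seq22 <- random_rna(1, 22, 0.25)
    substr(seq22, 2, 7) <- random_rna(1, 6, p_g_seed)
    seq22
  }
  arms <- purrr::map_dfr(seq_len(n), function(i) {
    p_g <- if (is_mirtron[i]) 0.5 else p_g_age[i]
    p_dom <- p_g
    p_lesser <- p_g
    if (label[i] == "oncogenic") { p_dom <- 0.02; p_lesser <- 0.6 }
    if (label[i] == "tumor_suppressive") { p_dom <- 0.6; p_lesser <- 0.02 }
    tibble(
      mirna_id = ids[i], arm = c("5p", "3p"),
      mature_seq = c(
        make_arm_seq(if (dominant[i] == "5p") p_dom else p_lesser),
        make_arm_seq(if (dominant[i] == "3p") p_dom else p_lesser)
      ),
      conservation_group = conservation[i], age_myr = age[i],
      is_mirtron = is_mirtron[i], oncogenic_label = label[i]
    )
  })

  base <- stats::rlnorm(n, log(60), 0.4)
  expression <- purrr::map_dfr(seq_len(n), function(i) {
    dom_is_dom <- runif(n_samples) < config$dominance_sample_frac
    dom <- base[i] * stats::rlnorm(n_samples, 0, 0.2)
    lesser <- dom / config$dominance_factor
    e_dom <- ifelse(dom_is_dom, dom, lesser)
    e_les <- ifelse(dom_is_dom, lesser, dom)
    out <- tibble(mirna_id = ids[i], arm = c("5p", "3p"))
    vals <- if (dominant[i] == "5p") rbind(e_dom, e_les) else rbind(e_les, e_dom)
    for (j in seq_len(n_samples)) out[[paste0("sample", j)]] <- vals[, j]
    out
  })

  list(arms = arms, expression = expression,
       truth = tibble(mirna_id = ids, dominant_arm = dominant))
}

#' Simulate control/treated Ago-bound read sets
#'
#' Reads are sampled around the canonical 5' ends of the reference arms
#' with lengths 19-26 (3' trimming/extension only), counts Poisson
#' around per-reference means, and one configured 5'-shift event: in the
#' treated sample a 5'-shortened form of one miRNA appears at the
#' configured fold change over control while all canonical forms stay
#' flat.
#'
#' @param config A [sim_config()].
#' @param references Tibble `mirna_id`, `mature_seq` (>= 19 nt each).
#' @param mean_count Mean collapsed-read count per reference per sample.
#' @return Tibble `sequence`, `count`, `sample` (samples `control` and
#'   `treated`), plus attribute `shift_truth` describing the planted
#'   event.
#' @export
sim_ago_readset <- function(config = sim_config(), references,
                            mean_count = 300) {
  stopifnot(nrow(references) >= 1)
  refs <- dplyr::distinct(as_tibble(references), .data$mirna_id,
                          .keep_all = TRUE)
  refs$mature_seq <- normalize_rna(refs$mature_seq, "mature_seq")
  stopifnot(all(nchar(refs$mature_seq) >= 19L))
  set.seed(substream_seed(config, "ago"))

  ev <- config$shift_event
  if (!is.null(ev)) {
    shift_id <- ev$mirna_id %||% refs$mirna_id[1]
    stopifnot(shift_id %in% refs$mirna_id)
  }

  variants <- function(seq22) {
    # a few 3'-length isoforms of the canonical 5' end
    lens <- unique(pmin(nchar(seq22), c(19L, 20L, 21L, nchar(seq22))))
    substring(seq22, 1L, lens)
  }
  out <- purrr::map_dfr(seq_len(nrow(refs)), function(i) {
    v <- variants(refs$mature_seq[i])
    w <- c(0.5, rep(0.5 / (length(v) - 1), length(v) - 1))
    base <- rpois(1, mean_count)
    purrr::map_dfr(c("control", "treated"), function(smp) {
      tibble(sequence = v,
             count = rpois(length(v), pmax(base * w, 1)),
             sample = smp)
    })
  })

  if (is.null(ev)) {
    return(structure(out, shift_truth = NULL))
  }
  ref_seq <- refs$mature_seq[refs$mirna_id == shift_id]
  shifted <- substr(ref_seq, 1L + ev$offset, nchar(ref_seq))
  # keep read length >= 19 by extending the 3' end with random bases
  if (nchar(shifted) < 19L) {
    shifted <- paste0(shifted, random_rna(1, 19L - nchar(shifted)))
  }
  ctrl_n <- max(rpois(1, mean_count), 120)
  trt_n <- round(ctrl_n * ev$fold * 1.1) # headroom so Poisson noise keeps >= fold
  out <- dplyr::bind_rows(out,
    tibble(sequence = shifted, count = c(ctrl_n, trt_n),
           sample = c("control", "treated")))
  structure(out, shift_truth = list(mirna_id = shift_id,
                                    offset5 = as.integer(ev$offset),
                                    fold = ev$fold,
                                    sequence = shifted))
}
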