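# Seed extraction, lookup, classification, ranking and screen statistics.

test_that("seed extraction takes positions 2-7 and normalizes T to U", {
  # antisense guide strands of characterized duplexes
  expect_equal(extract_guide_seed("UGGCAGUACAUGUAAACCAAA"), "GGCAGU")
  expect_equal(extract_guide_seed("AAGCUGGGUUGAGAGGGCGAA"), "AGCUGG")
  expect_equal(extract_guide_seed("AUAUGGGUAAUUGAAGGGCAA"), "UAUGGG")
  expect_equal(extract_guide_seed("TGGCAGTACATGTAAACCAAA"), "GGCAGU")
  expect_error(extract_guide_seed("AGCUGG"), class = "seedtox_length_error")
  expect_error(extract_guide_seed("AGCUGGXUA"),
               class = "seedtox_alphabet_error")
})

test_that("seed match sequence is the reverse complement, and an involution", {
  expect_equal(seed_match_sequence("GGCAGU", "DNA"), "ACTGCC")
  expect_equal(seed_match_sequence("UUUUUU", "DNA"), "AAAAAA")
  expect_equal(seed_match_sequence("GGCAGU", "RNA"), "ACUGCC")
  # reverse-complementing twice is the identity on the full universe
  universe <- all_seeds()
  expect_equal(seed_match_sequence(seed_match_sequence(universe, "RNA"), "RNA"),
               universe)
})

test_that("viability tables round-trip and reject malformed input", {
  tbl <- toy_viability(c("AAAAAA", "GGGGGG"), c(95, 6), c(90, 12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_viability_table(tbl, path)
  back <- read_viability_table(path)
  attr(back, "provenance") <- attr(tbl, "provenance")
  expect_equal(as.data.frame(back), as.data.frame(tbl))
  expect_false(attr(back, "complete"))
  expect_equal(attr(back, "cell_lines"), c("line1", "line2"))

  dup <- tibble::tibble(seed = c("AAAAAA", "AAAAAA"), line1 = c(1, 2))
  expect_error(as_viability_table(dup), class = "seedtox_format_error")
  bad <- tibble::tibble(seed = "AAAAAA", line1 = "high")
  expect_error(as_viability_table(bad), class = "seedtox_format_error")
  neg <- tibble::tibble(seed = "AAAAAA", line1 = -5)
  expect_error(as_viability_table(neg), class = "seedtox_format_error")
})

test_that("a generated 4096-seed table is flagged complete", {
  vt <- sim_viability_table(sim_config(rng_seed = 3))
  expect_true(attr(vt$table, "complete"))
  expect_equal(nrow(vt$table), 4096L)
})

test_that("average viability is the arithmetic mean over chosen cell lines", {
  tbl <- toy_viability("ACGUAC", 10, 30)
  expect_equal(average_viability(tbl, "ACGUAC")$viability, 20)
  expect_equal(average_viability(tbl, "ACGUAC", "line2")$viability, 30)
  expect_error(average_viability(tbl, "GGGGGG"),
               class = "seedtox_lookup_error")
  expect_error(average_viability(tbl, "ACGUAC", "lineX"),
               class = "seedtox_lookup_error")
})

test_that("toxicity classes honor the 10/50 thresholds inclusively", {
  expect_equal(as.character(classify_toxicity(c(9.3, 49.2, 100))),
               c("highly_toxic", "moderately_toxic", "non_toxic"))
  expect_equal(as.character(classify_toxicity(c(10, 10.0001, 50, 50.0001))),
               c("highly_toxic", "moderately_toxic", "moderately_toxic",
                 "non_toxic"))
  expect_error(classify_toxicity(-1), class = "seedtox_domain_error")
})

test_that("ranking is ascending in viability with lexicographic tie-break", {
  tbl <- toy_viability(c("AAAAAA", "CCCCCC", "GGGGGG"), c(5, 90, 5))
  rk <- rank_seeds(tbl)
  expect_equal(rk$seed, c("AAAAAA", "GGGGGG", "CCCCCC"))
  expect_equal(rk$rank, 1:3)
  # permutation of keys, rank 1 = minimum
  expect_setequal(rk$seed, tbl$seed)
  expect_equal(rk$viability[1], min(average_viability(tbl)$viability))

  # reversing viabilities reverses the order (no ties here)
  set.seed(11)
  t1 <- toy_viability(seed_universe_64(), sample(64))
  t2 <- toy_viability(seed_universe_64(), 100 - average_viability(t1)$viability)
  expect_equal(rank_seeds(t1)$seed, rev(rank_seeds(t2)$seed))

  # matches an independent sort oracle on a 64-seed universe
  av <- average_viability(t1)
  oracle <- av$seed[order(av$viability, av$seed)]
  expect_equal(rank_seeds(t1)$seed, oracle)
})

test_that("shared extreme seeds find the minimal depth", {
  tbl <- random_table_64()
  same <- shared_extreme_seeds(tbl, tbl, k = 20)
  expect_equal(same$depth, 20L)
  expect_equal(same$seeds, rank_seeds(tbl)$seed[1:20])

  set.seed(42)
  for (i in 1:5) {
    ta <- random_table_64()
    tb <- random_table_64()
    for (end in c("top", "bottom")) {
      res <- shared_extreme_seeds(ta, tb, k = 10, end = end)
      expect_equal(res$depth, oracle_shared_depth(ta, tb, 10, end))
      expect_gte(res$depth, 10L)
      expect_length(res$seeds, 10L)
      # every returned seed really is in both top-d sets
      topd <- function(t) {
        rk <- rank_seeds(t)
        if (end == "bottom") rk <- rk[rev(seq_len(nrow(rk))), ]
        rk$seed[seq_len(res$depth)]
      }
      expect_true(all(res$seeds %in% intersect(topd(ta), topd(tb))))
    }
  }
  expect_error(shared_extreme_seeds(tbl, tbl, k = 100),
               class = "seedtox_domain_error")
})

test_that("cross-screen correlation behaves on exact and degenerate inputs", {
  tbl <- random_table_64()
  av <- average_viability(tbl)
  expect_equal(cross_screen_correlation(tbl, tbl)$r, 1.0)
  flipped <- toy_viability(av$seed, 100 - av$viability)
  expect_equal(cross_screen_correlation(tbl, flipped)$r, -1.0)
  flat <- toy_viability(av$seed, 50)
  expect_error(cross_screen_correlation(tbl, flat),
               class = "seedtox_domain_error")
  # invariant under common positive affine rescaling
  scaled_a <- toy_viability(av$seed, av$viability * 0.7 + 3)
  r0 <- cross_screen_correlation(tbl, flipped)$r
  r1 <- cross_screen_correlation(scaled_a, flipped)$r
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("shRNA coupling reports correlation and both group tests", {
  # 12 toxic-seed shRNAs strongly depleted, 12 neutral ones near zero
  seeds_toxic <- high_content_seeds("G", 0.8)[1:12]
  seeds_safe <- high_content_seeds("A", 0.8)[1:12]
  tbl <- toy_viability(c(seeds_toxic, seeds_safe),
                       c(runif(12, 2, 8), runif(12, 90, 98)))
  guides <- paste0("A", c(seeds_toxic, seeds_safe),
                   "UAAACCAAAUGGUUU") # pad to plausible guide length
  shr <- tibble::tibble(
    id = paste0("sh", 1:24),
    guide_sequence = guides,
    fold_down = c(runif(12, 8, 20), runif(12, -0.5, 0.5))
  )
  res <- shrna_seed_analysis(shr, tbl, threshold = 5)
  expect_s3_class(res, "shrna_seed_analysis")
  expect_lt(res$correlation$r, -0.8) # depletion tracks toxicity
  expect_lt(res$group_test$p_ranksum, 1e-6) # disjoint viability supports
  expect_lt(res$group_test$p_ttest, 1e-6)
  expect_equal(res$group_test$n_per_group, 12L)
  expect_equal(sort(unique(tidy(res)$group)), c("control", "other", "toxic")[-2])
  expect_equal(nrow(glance(res)), 1L)

  # all shRNAs sharing one seed -> zero variance -> surfaced error
  mono <- tibble::tibble(id = "s", guide_sequence = "AGGGGGGUAAACC",
                         fold_down = 10)
  mono <- mono[rep(1, 6), ]
  tbl1 <- toy_viability("GGGGGG", 5)
  expect_error(shrna_seed_analysis(mono, tbl1),
               class = "seedtox_domain_error")
})

test_that("control-row normalization rescales to percent of control", {
  raw <- tibble::tibble(id = c("lipid", "s1", "s2"),
                        line1 = c(200, 100, 50), line2 = c(100, 100, 25))
  norm <- normalize_to_control(raw, "lipid")
  expect_equal(norm$line1, c(100, 50, 25))
  expect_equal(norm$line2, c(100, 100, 25))
  expect_error(normalize_to_control(raw, "nope"),
               class = "seedtox_lookup_error")
})
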