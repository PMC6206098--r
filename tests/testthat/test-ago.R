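# Ago-bound read processing: filtering, matching, collapsing, grouping,
# shift detection.

mk_reads <- function(sequences, counts = 1L, sample = "control") {
  tibble::tibble(sequence = sequences,
                 count = rep_len(counts, length(sequences)),
                 sample = rep_len(sample, length(sequences)))
}

ref_320a <- tibble::tibble(
  mirna_id = "miR-320a-3p",
  mature_seq = "AAAAGCUGGGUUGAGAGGGCGA" # canonical 22-nt arm
)

test_that("length filter keeps 19-26 nt inclusive and matches brute force", {
  reads <- mk_reads(vapply(c(18, 19, 22, 26, 27),
                           function(l) strrep("A", l), ""))
  kept <- filter_read_length(reads)
  expect_equal(nchar(kept$sequence), c(19, 22, 26))
  set.seed(41)
  lens <- sample(10:35, 1000, replace = TRUE)
  rnd <- mk_reads(vapply(lens, function(l) strrep("C", l), ""))
  expect_equal(nrow(filter_read_length(rnd)), sum(lens >= 19 & lens <= 26))
})

test_that("read matching requires a 16-nt exact stretch and reports offsets", {
  refs <- tibble::tibble(
    mirna_id = c("mirX", "mirY"),
    mature_seq = c("UGGCAGUACAUGUAAACCAAAC", "CCGGAAUUCCGGAAUUCCGGAA")
  )
  # identical to a reference -> offset5 = 0
  m0 <- match_reads(mk_reads(refs$mature_seq[1]), refs)
  expect_equal(m0$status, "matched")
  expect_equal(m0$mirna_id, "mirX")
  expect_equal(m0$offset5, 0L)
  expect_equal(m0$match_length, 22L)

  # maximal shared stretch of 15 nt -> no match
  frag15 <- substr(refs$mature_seq[1], 1, 15)
  read15 <- paste0(frag15, "GGGGGGG") # 22 nt, breaks the stretch at 16
  m15 <- match_reads(mk_reads(read15), refs[1, ])
  expect_equal(m15$status, "no_match")
  expect_equal(m15$match_length, 15L)

  # 5'-shortened by two with two extra 3' bases -> offset5 = +2
  read_shift <- paste0(substr(ref_320a$mature_seq, 3, 22), "AA")
  ms <- match_reads(mk_reads(read_shift), ref_320a)
  expect_equal(ms$status, "matched")
  expect_equal(ms$offset5, 2L)

  # tie between two references -> ambiguous, read discarded downstream
  refs_tie <- tibble::tibble(
    mirna_id = c("m1", "m2"),
    mature_seq = c(paste0("AAAA", strrep("CG", 9)),
                   paste0("UUUU", strrep("CG", 9))))
  tie_read <- paste0("GGGG", strrep("CG", 9))
  mt <- match_reads(mk_reads(tie_read), refs_tie)
  expect_equal(mt$status, "ambiguous")
  expect_equal(nrow(collapse_reads(mt)), 0L)
})

test_that("collapsing trims to 19 nt, groups by 5' anchor, conserves counts", {
  refs <- tibble::tibble(mirna_id = "mirX",
                         mature_seq = "UGGCAGUACAUGUAAACCAAAC")
  seqs <- c(
    substr(refs$mature_seq, 1, 22), substr(refs$mature_seq, 1, 22), # same
    substr(refs$mature_seq, 1, 20), # same 5' anchor, shorter 3'
    paste0(substr(refs$mature_seq, 2, 22), "A") # 5' end differs by 1
  )
  reads <- mk_reads(seqs, counts = c(3L, 4L, 5L, 7L))
  col <- collapse_reads(match_reads(reads, refs))
  expect_equal(nrow(col), 2L) # two distinct 5' anchors
  anchor0 <- col[col$offset5 == 0, ]
  expect_equal(anchor0$count_control, 12) # 3 + 4 + 5
  expect_equal(nchar(col$anchor19), c(19L, 19L))
  expect_equal(col$seed, substr(col$anchor19, 2, 7))
  # conservation: total in = total out for matched reads
  expect_equal(sum(col$count_control), sum(reads$count))
})

test_that("fold-change grouping applies inclusive boundaries and min reads", {
  col <- tibble::tibble(
    mirna_id = paste0("m", 1:4), anchor19 = strrep("A", 19), offset5 = 0L,
    seed = "AAAAAA",
    count_control = c(100, 10, 100, 150),
    count_treated = c(150, 99, 100, 100)
  )
  gr <- fold_change_groups(col, "control", "treated")
  expect_equal(gr$up$mirna_id, "m1") # 150/100 = 1.5, inclusive
  expect_equal(gr$down$mirna_id, "m4") # 150/100 control/treated
  expect_false("m2" %in% gr$table$mirna_id) # treated 99 < 100 removed
  expect_equal(gr$table$direction[gr$table$mirna_id == "m3"], "none")
  expect_error(fold_change_groups(col, "control", "treated", fc = 1),
               class = "seedtox_config_error")
  expect_error(fold_change_groups(col, "control", "missing"),
               class = "seedtox_lookup_error")

  # brute-force classification oracle on random counts
  set.seed(42)
  rnd <- tibble::tibble(
    mirna_id = paste0("r", 1:200), anchor19 = strrep("G", 19), offset5 = 0L,
    seed = "GGGGGG",
    count_control = rpois(200, 120), count_treated = rpois(200, 120)
  )
  gr2 <- fold_change_groups(rnd, "control", "treated")
  keep <- rnd$count_treated >= 100
  ctrl <- pmax(rnd$count_control, 0.01)
  trt <- pmax(rnd$count_treated, 0.01)
  oracle <- ifelse(trt / ctrl >= 1.5, "up",
                   ifelse(ctrl / trt >= 1.5, "down", "none"))[keep]
  expect_equal(gr2$table$direction, oracle)
})

test_that("group seed toxicity compares viability distributions", {
  vt <- complete_toy_table()
  recs <- function(seeds) tibble::tibble(seed = seeds)
  same <- group_seed_toxicity(recs(c("AAAAAA", "CCCCCC")),
                              recs(c("AAAAAA", "CCCCCC")), vt)
  expect_equal(same$D, 0)
  one <- group_seed_toxicity(recs("AAAAAA"), recs("CCCCCC"), vt)
  expect_true(one$D %in% c(0, 1))
  expect_error(group_seed_toxicity(recs(character(0)), recs("AAAAAA"), vt),
               class = "seedtox_domain_error")
})

test_that("seed shift detection recovers the miR-320a-style shift", {
  # table carrying the two printed viabilities for the canonical and
  # shifted seeds
  vt <- toy_viability(c("AAGCUG", "AGCUGG", "AAAGCU", "GCUGGG"),
                      c(49.2, 9.3, 60, 5))
  # reference whose positions 2-7 read AAGCUG; the Ago-bound guide
  # AAGCUGGGUUGAGAGGGCGAA then sits one base into it
  ref_seed_frame <- tibble::tibble(mirna_id = "miR-320a-3p",
                                   mature_seq = "AAAGCUGGGUUGAGAGGGCGA")
  col <- collapse_reads(match_reads(
    mk_reads("AAGCUGGGUUGAGAGGGCGAA"), ref_seed_frame))
  shift <- detect_seed_shift(col, ref_seed_frame, vt)
  expect_equal(shift$offset5, 1L)
  expect_equal(shift$canonical_seed, "AAGCUG")
  expect_equal(shift$observed_seed, "AGCUGG")
  expect_equal(shift$canonical_viability, 49.2)
  expect_equal(shift$observed_viability, 9.3)
  expect_true(shift$shifted)

  # against the canonical 22-nt miRBase-style arm the same read is
  # 5'-shortened by two nucleotides
  col2 <- collapse_reads(match_reads(
    mk_reads("AAGCUGGGUUGAGAGGGCGAA"), ref_320a))
  shift2 <- detect_seed_shift(col2, ref_320a, vt)
  expect_equal(shift2$offset5, 2L)
  expect_equal(shift2$observed_seed, "AGCUGG")

  # offset 0 -> canonical seed = observed seed
  col0 <- collapse_reads(match_reads(mk_reads(ref_320a$mature_seq), ref_320a))
  shift0 <- detect_seed_shift(col0, ref_320a, vt)
  expect_equal(shift0$offset5, 0L)
  expect_equal(shift0$canonical_seed, shift0$observed_seed)
  expect_false(shift0$shifted)
})

test_that("planted shift events are recovered end to end", {
  cfg <- sim_config(rng_seed = 12)
  set.seed(43)
  refs <- tibble::tibble(
    mirna_id = paste0("mir", 1:5),
    mature_seq = replicate(5, paste(sample(c("A", "C", "G", "U"), 22, TRUE),
                                    collapse = ""))
  )
  reads <- sim_ago_readset(cfg, refs)
  truth <- attr(reads, "shift_truth")
  col <- collapse_reads(match_reads(filter_read_length(reads), refs))
  gr <- fold_change_groups(col, "control", "treated")
  shifts <- detect_seed_shift(gr$up, refs,
                              sim_viability_table(cfg)$table)
  up_shifted <- shifts[shifts$shifted, ]
  expect_equal(nrow(up_shifted), 1L)
  expect_equal(up_shifted$mirna_id, truth$mirna_id)
  expect_equal(up_shifted$offset5, truth$offset5)
  # no event planted -> every recovered offset is 0
  cfg0 <- sim_config(rng_seed = 12, shift_event = NULL)
  reads0 <- sim_ago_readset(cfg0, refs)
  col0 <- collapse_reads(match_reads(filter_read_length(reads0), refs))
  expect_true(all(col0$offset5 == 0L))
})
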