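# Fixtures built in code: toy viability tables and gene-region builders.

# toy table assigning given viabilities (recycled) to chosen seeds
toy_viability <- function(seeds, line1, line2 = line1) {
  as_viability_table(tibble::tibble(
    seed = seeds,
    line1 = rep_len(line1, length(seeds)),
    line2 = rep_len(line2, length(seeds))
  ))
}

# a complete table over all 4096 seeds with deterministic values
complete_toy_table <- function(offset = 0) {
  seeds <- all_seeds()
  as_viability_table(tibble::tibble(
    seed = seeds,
    line1 = (seq_along(seeds) %% 119) + offset + 0.5
  ))
}

# random 64-seed universe: all 3mers over {A,C,G,U} doubled into 6mers
seed_universe_64 <- function() {
  mers <- expand.grid(b1 = c("A", "C", "G", "U"), b2 = c("A", "C", "G", "U"),
                      b3 = c("A", "C", "G", "U"), stringsAsFactors = FALSE)
  sort(paste0(mers$b1, mers$b2, mers$b3, mers$b1, mers$b2, mers$b3))
}

random_table_64 <- function() {
  toy_viability(seed_universe_64(), stats::runif(64, 1, 99))
}

# independent brute-force depth scan for shared_extreme_seeds
oracle_shared_depth <- function(table_a, table_b, k, end = "top") {
  va <- average_viability(table_a)
  vb <- average_viability(table_b)
  ord <- function(v) {
    if (end == "top") v$seed[order(v$viability, v$seed)]
    else v$seed[order(-v$viability, v$seed)]
  }
  sa <- ord(va); sb <- ord(vb)
  for (d in k:length(sa)) {
    if (length(intersect(sa[seq_len(d)], sb[seq_len(d)])) >= k) return(d)
  }
  NA_integer_
}

# regex-with-lookahead oracle for overlapping match counting
oracle_count_matches <- function(region, match_dna) {
  if (nchar(region) == 0) return(0L)
  m <- gregexpr(paste0("(?=", match_dna, ")"), region, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

random_dna_str <- function(len, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
        collapse = "")
}

# minimal gene-region tibble
toy_gene <- function(gene_id = "g1", utr5 = "", cds = "", utr3 = "",
                     set_label = "SG") {
  tibble::tibble(gene_id = gene_id, utr5 = utr5, cds = cds, utr3 = utr3,
                 set_label = set_label)
}
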