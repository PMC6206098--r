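Package: seedtox
Title: 6mer Seed Toxicity Analysis for si/sh/miRNAs
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse 6mer-seed-mediated toxicity of small RNAs.
    Maps per-seed cell-viability measurements from an arrayed 4096-seed
    siRNA screen onto siRNA, shRNA and miRNA guide sequences; scans gene
    regions (5'UTR/CDS/3'UTR) for reverse-complement seed matches and
    compares survival-gene and control cohorts with eCDF/Kolmogorov-Smirnov
    statistics; computes positional nucleotide composition of seed sets;
    analyses miRNA arm dominance, seed conservation/age trends and miRtron
    seeds; detects 5' seed shifts in Argonaute-bound small-RNA reads; and
    simulates every input class with planted ground truth for parameter
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
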