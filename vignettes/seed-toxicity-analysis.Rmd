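---
title: "Mapping 6mer seed toxicity onto small RNAs, target UTRs and miRNA biology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping 6mer seed toxicity onto small RNAs, target UTRs and miRNA biology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedtox)
library(dplyr)
```

## The model

Many si- and shRNAs kill cells independently of their intended target
through the 6mer seed — positions 2–7 of the RISC-loaded guide strand —
which is sufficient for miRNA-like repression of any mRNA carrying the
exact reverse-complement match in its 3'UTR. When the seed happens to
hit the 3'UTRs of many survival genes (SGs) at once, the cumulative
moderate knockdown is lethal (death induced by survival-gene
elimination). An arrayed screen of all $4^6 = 4096$ seeds in a neutral
siRNA scaffold measures, per seed and cell line, percent viability
(ATP content relative to control transfection; lower = more toxic).

`seedtox` re-implements the computational layer around such a screen:

* **core seeds** — seed extraction, viability lookup and averaging,
  toxicity classes (viability $\le 10\%$ highly toxic, $\le 50\%$
  moderately toxic), deterministic rankings, minimal-depth shared-extreme
  sets, cross-screen Pearson correlations, and the coupling of an shRNA
  dropout screen to seed viability;
* **composition** — position frequency matrices over seed sets,
  high-content seed enumeration, Fisher-exact positional enrichment;
* **target scanning** — exact overlapping reverse-complement match
  counting in 5'UTR/CDS/3'UTR, per-gene toxic/non-toxic count ratios
  compared by two-sample two-sided Kolmogorov–Smirnov tests, boundary
  metaplots around the translational start/stop, and the Toxicity Index
  $\mathrm{TI}(s) = (m_{SG}(s) + \varepsilon)/(m_{nonSG}(s) + \varepsilon)$
  on 3'UTR match totals;
* **miRNA atlas** — arm collapsing, seed-toxicity annotation,
  conservation/age/miRtron group comparisons, arm-dominance calls from a
  tissue expression matrix and the dominant/lesser toxicity-ratio
  ranking;
* **Ago reads** — small-RNA read filtering (19–26 nt), reference
  matching by exact $\ge 16$-nt common substring, 19-nt 5'-anchored
  collapsing, fold-change grouping and 5' seed-shift (isomiR) detection;
* **synthetic data** — generators for every input class with planted
  ground truth.

Every user-facing function takes a data frame first and returns a
tibble, so analyses compose with the pipe; `autoplot()`/`plot_*()`
give ggplot2 views, and fitted-object classes have `tidy()`/`glance()`
methods.

## A worked chain

```{r}
cfg <- sim_config(rng_seed = 1)
vt  <- sim_viability_table(cfg)
rank_seeds(vt$table) |> head(3)
position_frequency_matrix(rank_seeds(vt$table)$seed[1:200])
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| toxicity thresholds | 10, 50 (% viability) | highly / moderately toxic classes, inclusive at the boundary |
| `epsilon` | 1 (counts) | pseudocount on both sides of every match-count ratio, keeping ratios defined for matchless genes |
| `window` | 500 (nt) | half-width of boundary metaplots |
| `min_sum` | 5 (RPM) | per-sample arm-sum above which a miRNA counts as expressed (exclusive); zeros are first replaced by 0.01 |
| `dominance_factor` | 1.25 | an arm is sample-dominant when $\ge$ 1.25× the other arm (inclusive) |
| `fc`, `min_reads` | 1.5, 100 | Ago fold-change grouping: inclusive fold threshold, minimum collapsed reads in the treated sample |
| `min_stretch` | 16 (nt) | exact ungapped identity required to match a read to a reference arm |

Design choices where the procedure was genuinely open:

* **Ranking ties** break lexicographically on the seed string, so ranks
  are reproducible.
* **Shared extremes** are defined by a minimal-depth search: the depth
  reported for $k$ shared seeds is the smallest $d$ such that the two
  screens' top-$d$ (or bottom-$d$) sets share at least $k$ seeds — the
  only parameter-free reading of "found in the top $d$".
* **Count ratios** use summed per-gene counts with a symmetric
  pseudocount $\varepsilon = 1$; swapping the toxic and non-toxic sets
  maps every ratio to its reciprocal.
* **Metaplot offsets**: downstream offsets are the 1-based positions of
  the downstream region (a match starting at 3'UTR position 10 covers
  offsets 10–15 of the stop-codon anchor); upstream offsets are
  $-1, -2, \dots$ counting back from the boundary; there is no offset 0.
  Normalisation divides by the number of genes long enough to reach each
  offset, so short UTRs clip rather than fabricate decay.
* **Overlapping matches count** (the scan slides one base at a time);
  `N` never matches.
* **shRNA group comparison** reports both a two-sided rank-sum p and a
  two-sided t-test p, as the two are used interchangeably in this
  analysis tradition; neither is privileged.
* **Read multi-mapping**: a read whose best exact stretch ties across
  two references is discarded as ambiguous rather than assigned
  arbitrarily.
* **Viability floor** 0.01 before arm-ratio formation avoids division by
  zero, mirroring the 0 → 0.01 substitution used for expression.
* **Fisher enrichment** is focal-vs-rest (default G vs non-G) per
  position, reported without multiplicity correction since the
  positional tests are read jointly, not selected from.

## What the generators emulate — and what they do not

The synthetic module supplies inputs with the statistical structure the
analyses assume, with ground truth exposed:

* **Screen**: viability per cell line is
  $\mathrm{clamp}(100 - \sum_p w_p[s_p = G] - b\,[s_6 = C] +
  \mathcal{N}(0, \sigma),\ 0.1,\ 120)$ with position weights
  $w = (28, 24, 18, 12, 8, 5)$ and a C-at-position-6 bonus $b = 10$.
  The weights decay 5'→3' so that a 5'-G gradient is the planted truth;
  `GGGGGC` is the deterministic minimum. At the default noise
  $\sigma = 15$ the deterministic spread (sd $\approx 19$) yields
  between-line correlations of $r \approx 0.63$, the regime of real
  multi-line screens. Values are clamped to $[0.1, 120]$ because
  normalized screens do exceed 100% and ratios need a positive floor.
* **Gene cohorts**: SG 3'UTRs use C fraction 0.32 vs 0.24 for controls
  (both A/U-rich overall, as real 3'UTRs are); with probability 0.9 each
  SG carries one planted toxic-seed match inside 3'UTR positions 42–65;
  RPMs are drawn matched between cohorts. UTR lengths 500–1500 nt keep
  a 200–500 nt metaplot window fully populated.
* **miRNA annotation**: the planted dominant arm is 10× the lesser arm
  in 90% of samples; seed G content decays with age (0.45 below 10 Myr,
  0.08 above 800 Myr) and rises in miRtrons; oncogenic labels plant a
  non-toxic guide over a toxic lesser arm, tumor-suppressive labels the
  reverse.
* **Ago reads**: 3'-length isoforms around canonical 5' ends with
  Poisson counts, plus one configured 5'-shift event (default +2 nt at
  1.6× fold change) in the treated sample.

The generators do **not** emulate sequencing error, adapter content,
plate-level luminescence artifacts, low-complexity/repeat structure of
real UTRs, or the phylogenetic correlation structure of real miRNA
families. Passing recovery tests therefore shows the estimators are
correct and well-calibrated under the assumed structure — not that real
data meet those assumptions.

## Numerical choices and degenerate inputs

* Correlations require $\ge 3$ points and non-zero variance on both
  sides; constant screens raise a domain error rather than returning NA.
* K–S tests are run two-sample two-sided; with tied ratios the
  asymptotic p is used (the exact-p warning is suppressed knowingly).
* The rank-sum test uses the exact distribution where R's default
  allows (small samples, no ties) and the normal approximation
  otherwise.
* Empty regions count 0 matches; empty seed sets, empty cohorts and
  empty groups raise typed errors (`seedtox_domain_error`,
  `seedtox_format_error`, ...) naming the offending field.
* All alphabets are normalized internally: seeds and mature miRNA
  sequences to RNA (T→U), gene regions to DNA (U→T); match strings are
  emitted in the alphabet of the sequence being scanned.

## Problem sizes in the test suite

The recovery tests run at the sizes the analyses are designed for,
scaled to a single CPU: 500 genes per cohort for the eCDF calibration
(100 generator replicates), 300 survival genes for the metaplot peak,
50 miRNAs × 20 tissue samples for dominance, and a 6-reference read
set for end-to-end shift recovery. The match-count oracle comparison
runs 10,000 random sequence/seed cases against an independent
regex-with-lookahead implementation.

## Known limitations

* The longest-common-substring read matcher is exact but quadratic per
  read–reference pair; it is intended for collapsed read sets against
  the ~2600-arm miRNA complement, not genome-scale alignment.
* Expression matching of cohorts is a greedy nearest-RPM pairing
  helper; cohorts with very different RPM distributions should be
  matched upstream.
* The arm-dominance call depends on an absolute expression threshold
  (`min_sum`), so rescaling all RPMs changes which samples count as
  expressed (documented, inherent to the rule).
* Conservation groups, ages and oncogenic labels are input metadata;
  the package never infers them.
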