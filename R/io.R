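# Shared IO: FASTA/FASTQ and TSV readers/writers for every input schema,
# run configuration, and the pipeline driver that chains the modules.

#' Read gene region sequences from FASTA
#'
#' Headers follow `gene_id|transcript_id|region` with region one of
#' `utr5`, `cds`, `utr3`. Returns one row per gene with the three region
#' sequences as columns (missing regions are empty strings); when a gene
#' has several transcripts the longest-3'UTR one is kept (ties by
#' transcript id).
#'
#' @param path FASTA file path.
#' @return Tibble `gene_id`, `transcript_id`, `utr5`, `cds`, `utr3`.
#' @export
read_fasta_regions <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warn(sprintf("empty FASTA: %s", path))
    return(tibble(gene_id = character(), transcript_id = character(),
                  utr5 = character(), cds = character(), utr3 = character()))
  }
  parts <- stringr::str_split_fixed(names(set), stringr::fixed("|"), 3)
  if (any(parts[, 3] == "")) {
    abort(sprintf("%s: FASTA headers must be 'gene|transcript|region'", path),
          class = "seedtox_format_error")
  }
  if (!all(parts[, 3] %in% c("utr5", "cds", "utr3"))) {
    abort(sprintf("%s: region must be one of utr5/cds/utr3", path),
          class = "seedtox_format_error")
  }
  long <- tibble(gene_id = parts[, 1], transcript_id = parts[, 2],
                 region = parts[, 3], sequence = as.character(set))
  wide <- tidyr::pivot_wider(long, names_from = "region",
                             values_from = "sequence", values_fill = "")
  for (r in c("utr5", "cds", "utr3")) {
    if (!r %in% names(wide)) wide[[r]] <- ""
  }
  longest_utr_per_gene(wide)
}

#' Write gene regions as FASTA
#'
#' @param genes Gene-region tibble (`gene_id`, optional `transcript_id`,
#'   `utr5`, `cds`, `utr3`).
#' @param path Output path.
#' @export
write_fasta_regions <- function(genes, path) {
  genes <- as_tibble(genes)
  tx <- if ("transcript_id" %in% names(genes)) genes$transcript_id
        else genes$gene_id
  recs <- character(0)
  vals <- character(0)
  for (r in c("utr5", "cds", "utr3")) {
    if (!r %in% names(genes)) next
    keep <- nchar(genes[[r]]) > 0
    recs <- c(recs, paste(genes$gene_id[keep], tx[keep], r, sep = "|"))
    vals <- c(vals, genes[[r]][keep])
  }
  set <- Biostrings::BStringSet(vals)
  names(set) <- recs
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read small-RNA reads from FASTA/FASTQ
#'
#' FASTA headers of the form `id-count` carry collapsed multiplicities
#' (the trailing integer after the final `-`); headers without one get
#' count 1, as does every FASTQ read.
#'
#' @param path Input path.
#' @param sample Sample name attached to every read.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return Tibble `sequence`, `count`, `sample`.
#' @export
read_reads <- function(path, sample, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  set <- Biostrings::readBStringSet(path, format = format)
  if (length(set) == 0L) {
    warn(sprintf("empty read file: %s", path))
    return(tibble(sequence = character(), count = integer(),
                  sample = character()))
  }
  counts <- rep(1L, length(set))
  if (format == "fasta") {
    m <- stringr::str_match(names(set), "-(\\d+)$")[, 2]
    counts <- ifelse(is.na(m), 1L, as.integer(m))
  }
  tibble(sequence = unname(as.character(set)), count = counts,
         sample = sample)
}

#' Write collapsed reads as FASTA with `id-count` headers
#'
#' @param reads Tibble `sequence`, `count`.
#' @param path Output path.
#' @export
write_reads <- function(reads, path) {
  set <- Biostrings::BStringSet(reads$sequence)
  names(set) <- sprintf("read%d-%d", seq_len(nrow(reads)), reads$count)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

read_tsv_checked <- function(path, required, context) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s in %s", context,
                  paste(missing, collapse = ", "), path),
          class = "seedtox_format_error")
  }
  tbl
}

#' Read an shRNA screen table
#'
#' Columns: `id`, `guide_sequence`, `fold_down`.
#' @param path TSV path.
#' @return Tibble.
#' @export
read_shrna_table <- function(path) {
  read_tsv_checked(path, c("id", "guide_sequence", "fold_down"),
                   "shRNA table")
}

#' Read a mature miRNA arm annotation
#'
#' Columns: `mirna_id`, `arm`, `mature_seq`, optionally
#' `conservation_group`, `age_myr`, `is_mirtron`, `oncogenic_label`.
#' @param path TSV path.
#' @return Tibble.
#' @export
read_arm_annotation <- function(path) {
  read_tsv_checked(path, c("mirna_id", "arm", "mature_seq"),
                   "arm annotation")
}

#' Read an arm x sample expression matrix
#'
#' First two columns `mirna_id`, `arm`, then one numeric column per
#' sample.
#' @param path TSV path.
#' @return Tibble.
#' @export
read_arm_expression <- function(path) {
  read_tsv_checked(path, c("mirna_id", "arm"), "arm expression matrix")
}

#' Run a named analysis end to end
#'
#' Executes one of the package's analysis chains from a configuration
#' list (or YAML file) and writes TSV outputs plus a JSON run manifest
#' (analysis name, config hash, package version, output files,
#' timestamp) to the output directory.
#'
#' Analyses:
#' \describe{
#'   \item{`simulate`}{writes a full synthetic input bundle (viability
#'     table, gene regions FASTA + gene-set TSV, arm annotation and
#'     expression TSVs, control/treated read FASTAs).}
#'   \item{`screen_stats`}{ranks one or two viability tables, writes the
#'     ranking, toxicity classes, cross-screen correlation and
#'     shared-extreme depths.}
#' }
#'
#' @param config List (or path to a YAML file) with at least `analysis`
#'   and `out_dir`; `rng_seed` and analysis-specific fields as needed
#'   (`viability`, `viability_b` paths for `screen_stats`; any
#'   [sim_config()] argument under `sim` for `simulate`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$analysis),
            !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(as_tibble(tbl), path, progress = FALSE)
    outputs <<- c(outputs, name)
  }

  if (config$analysis == "simulate") {
    sim_args <- config$sim %||% list()
    if (!is.null(config$rng_seed)) sim_args$rng_seed <- config$rng_seed
    cfg <- do.call(sim_config, sim_args)
    vt <- sim_viability_table(cfg)
    emit(vt$table, "viability.tsv")
    cohorts <- sim_gene_cohorts(cfg, n_sg = config$n_sg %||% 200,
                                n_nonsg = config$n_nonsg %||% 200)
    write_fasta_regions(cohorts$genes, file.path(out_dir, "regions.fasta"))
    outputs <- c(outputs, "regions.fasta")
    emit(dplyr::select(cohorts$genes, "gene_id", "set_label", "rpm"),
         "gene_sets.tsv")
    mir <- sim_mirna_annotation(cfg, n = config$n_mirna %||% 50)
    emit(mir$arms, "arms.tsv")
    emit(mir$expression, "arm_expression.tsv")
    reads <- sim_ago_readset(cfg, dplyr::filter(mir$arms, .data$arm == "5p"))
    for (smp in c("control", "treated")) {
      write_reads(reads[reads$sample == smp, ],
                  file.path(out_dir, paste0("reads_", smp, ".fasta")))
      outputs <- c(outputs, paste0("reads_", smp, ".fasta"))
    }
  } else if (config$analysis == "screen_stats") {
    table_a <- read_viability_table(config$viability)
    ranked <- rank_seeds(table_a)
    ranked$toxicity_class <- classify_toxicity(ranked$viability)
    emit(ranked, "seed_ranking.tsv")
    if (!is.null(config$viability_b)) {
      table_b <- read_viability_table(config$viability_b)
      emit(cross_screen_correlation(table_a, table_b), "correlation.tsv")
      top <- shared_extreme_seeds(table_a, table_b, k = config$k %||% 20,
                                  end = "top")
      bottom <- shared_extreme_seeds(table_a, table_b, k = config$k %||% 20,
                                     end = "bottom")
      emit(tibble(end = c("top", "bottom"),
                  depth = c(top$depth, bottom$depth),
                  seeds = c(paste(top$seeds, collapse = ","),
                            paste(bottom$seeds, collapse = ","))),
           "shared_extremes.tsv")
    }
  } else {
    abort(sprintf("unknown analysis '%s'", config$analysis),
          class = "seedtox_config_error")
  }

  hash_cfg <- config
  hash_cfg$out_dir <- NULL
  manifest <- list(
    analysis = config$analysis,
    config_hash = rlang::hash(hash_cfg),
    package_version = as.character(utils::packageVersion("seedtox")),
    outputs = outputs,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
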