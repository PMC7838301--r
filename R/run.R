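#' Run a quantitation job from a configuration
#'
#' Headless end-to-end run: reads the input files named in the configuration,
#' executes the pipeline for one algorithmic combination, writes the three
#' result tables plus a run log, and returns the result invisibly.
#'
#' The configuration is a YAML file (or an equivalent named list) with keys:
#' `spectra` (mzML/mzXML path), `psms` (pepXML or PSM TSV), `proteins`
#' (optional protXML or protein TSV), `matrix_csv` (optional impurity CSV),
#' `plex`, `pairs` (vector of `"num/den"` strings), `peptide_kernel`,
#' `protein_kernel`, `normalization`, `rcc_enabled`, `fdr_threshold`,
#' `reporter_tolerance_th`, `weight_scheme`, `unique_peptides_only`,
#' `require_complete_channels`, `out_dir`.
#'
#' @param config Path to a YAML configuration file, or a named list.
#' @param overrides Named list of values that win over the file's (mirrors
#'   command-line flag overrides).
#' @return The `quant_result`, invisibly.
#' @export
run_quant <- function(config, overrides = list()) {
  cfg <- load_run_config(config, overrides)
  dataset <- load_config_dataset(cfg)
  result <- quantify(
    dataset, pairs = cfg$pairs,
    peptide_kernel = cfg$peptide_kernel %||% "MedianPsmRatio",
    protein_kernel = cfg$protein_kernel %||% "MedianPepRatio",
    normalization = cfg$normalization %||% "none",
    rcc = isTRUE(cfg$rcc_enabled),
    fdr_threshold = cfg$fdr_threshold %||% 0.01,
    reporter_tol = cfg$reporter_tolerance_th %||% 0.002,
    weight_scheme = cfg$weight_scheme %||% "pair",
    unique_peptides_only = cfg$unique_peptides_only %||% TRUE,
    require_complete_channels = isTRUE(cfg$require_complete_channels)
  )
  out_dir <- cfg$out_dir %||% "."
  write_quant_tables(result, out_dir)
  log_lines <- c(
    paste0("psms_read: ", result$counts$psms_read),
    paste0("psms_kept: ", result$counts$psms_kept),
    paste0("psms_dropped_empty: ", result$counts$psms_dropped_empty),
    paste0("proteins_quantified: ", result$counts$proteins_quantified),
    paste0("combination: ", paste(unlist(result$combination), collapse = "~"))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  message(paste(log_lines, collapse = "; "))
  invisible(result)
}

#' Run a combination sweep from a configuration
#'
#' Like [run_quant()], but executes every combination allowed by
#' `normalization_subset` (all seven strategies by default) and writes one
#' metrics row per combination to `sweep_metrics.tsv` in `out_dir`. The
#' configuration must name a ground-truth file (`truth`, a TSV with
#' `accession`, `class` and one abundance column per channel, as written by
#' [write_fixture_files()], or long form with `pair` and `ideal` columns).
#'
#' @inheritParams run_quant
#' @param normalization_subset Subset of [normalization_strategies()].
#' @return The metrics tibble, invisibly.
#' @export
run_sweep <- function(config, overrides = list(),
                      normalization_subset = normalization_strategies()) {
  cfg <- load_run_config(config, overrides)
  if (is.null(cfg$truth)) stop("Sweep requires a ground-truth file ('truth')",
                               call. = FALSE)
  dataset <- load_config_dataset(cfg)
  truth_raw <- readr::read_tsv(cfg$truth, show_col_types = FALSE,
                               progress = FALSE)
  truth <- if (all(c("pair", "ideal") %in% names(truth_raw))) truth_raw
           else ground_truth_ratios(truth_raw, cfg$pairs)
  metrics <- sweep_quant(
    dataset, pairs = cfg$pairs,
    combinations = enumerate_combinations(normalization_subset),
    truth = truth,
    fdr_threshold = cfg$fdr_threshold %||% 0.01,
    reporter_tol = cfg$reporter_tolerance_th %||% 0.002,
    weight_scheme = cfg$weight_scheme %||% "pair",
    unique_peptides_only = cfg$unique_peptides_only %||% TRUE,
    require_complete_channels = isTRUE(cfg$require_complete_channels)
  )
  out_dir <- cfg$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_tsv(metrics, file.path(out_dir, "sweep_metrics.tsv"),
                   na = "", progress = FALSE)
  invisible(metrics)
}

load_run_config <- function(config, overrides = list()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  for (key in c("spectra", "psms", "proteins", "matrix_csv", "truth")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("Configured path does not exist: ", key, " = ", cfg[[key]],
           call. = FALSE)
    }
  }
  if (is.null(cfg$spectra) || is.null(cfg$psms)) {
    stop("Configuration must name 'spectra' and 'psms' inputs", call. = FALSE)
  }
  if (is.null(cfg$pairs)) stop("Configuration must name 'pairs'", call. = FALSE)
  cfg$pairs <- as.character(unlist(cfg$pairs))
  cfg
}

load_config_dataset <- function(cfg) {
  spectra <- read_spectra(cfg$spectra)
  psms <- if (grepl("\\.pep\\.?xml$", cfg$psms, ignore.case = TRUE)) {
    read_pepxml(cfg$psms)
  } else read_psm_table(cfg$psms)
  proteins <- NULL
  if (!is.null(cfg$proteins)) {
    proteins <- if (grepl("\\.prot\\.?xml$", cfg$proteins, ignore.case = TRUE)) {
      read_protxml(cfg$proteins)
    } else read_protein_table(cfg$proteins)
  }
  mtx <- if (!is.null(cfg$matrix_csv)) {
    load_correction_matrix(cfg$matrix_csv, plex_name = cfg$plex)
  } else NULL
  channels <- if (!is.null(cfg$plex)) plex_channels(cfg$plex) else NULL
  quant_dataset(spectra, psms, proteins, matrix = mtx, plex = cfg$plex,
                channels = channels)
}
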