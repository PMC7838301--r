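#' Kernel and combination enumerations
#'
#' Peptide ratios can be computed from PSMs by four kernels, protein ratios by
#' six (four acting on PSM ratios directly and two rolling up peptide ratios).
#' Together with the seven normalization strategies and the ratio-compression
#' correction toggle this yields a lattice of 4 x 6 x 7 x 2 = 336 algorithmic
#' combinations.
#'
#' @return Character vectors of kernel names.
#' @export
peptide_kernels <- function() {
  c("LinearRegression", "SumPsmIntensity", "MedianPsmRatio", "WeightedPsmRatio")
}

#' @rdname peptide_kernels
#' @export
protein_kernels <- function() {
  c("SumPsmIntensity", "MedianPsmRatio", "WeightedPsmRatio",
    "TrimmedMeanPsmRatio", "MedianPepRatio", "WeightedPepRatio")
}

# Protein kernels that operate on PSM ratios directly, so the peptide kernel
# does not influence the protein-level output.
psm_level_protein_kernels <- function() {
  c("SumPsmIntensity", "MedianPsmRatio", "WeightedPsmRatio",
    "TrimmedMeanPsmRatio")
}

#' Enumerate algorithmic combinations
#'
#' Full cross product of peptide kernels, protein kernels, normalization
#' strategies and the RCC toggle, in deterministic lexicographic order (by the
#' canonical ordering of each enumeration). The full lattice has
#' 4 x 6 x 7 x 2 = 336 points; restricting normalization to `"none"` gives 48.
#'
#' @param normalizations Subset of [normalization_strategies()] to include.
#' @param peptide,protein Subsets of the kernel enumerations.
#' @param rcc Logical vector of RCC settings to include.
#' @return A tibble with columns `combination_id`, `peptide_kernel`,
#'   `protein_kernel`, `normalization`, `rcc`.
#' @examples
#' nrow(enumerate_combinations())            # 336
#' nrow(enumerate_combinations("none"))      # 48
#' @export
enumerate_combinations <- function(normalizations = normalization_strategies(),
                                   peptide = peptide_kernels(),
                                   protein = protein_kernels(),
                                   rcc = c(FALSE, TRUE)) {
  normalizations <- match.arg(normalizations, normalization_strategies(),
                              several.ok = TRUE)
  peptide <- match.arg(peptide, peptide_kernels(), several.ok = TRUE)
  protein <- match.arg(protein, protein_kernels(), several.ok = TRUE)
  stopifnot(length(normalizations) >= 1L, length(rcc) >= 1L)
  grid <- tidyr::expand_grid(
    peptide_kernel = factor(peptide, levels = peptide_kernels()),
    protein_kernel = factor(protein, levels = protein_kernels()),
    normalization = factor(normalizations,
                           levels = normalization_strategies()),
    rcc = sort(unique(rcc))
  )
  grid <- dplyr::arrange(grid, .data$peptide_kernel, .data$protein_kernel,
                         .data$normalization, .data$rcc)
  grid <- dplyr::mutate(grid,
    peptide_kernel = as.character(.data$peptide_kernel),
    protein_kernel = as.character(.data$protein_kernel),
    normalization = as.character(.data$normalization),
    combination_id = paste(.data$peptide_kernel, .data$protein_kernel,
                           .data$normalization,
                           ifelse(.data$rcc, "enRCC", "disRCC"), sep = "~")
  )
  dplyr::select(grid, "combination_id", "peptide_kernel", "protein_kernel",
                "normalization", "rcc")
}

#' Assemble a quantitation dataset
#'
#' Bundles the pieces of one run: spectra, identifications, the impurity
#' matrix, and the plex channel layout.
#'
#' @param spectra Spectra tibble ([read_spectra()]).
#' @param psms PSM tibble ([read_pepxml()], [read_psm_table()]).
#' @param proteins Optional protein-group tibble ([read_protxml()],
#'   [read_protein_table()]).
#' @param matrix An `impurity_matrix`; defaults to the identity for `plex`.
#' @param plex Plex name used to resolve reporter m/z values; defaults to the
#'   matrix's plex name.
#' @param channels Channel tibble overriding the plex layout (columns `label`,
#'   `reporter_mz`).
#' @return A `quant_dataset` list.
#' @export
quant_dataset <- function(spectra, psms, proteins = NULL, matrix = NULL,
                          plex = NULL, channels = NULL) {
  if (is.null(channels)) {
    key <- plex %||% matrix$plex_name
    if (is.null(key)) stop("Provide 'plex' or 'channels'", call. = FALSE)
    channels <- plex_channels(key)
  }
  if (is.null(matrix)) {
    matrix <- new_impurity_matrix(diag(nrow(channels)), channels$label,
                                  plex %||% "custom")
  }
  if (!identical(matrix$channels, channels$label)) {
    stop("Impurity matrix channels do not match the plex channel layout",
         call. = FALSE)
  }
  structure(
    list(spectra = spectra, psms = psms, proteins = proteins,
         matrix = matrix, channels = channels),
    class = "quant_dataset"
  )
}

#' PSM-level ratios for a set of channel pairs
#'
#' For each PSM and channel pair, the ratio of the (processed) reporter
#' intensities of the two channels, together with its weight. A PSM's ratio is
#' undefined (`NA`) when either channel's intensity is not positive; undefined
#' ratios are excluded from all aggregation. The weight is the summed reporter
#' intensity, either of the two selected channels (`weight_scheme = "pair"`,
#' the default: the weight tracks the information content of that specific
#' ratio) or of all channels (`"all"`).
#'
#' @param intensities Wide tibble (`psm_id` + one column per channel).
#' @param pairs Character vector of `"num/den"` pair strings, or a tibble from
#'   [parse_channel_pairs()].
#' @param weight_scheme `"pair"` or `"all"`.
#' @return Tibble `psm_id`, `pair`, `num`, `den`, `value`, `weight` (one row
#'   per PSM per pair; `value` may be `NA`).
#' @export
psm_ratios <- function(intensities, pairs, weight_scheme = c("pair", "all")) {
  weight_scheme <- match.arg(weight_scheme)
  if (is.character(pairs)) pairs <- parse_channel_pairs(pairs)
  channel_cols <- setdiff(names(intensities)[vapply(intensities, is.numeric, TRUE)],
                          c("s2i", "retention_time"))
  all_sum <- rowSums(as.matrix(intensities[, channel_cols]))
  out <- purrr::pmap(pairs, function(pair, numerator, denominator) {
    num <- intensities[[numerator]]
    den <- intensities[[denominator]]
    if (is.null(num) || is.null(den)) {
      stop("Channel '", if (is.null(num)) numerator else denominator,
           "' not found in the intensity table", call. = FALSE)
    }
    tibble::tibble(
      psm_id = intensities$psm_id,
      pair = pair,
      num = num,
      den = den,
      value = ifelse(num > 0 & den > 0, num / den, NA_real_),
      weight = if (weight_scheme == "pair") num + den else all_sum
    )
  })
  dplyr::bind_rows(out)
}

# One row per (psm_id, accession) assignment. unique_only keeps PSMs that
# resolve to exactly one protein group (unique-peptide mode).
assign_psms_to_proteins <- function(psms, kept_accessions = NULL,
                                    unique_only = TRUE) {
  amap <- tibble::tibble(
    psm_id = rep(psms$psm_id, lengths(psms$proteins)),
    peptide_key = rep(psms$peptide_key, lengths(psms$proteins)),
    accession = unlist(psms$proteins)
  )
  if (!is.null(kept_accessions)) {
    amap <- amap[amap$accession %in% kept_accessions, ]
  }
  amap <- dplyr::distinct(amap)
  if (unique_only) {
    counts <- dplyr::count(dplyr::distinct(amap, .data$psm_id, .data$accession),
                           .data$psm_id)
    unique_ids <- counts$psm_id[counts$n == 1L]
    amap <- amap[amap$psm_id %in% unique_ids, ]
  }
  amap
}

# Aggregate PSM rows to peptide ratios under one peptide kernel.
aggregate_peptides <- function(psm_pair_tbl, kernel) {
  kernel <- match.arg(kernel, peptide_kernels())
  dplyr::summarise(
    dplyr::group_by(psm_pair_tbl, .data$accession, .data$peptide_key,
                    .data$pair),
    value = switch(
      kernel,
      LinearRegression = regression_slope_ratio(.data$den, .data$num),
      SumPsmIntensity = sum_intensity_ratio(.data$num, .data$den),
      MedianPsmRatio = median_ratio(.data$value),
      WeightedPsmRatio = weighted_mean_ratio(.data$value, .data$weight)
    ),
    weight = peptide_weight(.data$weight[!is.na(.data$value)]),
    n_psms = sum(!is.na(.data$value)),
    .groups = "drop"
  )
}

# Aggregate to protein ratios under one protein kernel.
aggregate_proteins <- function(psm_pair_tbl, peptide_tbl, kernel) {
  kernel <- match.arg(kernel, protein_kernels())
  if (kernel %in% psm_level_protein_kernels()) {
    out <- dplyr::summarise(
      dplyr::group_by(psm_pair_tbl, .data$accession, .data$pair),
      value = switch(
        kernel,
        SumPsmIntensity = sum_intensity_ratio(.data$num, .data$den),
        MedianPsmRatio = median_ratio(.data$value),
        WeightedPsmRatio = weighted_mean_ratio(.data$value, .data$weight),
        TrimmedMeanPsmRatio = trimmed_mean_ratio(.data$value)
      ),
      n_psms = sum(!is.na(.data$value)),
      n_peptides = dplyr::n_distinct(.data$peptide_key[!is.na(.data$value)]),
      .groups = "drop"
    )
  } else {
    pep <- peptide_tbl[!is.na(peptide_tbl$value), ]
    out <- dplyr::summarise(
      dplyr::group_by(pep, .data$accession, .data$pair),
      value = switch(
        kernel,
        MedianPepRatio = median_ratio(.data$value),
        WeightedPepRatio = weighted_mean_ratio(.data$value, .data$weight)
      ),
      n_psms = sum(.data$n_psms),
      n_peptides = dplyr::n(),
      .groups = "drop"
    )
  }
  out[!is.na(out$value), ]
}

#' Run the full quantitation pipeline for one algorithmic combination
#'
#' Executes, in order: FDR filtering, reporter-ion extraction,
#' isotope-impurity correction, ratio-compression correction (when enabled),
#' reporter-level normalization (when in the strategy), PSM ratios, peptide
#' ratios, peptide-ratio normalization, protein ratios, and protein-ratio
#' normalization. Ratio-level normalizations are applied per channel pair.
#'
#' @param dataset A `quant_dataset` (see [quant_dataset()]).
#' @param pairs Character vector of `"num/den"` channel pairs.
#' @param peptide_kernel,protein_kernel Kernel names (see [peptide_kernels()],
#'   [protein_kernels()]).
#' @param normalization One of [normalization_strategies()].
#' @param rcc Enable ratio-compression correction.
#' @param fdr_threshold FDR gate for identifications (default 0.01).
#' @param reporter_tol Reporter extraction window half-width (Th).
#' @param weight_scheme PSM weight definition, `"pair"` (default) or `"all"`.
#' @param unique_peptides_only Restrict protein rollup to PSMs mapping to a
#'   single protein group (default `TRUE`).
#' @param require_complete_channels Drop PSMs with a zero intensity in any
#'   channel (default `FALSE`; PSMs that are zero in *every* channel are
#'   always dropped).
#' @param s2i_kmax,s2i_match_ppm,s2i_interpolate S2I estimation settings (see
#'   [compute_s2i()]).
#' @return A `quant_result`: list with tibbles `proteins` (`accession`, `pair`,
#'   `value`, `n_psms`, `n_peptides`), `peptides`, `psms` (per-stage channel
#'   intensities and S2I), plus `combination`, `pairs` and a `counts` list.
#' @export
quantify <- function(dataset, pairs,
                     peptide_kernel = "MedianPsmRatio",
                     protein_kernel = "MedianPepRatio",
                     normalization = "none",
                     rcc = FALSE,
                     fdr_threshold = 0.01,
                     reporter_tol = 0.002,
                     weight_scheme = c("pair", "all"),
                     unique_peptides_only = TRUE,
                     require_complete_channels = FALSE,
                     s2i_kmax = 3L, s2i_match_ppm = 10,
                     s2i_interpolate = TRUE) {
  weight_scheme <- match.arg(weight_scheme)
  prep <- prepare_profiles(dataset, fdr_threshold, reporter_tol,
                           require_complete_channels, s2i_kmax, s2i_match_ppm,
                           s2i_interpolate)
  finish_quantify(prep, dataset, pairs, peptide_kernel, protein_kernel,
                  normalization, rcc, weight_scheme, unique_peptides_only)
}

# Stage shared across combinations: FDR filter, extraction, impurity
# correction, S2I. Returned object feeds finish_quantify() (used directly by
# quantify() and cached by sweep_quant()).
prepare_profiles <- function(dataset, fdr_threshold, reporter_tol,
                             require_complete_channels, s2i_kmax,
                             s2i_match_ppm, s2i_interpolate) {
  stopifnot(inherits(dataset, "quant_dataset"))
  filt <- filter_by_fdr(dataset$psms, dataset$proteins, fdr_threshold)
  psms <- filt$psms
  channels <- dataset$channels
  raw <- reporter_intensities(psms, dataset$spectra, channels, reporter_tol)
  psms <- psms[psms$psm_id %in% raw$psm_id, ]
  corrected <- correct_impurities(raw, dataset$matrix)

  labels <- channels$label
  mat <- as.matrix(corrected[, labels])
  all_zero <- rowSums(mat) <= 0
  incomplete <- if (require_complete_channels) {
    apply(mat, 1, function(v) any(v <= 0))
  } else all_zero
  n_dropped <- sum(incomplete)
  if (n_dropped > 0L) {
    message(n_dropped, " PSM(s) dropped: ",
            if (require_complete_channels) "missing reporter in some channel"
            else "zero intensity in every channel")
  }
  keep <- !incomplete
  raw <- raw[keep, ]; corrected <- corrected[keep, ]; psms <- psms[keep, ]

  s2i <- compute_s2i(psms, dataset$spectra, k_max = s2i_kmax,
                     match_ppm = s2i_match_ppm,
                     interpolate = s2i_interpolate)
  rcc_corrected <- apply_rcc(corrected, s2i$s2i, channels = labels)

  list(psms = psms, proteins = filt$proteins, raw = raw,
       corrected = corrected, rcc_corrected = rcc_corrected, s2i = s2i,
       labels = labels,
       counts = list(psms_read = nrow(dataset$psms), psms_kept = nrow(psms),
                     psms_dropped_empty = n_dropped))
}

finish_quantify <- function(prep, dataset, pairs, peptide_kernel,
                            protein_kernel, normalization, rcc, weight_scheme,
                            unique_peptides_only) {
  peptide_kernel <- match.arg(peptide_kernel, peptide_kernels())
  protein_kernel <- match.arg(protein_kernel, protein_kernels())
  levels_on <- strategy_levels(normalization)
  labels <- prep$labels
  pairs_tbl <- parse_channel_pairs(pairs, dataset$channels)

  stage <- if (isTRUE(rcc)) prep$rcc_corrected else prep$corrected
  if ("reporter" %in% levels_on) {
    stage <- normalize_reporter_medians(stage, channels = labels)
  }

  ppt <- psm_ratios(stage, pairs_tbl, weight_scheme = weight_scheme)
  amap <- assign_psms_to_proteins(
    prep$psms,
    kept_accessions = if (!is.null(prep$proteins)) prep$proteins$accession,
    unique_only = unique_peptides_only
  )
  ppt <- dplyr::inner_join(ppt, amap, by = "psm_id", relationship = "many-to-many")

  peptides <- aggregate_peptides(ppt, peptide_kernel)
  if ("peptide" %in% levels_on) {
    peptides <- dplyr::mutate(
      dplyr::group_by(peptides, .data$pair),
      value = normalize_ratio_vector(.data$value)
    )
    peptides <- dplyr::ungroup(peptides)
  }

  proteins <- aggregate_proteins(ppt, peptides, protein_kernel)
  if ("protein" %in% levels_on && nrow(proteins) > 0L) {
    proteins <- dplyr::mutate(
      dplyr::group_by(proteins, .data$pair),
      value = normalize_ratio_vector(.data$value)
    )
    proteins <- dplyr::ungroup(proteins)
  }
  proteins <- dplyr::arrange(proteins, .data$accession, .data$pair)

  psm_out <- build_psm_output(prep, stage, rcc, levels_on, labels)
  structure(
    list(
      proteins = proteins,
      peptides = dplyr::arrange(peptides, .data$accession, .data$peptide_key,
                                .data$pair),
      psms = psm_out,
      psm_ratios = dplyr::arrange(ppt, .data$psm_id, .data$pair),
      combination = tibble::tibble(
        peptide_kernel = peptide_kernel, protein_kernel = protein_kernel,
        normalization = normalization, rcc = isTRUE(rcc)
      ),
      pairs = pairs_tbl,
      counts = c(prep$counts,
                 list(proteins_quantified = dplyr::n_distinct(proteins$accession)))
    ),
    class = "quant_result"
  )
}

build_psm_output <- function(prep, stage, rcc, levels_on, labels) {
  out <- tibble::tibble(
    psm_id = prep$psms$psm_id,
    scan_id = prep$psms$scan_id,
    peptide_key = prep$psms$peptide_key,
    s2i = prep$s2i$s2i
  )
  add <- function(out, tbl, prefix) {
    block <- tbl[, labels]
    names(block) <- paste0(prefix, "_", labels)
    dplyr::bind_cols(out, block)
  }
  out <- add(out, prep$raw, "raw")
  out <- add(out, prep$corrected, "corrected")
  if (isTRUE(rcc)) out <- add(out, prep$rcc_corrected, "rcc")
  if ("reporter" %in% levels_on) out <- add(out, stage, "normalized")
  out
}

#' @export
print.quant_result <- function(x, ...) {
  cat("<quant_result> ", x$combination$peptide_kernel, "~",
      x$combination$protein_kernel, "~", x$combination$normalization, "~",
      if (x$combination$rcc) "enRCC" else "disRCC", "\n", sep = "")
  cat("  PSMs kept:", x$counts$psms_kept,
      "| proteins quantified:", x$counts$proteins_quantified, "\n")
  cat("  pairs:", paste(x$pairs$pair, collapse = ", "), "\n")
  invisible(x)
}

#' Sweep the algorithmic-combination lattice
#'
#' Runs every requested combination on one dataset, reusing the shared
#' preprocessing stages (extraction, impurity correction, S2I, the two RCC
#' states and the two reporter-normalization states) so the lattice sweep
#' costs little more than the protein rollups. When ground truth is supplied,
#' one row of evaluation metrics per combination is returned; otherwise the
#' protein tables are returned as a list-column.
#'
#' @inheritParams quantify
#' @param combinations Tibble from [enumerate_combinations()].
#' @param truth Optional ground-truth tibble with columns `accession`, `pair`,
#'   `ideal` and optionally `class` (`"standard"`/`"background"`).
#' @return A tibble: the combination columns plus either metric columns
#'   (`auccd`, `are`, `are_std`, `are_bg`, `rmse`, `n_proteins`) or a
#'   `proteins` list-column, sorted stably by `combination_id` order of
#'   `combinations`.
#' @export
sweep_quant <- function(dataset, pairs,
                        combinations = enumerate_combinations(),
                        truth = NULL,
                        fdr_threshold = 0.01, reporter_tol = 0.002,
                        weight_scheme = c("pair", "all"),
                        unique_peptides_only = TRUE,
                        require_complete_channels = FALSE,
                        s2i_kmax = 3L, s2i_match_ppm = 10,
                        s2i_interpolate = TRUE) {
  weight_scheme <- match.arg(weight_scheme)
  prep <- prepare_profiles(dataset, fdr_threshold, reporter_tol,
                           require_complete_channels, s2i_kmax, s2i_match_ppm,
                           s2i_interpolate)
  pairs_tbl <- parse_channel_pairs(pairs, dataset$channels)
  labels <- prep$labels

  # Stage cache: (rcc, reporter-normalized) -> intensity table and PSM ratios.
  stage_key <- function(rcc, rep_norm) paste0(rcc, ".", rep_norm)
  stages <- list()
  for (rcc in unique(combinations$rcc)) {
    base <- if (isTRUE(rcc)) prep$rcc_corrected else prep$corrected
    for (rep_norm in c(FALSE, TRUE)) {
      tbl <- if (rep_norm) normalize_reporter_medians(base, channels = labels) else base
      stages[[stage_key(rcc, rep_norm)]] <- tbl
    }
  }
  amap <- assign_psms_to_proteins(
    prep$psms,
    kept_accessions = if (!is.null(prep$proteins)) prep$proteins$accession,
    unique_only = unique_peptides_only
  )
  psm_tables <- lapply(stages, function(tbl) {
    ppt <- psm_ratios(tbl, pairs_tbl, weight_scheme = weight_scheme)
    dplyr::inner_join(ppt, amap, by = "psm_id", relationship = "many-to-many")
  })
  # Peptide cache: (stage, peptide kernel).
  pep_cache <- new.env(parent = emptyenv())
  get_peptides <- function(key, kernel) {
    ck <- paste0(key, "|", kernel)
    if (is.null(pep_cache[[ck]])) {
      pep_cache[[ck]] <- aggregate_peptides(psm_tables[[key]], kernel)
    }
    pep_cache[[ck]]
  }

  rows <- purrr::pmap(combinations, function(combination_id, peptide_kernel,
                                             protein_kernel, normalization,
                                             rcc) {
    levels_on <- strategy_levels(normalization)
    key <- stage_key(rcc, "reporter" %in% levels_on)
    ppt <- psm_tables[[key]]
    peptides <- get_peptides(key, peptide_kernel)
    if ("peptide" %in% levels_on) {
      peptides <- dplyr::ungroup(dplyr::mutate(
        dplyr::group_by(peptides, .data$pair),
        value = normalize_ratio_vector(.data$value)))
    }
    proteins <- aggregate_proteins(ppt, peptides, protein_kernel)
    if ("protein" %in% levels_on && nrow(proteins) > 0L) {
      proteins <- dplyr::ungroup(dplyr::mutate(
        dplyr::group_by(proteins, .data$pair),
        value = normalize_ratio_vector(.data$value)))
    }
    if (is.null(truth)) {
      tibble::tibble(combination_id = combination_id,
                     proteins = list(proteins))
    } else {
      dplyr::bind_cols(tibble::tibble(combination_id = combination_id),
                       evaluate_ratios(proteins, truth))
    }
  })
  dplyr::left_join(combinations, dplyr::bind_rows(rows), by = "combination_id")
}
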