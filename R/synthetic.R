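#' Specification for a synthetic isobaric-labeling dataset
#'
#' Defines the ground truth and noise structure of a generated dataset:
#' proteins of one or more abundance classes (each class is a strictly
#' positive per-channel abundance vector), log-normal multiplicative peak
#' noise of a given coefficient of variation, co-isolation interference
#' contributing a fixed fraction of the reporter signal as a flat 1:1 vector,
#' and an isotope-impurity matrix folded into the observed intensities. The
#' defaults emulate a standard-protein spike-in design: a minority of
#' "standard" proteins at varying fold changes over a majority of 1:1
#' "background" proteins, with 10% peak noise and a clean (interference-free)
#' acquisition.
#'
#' @param n_proteins Number of proteins (default 50).
#' @param peptides_per_protein Integer range `c(min, max)` (default `c(2, 4)`).
#' @param psms_per_peptide Integer range (default `c(1, 4)`).
#' @param plex Plex preset name (default `"tmt6"`).
#' @param ratios Named list: class name -> per-channel abundance vector
#'   (length = number of channels, all positive). The default is a balanced
#'   spike-in panel: three "standard" sub-classes whose fold-change patterns
#'   are cyclic permutations of (1, 2, 4), so every channel carries the same
#'   total spike mass and the equal-loading assumption behind reporter-level
#'   normalization holds by construction, over a 1:1 background.
#' @param class_fractions Named numeric: fraction of proteins per class (same
#'   names as `ratios`; must sum to 1).
#' @param class_labels Named character mapping each ratio class to the class
#'   reported in the ground truth (e.g. several spike-in sub-classes all
#'   labelled `"standard"`). Defaults to the ratio class names themselves.
#' @param cv_noise Coefficient of variation of the multiplicative log-normal
#'   noise on each reporter peak (default 0.1).
#' @param noise_correlation Fraction of the peak-noise variance shared by all
#'   channels of a scan (default 0.8). Reporter ions of one MS2 spectrum are
#'   acquired together, so ion-sampling and injection-time fluctuations hit
#'   all channels alike; only the channel-specific part of the noise
#'   propagates into ratios. The per-peak CV stays `cv_noise` regardless.
#' @param interference_fraction Fraction in \[0, 1) of the total reporter
#'   signal contributed by 1:1 co-isolation interference (default 0, i.e. a
#'   clean run); the realized precursor S2I is `1 - interference_fraction`.
#' @param impurity_table Optional percentage table (`channel, minus2, minus1,
#'   plus1, plus2`) to fold in; `NULL` means no impurity mixing.
#' @param base_intensity Median summed reporter intensity scale (arbitrary
#'   counts, default 1e5).
#' @param base_log_sd Log-scale SD of per-PSM base abundance (default 0.5,
#'   i.e. a 95% intensity range of roughly a factor of seven).
#' @param seed RNG seed (default 42).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_proteins = 50L,
                       peptides_per_protein = c(2L, 4L),
                       psms_per_peptide = c(1L, 4L),
                       plex = "tmt6",
                       ratios = NULL,
                       class_fractions = NULL,
                       class_labels = NULL,
                       cv_noise = 0.1,
                       noise_correlation = 0.8,
                       interference_fraction = 0,
                       impurity_table = NULL,
                       base_intensity = 1e5,
                       base_log_sd = 0.5,
                       seed = 42L) {
  channels <- plex_channels(plex)
  n_ch <- nrow(channels)
  if (is.null(ratios)) {
    base <- rep(c(1, 2, 4), length.out = n_ch)
    ratios <- list(
      standard_a = base,
      standard_b = base[c(2:n_ch, 1)],
      standard_c = base[c(3:n_ch, 1:2)],
      background = rep(1, n_ch)
    )
    if (is.null(class_fractions)) {
      class_fractions <- c(standard_a = 0.1, standard_b = 0.1,
                           standard_c = 0.1, background = 0.7)
    }
    if (is.null(class_labels)) {
      class_labels <- c(standard_a = "standard", standard_b = "standard",
                        standard_c = "standard", background = "background")
    }
  }
  if (is.null(class_fractions)) {
    class_fractions <- stats::setNames(rep(1 / length(ratios), length(ratios)),
                                       names(ratios))
  }
  if (is.null(class_labels)) {
    class_labels <- stats::setNames(names(ratios), names(ratios))
  }
  stopifnot(length(peptides_per_protein) == 2L, length(psms_per_peptide) == 2L,
            peptides_per_protein[1] >= 1L, psms_per_peptide[1] >= 1L,
            cv_noise >= 0, noise_correlation >= 0, noise_correlation <= 1,
            interference_fraction >= 0, interference_fraction < 1,
            abs(sum(class_fractions) - 1) < 1e-8,
            setequal(names(ratios), names(class_fractions)),
            all(names(ratios) %in% names(class_labels)))
  for (v in ratios) {
    stopifnot(length(v) == n_ch, all(v > 0))
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         peptides_per_protein = as.integer(peptides_per_protein),
         psms_per_peptide = as.integer(psms_per_peptide),
         plex = plex, channels = channels, ratios = ratios,
         class_fractions = class_fractions[names(ratios)],
         class_labels = class_labels,
         cv_noise = cv_noise, noise_correlation = noise_correlation,
         interference_fraction = interference_fraction,
         impurity_table = impurity_table,
         base_intensity = base_intensity, base_log_sd = base_log_sd,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Generate a synthetic dataset from a specification
#'
#' Builds spectra, identifications, the impurity matrix and ground truth.
#' Each PSM's reporter signal is the per-channel class abundance scaled by a
#' log-normal base intensity and per-channel log-normal noise (unit mean),
#' blended with a flat 1:1 interference vector contributing exactly
#' `interference_fraction` of the summed reporter signal, then forward-mixed
#' through the impurity matrix. Every MS2 scan is flanked by two private MS1
#' scans containing the precursor isotope cluster plus an interfering ion
#' placed so that the window's signal-to-interference equals
#' `1 - interference_fraction` exactly. All identifications carry posterior
#' probability 1. Deterministic under the spec's seed.
#'
#' @param spec A [synth_spec()].
#' @return A `synth_dataset` list: `spectra`, `psms`, `proteins`, `matrix`,
#'   `channels`, `truth` (per-protein class and per-channel abundance),
#'   `psm_truth` (`psm_id`, `s2i_true`), and the originating `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  channels <- spec$channels
  n_ch <- nrow(channels)
  M <- if (is.null(spec$impurity_table)) {
    new_impurity_matrix(diag(n_ch), channels$label, spec$plex)
  } else {
    impurity_table_to_matrix(spec$impurity_table, spec$plex)
  }
  if (!identical(M$channels, channels$label)) {
    stop("Impurity table channels must match the plex layout", call. = FALSE)
  }

  classes <- assign_classes(spec$n_proteins, spec$class_fractions)
  f <- spec$interference_fraction
  sigma <- sqrt(log(1 + spec$cv_noise^2))

  psm_rows <- list(); spec_rows <- list(); prot_rows <- list()
  truth_rows <- list(); psm_truth <- list()
  scan <- 0L; psm_k <- 0L; pep_k <- 0L
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

  for (p in seq_len(spec$n_proteins)) {
    acc <- sprintf("PROT%04d", p)
    cls <- classes[p]
    abund <- spec$ratios[[cls]]
    truth_rows[[p]] <- dplyr::bind_cols(
      tibble::tibble(accession = acc,
                     class = unname(spec$class_labels[[cls]])),
      tibble::as_tibble(as.list(stats::setNames(abund, channels$label)))
    )
    n_pep <- sample_range(spec$peptides_per_protein)
    pep_keys <- character(n_pep)
    for (j in seq_len(n_pep)) {
      pep_k <- pep_k + 1L
      pep_keys[j] <- paste0(paste(sample(aa, 9, replace = TRUE), collapse = ""),
                            "K_", pep_k)
      prec_mz <- stats::runif(1, 400, 1200)
      charge <- sample(2:3, 1)
      n_psm <- sample_range(spec$psms_per_peptide)
      for (s in seq_len(n_psm)) {
        psm_k <- psm_k + 1L
        base <- spec$base_intensity * stats::rlnorm(1, 0, spec$base_log_sd)
        rho <- spec$noise_correlation
        eps <- stats::rnorm(1, 0, sqrt(rho) * sigma) +
          stats::rnorm(n_ch, 0, sqrt(1 - rho) * sigma)
        noise <- exp(eps - sigma^2 / 2)
        signal <- base * abund * noise / sum(abund)
        i_total <- if (f > 0) sum(signal) * f / (1 - f) else 0
        true_x <- signal + i_total / n_ch
        observed <- as.numeric(M$matrix %*% true_x)

        rt0 <- 10 * psm_k
        ms1_peaks <- ms1_cluster_peaks(prec_mz, charge, sum(observed), f)
        ms2_peaks <- tibble::tibble(mz = channels$reporter_mz,
                                    intensity = observed)
        ms2_peaks <- ms2_peaks[order(ms2_peaks$mz), ]

        id_pre <- scan + 1L; id_ms2 <- scan + 2L; id_post <- scan + 3L
        scan <- scan + 3L
        spec_rows[[length(spec_rows) + 1L]] <- tibble::tibble(
          scan_id = as.character(c(id_pre, id_ms2, id_post)),
          ms_level = c(1L, 2L, 1L),
          retention_time = rt0 + c(0, 1, 2),
          peaks = list(ms1_peaks, ms2_peaks, ms1_peaks),
          target_mz = c(NA, prec_mz, NA),
          charge = c(NA, charge, NA),
          isolation_center = c(NA, prec_mz, NA),
          isolation_width = c(NA, 2, NA),
          parent_ms1_scan = c(NA, as.character(id_pre), NA)
        )
        psm_rows[[psm_k]] <- tibble::tibble(
          psm_id = sprintf("PSM%05d", psm_k),
          scan_id = as.character(id_ms2),
          peptide_key = pep_keys[j],
          charge = charge,
          proteins = list(acc),
          probability = 1.0,
          q_value = NA_real_,
          is_decoy = FALSE
        )
        psm_truth[[psm_k]] <- tibble::tibble(
          psm_id = sprintf("PSM%05d", psm_k), s2i_true = 1 - f
        )
      }
    }
    prot_rows[[p]] <- tibble::tibble(
      accession = acc, peptides = list(pep_keys), probability = 1.0,
      is_decoy = FALSE
    )
  }

  structure(
    list(
      spectra = dplyr::bind_rows(spec_rows),
      psms = dplyr::bind_rows(psm_rows),
      proteins = dplyr::bind_rows(prot_rows),
      matrix = M,
      channels = channels,
      truth = dplyr::bind_rows(truth_rows),
      psm_truth = dplyr::bind_rows(psm_truth),
      spec = spec
    ),
    class = "synth_dataset"
  )
}

sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
}

assign_classes <- function(n, fractions) {
  nm <- names(fractions)
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(fractions * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  rep(nm, times = counts)
}

# Precursor isotope cluster plus one interfering ion inside the +-1 Th
# isolation window, sized so that S2I = 1 - f exactly. Isotope peaks that
# would fall outside the window are omitted (they would count in neither the
# signal nor the window total). The interferer sits at +0.71 Th, away from
# any isotope position of charges 1-3 at 10 ppm.
ms1_cluster_peaks <- function(prec_mz, charge, scale, f, half_width = 1) {
  iso_rel <- c(1, 0.5, 0.2)
  offsets <- (0:2) * 1.00335 / charge
  keep <- offsets < half_width
  mz <- prec_mz + offsets[keep]
  int <- scale * 10 * iso_rel[keep]
  if (f > 0) {
    mz <- c(mz, prec_mz + 0.71)
    int <- c(int, sum(int) * f / (1 - f))
  }
  tb <- tibble::tibble(mz = mz, intensity = int)
  tb[order(tb$mz), ]
}

# Assemble an impurity matrix from an in-memory percentage table (same layout
# as the CSV format read by load_correction_matrix()).
impurity_table_to_matrix <- function(impurity_table, plex_name = "custom") {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  write_impurity_csv(impurity_table, tmp)
  read_impurity_csv(tmp, plex_name = plex_name)
}

#' Ideal protein ratios for a set of channel pairs
#'
#' Converts the per-channel abundance ground truth of a synthetic dataset into
#' per-pair ideal ratios, the format expected by [evaluate_ratios()].
#'
#' @param truth Truth tibble from [generate_dataset()] (`accession`, `class`,
#'   one abundance column per channel).
#' @param pairs Character vector of `"num/den"` pair strings.
#' @return Tibble `accession`, `pair`, `ideal`, `class`.
#' @export
ground_truth_ratios <- function(truth, pairs) {
  pairs_tbl <- parse_channel_pairs(pairs)
  out <- purrr::pmap(pairs_tbl, function(pair, numerator, denominator) {
    tibble::tibble(
      accession = truth$accession,
      pair = pair,
      ideal = truth[[numerator]] / truth[[denominator]],
      class = truth$class
    )
  })
  dplyr::bind_rows(out)
}

#' Convert a synthetic dataset to a quantitation dataset
#'
#' @param dataset A `synth_dataset` from [generate_dataset()].
#' @return A `quant_dataset` ready for [quantify()] or [sweep_quant()].
#' @export
as_quant_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "synth_dataset"))
  quant_dataset(dataset$spectra, dataset$psms, dataset$proteins,
                matrix = dataset$matrix, channels = dataset$channels)
}

#' Write a synthetic dataset as standard-format fixture files
#'
#' Emits `spectra.mzML`, `psms.tsv`, `proteins.tsv`, `impurity.csv` and
#' `truth.tsv` into a directory; all are readable back with the package's own
#' readers (see [read_fixture_dataset()]).
#'
#' @param dataset A `synth_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture_files <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_mzml(dataset$spectra, file.path(out_dir, "spectra.mzML"))
  write_psm_table(dataset$psms, file.path(out_dir, "psms.tsv"))
  write_protein_table(dataset$proteins, file.path(out_dir, "proteins.tsv"))
  imp <- dataset$spec$impurity_table
  if (is.null(imp)) {
    imp <- tibble::tibble(channel = dataset$channels$label,
                          minus2 = 0, minus1 = 0, plus1 = 0, plus2 = 0)
  }
  write_impurity_csv(imp, file.path(out_dir, "impurity.csv"))
  readr::write_tsv(dataset$truth, file.path(out_dir, "truth.tsv"),
                   progress = FALSE)
  readr::write_tsv(dataset$psm_truth, file.path(out_dir, "psm_truth.tsv"),
                   progress = FALSE)
  writeLines(yaml::as.yaml(list(plex = dataset$spec$plex)),
             file.path(out_dir, "dataset.yaml"))
  invisible(out_dir)
}

#' Read fixture files back into a quantitation dataset
#'
#' @param dir Directory written by [write_fixture_files()].
#' @return A list with `dataset` (a `quant_dataset`), `truth` and `psm_truth`.
#' @export
read_fixture_dataset <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "dataset.yaml"))
  spectra <- read_spectra(file.path(dir, "spectra.mzML"))
  psms <- read_psm_table(file.path(dir, "psms.tsv"))
  proteins <- read_protein_table(file.path(dir, "proteins.tsv"))
  matrix <- load_correction_matrix(file.path(dir, "impurity.csv"),
                                   plex_name = meta$plex)
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  psm_truth_path <- file.path(dir, "psm_truth.tsv")
  psm_truth <- if (file.exists(psm_truth_path)) {
    readr::read_tsv(psm_truth_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  list(
    dataset = quant_dataset(spectra, psms, proteins, matrix = matrix,
                            channels = plex_channels(meta$plex)),
    truth = truth,
    psm_truth = psm_truth
  )
}

#' Ratio-compression curve: measured ratio vs interference level
#'
#' For each interference fraction, generates a dataset (same seed, so runs are
#' paired), quantifies it with and without ratio-compression correction, and
#' reports the median protein ratio of the non-unit class alongside the truth.
#' Without correction the measured ratio shrinks toward 1 as interference
#' grows; with correction it tracks the truth while no channel clamps at zero.
#'
#' @param spec A [synth_spec()] whose first ratio class is not all-1.
#' @param interference_grid Numeric vector of interference fractions in
#'   \[0, 1).
#' @param pair A `"num/den"` pair string; defaults to the pair of the last and
#'   first channel.
#' @param protein_kernel Kernel used for the rollup (default
#'   `"MedianPsmRatio"`).
#' @return Tibble `interference`, `ideal`, `uncorrected`, `rcc`, `clamped`.
#' @export
compression_curve <- function(spec, interference_grid,
                              pair = NULL, protein_kernel = "MedianPsmRatio") {
  stopifnot(inherits(spec, "synth_spec"))
  labels <- spec$channels$label
  if (is.null(pair)) pair <- paste0(labels[length(labels)], "/", labels[1])
  pp <- parse_channel_pairs(pair, spec$channels)
  rows <- purrr::map(interference_grid, function(f) {
    sp <- spec
    sp$interference_fraction <- f
    ds <- generate_dataset(sp)
    qd <- as_quant_dataset(ds)
    truth <- ground_truth_ratios(ds$truth, pair)
    varying <- truth$ideal[truth$ideal != 1]
    ideal <- if (length(varying) > 0L) {
      as.numeric(names(which.max(table(varying))))
    } else 1
    accs <- truth$accession[truth$ideal == ideal]
    res_off <- quantify(qd, pair, protein_kernel = protein_kernel,
                        normalization = "none", rcc = FALSE)
    res_on <- quantify(qd, pair, protein_kernel = protein_kernel,
                       normalization = "none", rcc = TRUE)
    corr_cols <- paste0("corrected_", labels)
    rcc_cols <- paste0("rcc_", labels)
    clamped <- any(as.matrix(res_on$psms[, rcc_cols]) == 0 &
                     as.matrix(res_on$psms[, corr_cols]) > 0)
    tibble::tibble(
      interference = f,
      ideal = ideal,
      uncorrected = stats::median(
        res_off$proteins$value[res_off$proteins$accession %in% accs]),
      rcc = stats::median(
        res_on$proteins$value[res_on$proteins$accession %in% accs]),
      clamped = clamped
    )
  })
  dplyr::bind_rows(rows)
}
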