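#' Filter identifications to a target FDR at peptide and protein level
#'
#' Applies the default 1% false-discovery-rate gate before quantitation. When
#' PSMs carry a `q_value`, records with `q_value <= threshold` are kept.
#' Otherwise the model-based FDR implied by posterior probabilities is used:
#' records are sorted by probability (descending) and the longest prefix whose
#' running mean of `1 - p` stays at or below the threshold is kept. Protein
#' groups are filtered independently by the same probability rule, and PSMs
#' whose every mapped protein was removed are dropped.
#'
#' @param psms PSM tibble (see [read_pepxml()]).
#' @param proteins Optional protein-group tibble (see [read_protxml()]); when
#'   `NULL` only the PSM-level filter is applied.
#' @param threshold FDR threshold in (0, 1]; default 0.01.
#' @return A list with elements `psms` and `proteins` (filtered tibbles).
#' @export
filter_by_fdr <- function(psms, proteins = NULL, threshold = 0.01) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  if (nrow(psms) > 0L && !all(is.na(psms$q_value))) {
    dropped_na <- sum(is.na(psms$q_value))
    if (dropped_na > 0L) {
      warning(dropped_na, " PSM(s) without q_value excluded by the FDR filter")
    }
    kept_psms <- psms[!is.na(psms$q_value) & psms$q_value <= threshold, ]
  } else {
    kept_psms <- psms[fdr_keep_by_probability(psms$probability, threshold), ]
  }

  kept_proteins <- proteins
  if (!is.null(proteins) && nrow(proteins) > 0L) {
    kept_proteins <- proteins[
      fdr_keep_by_probability(proteins$probability, threshold), ]
    if (nrow(kept_psms) > 0L) {
      acc <- kept_proteins$accession
      has_protein <- vapply(kept_psms$proteins,
                            function(p) any(p %in% acc), TRUE)
      kept_psms <- kept_psms[has_protein, ]
    }
  }
  if (nrow(kept_psms) == 0L) {
    warning("No PSM passes the FDR threshold of ", threshold)
  }
  list(psms = kept_psms, proteins = kept_proteins)
}

# Longest prefix (by descending probability) with mean(1 - p) <= threshold.
fdr_keep_by_probability <- function(p, threshold) {
  n <- length(p)
  if (n == 0L) return(logical(0))
  ord <- order(p, decreasing = TRUE)
  running_fdr <- cumsum(1 - p[ord]) / seq_len(n)
  # tolerance absorbs floating-point residue of 1 - p (e.g. 1 - 0.99 > 0.01)
  ok <- running_fdr <= threshold + 1e-12
  k <- if (any(ok)) max(which(ok)) else 0L
  keep <- logical(n)
  if (k > 0L) keep[ord[seq_len(k)]] <- TRUE
  keep
}

#' Extract reporter-ion intensities from an MS2 peak list
#'
#' For each channel, takes the intensity of the most intense peak within
#' `tol` Th of the channel's reporter m/z; channels with no peak in the window
#' get 0. The most-intense rule (rather than nearest-m/z) is robust to small
#' calibration errors.
#'
#' @param peaks Tibble with columns `mz`, `intensity` (one MS2 scan's
#'   centroided peaks).
#' @param channels Channel tibble from [plex_channels()].
#' @param tol Half-width of the extraction window (Th), default 0.002.
#' @return Tibble with columns `label`, `intensity`, in channel order.
#' @export
extract_reporter_ions <- function(peaks, channels, tol = 0.002) {
  check_reporter_windows(channels, tol)
  ints <- vapply(channels$reporter_mz, function(mz) {
    hit <- peaks$intensity[peaks$mz >= mz - tol & peaks$mz <= mz + tol]
    if (length(hit) == 0L) 0 else max(hit)
  }, 0)
  tibble::tibble(label = channels$label, intensity = ints)
}

check_reporter_windows <- function(channels, tol) {
  stopifnot(is.numeric(tol), length(tol) == 1L, tol > 0)
  mz <- sort(channels$reporter_mz)
  if (length(mz) >= 2L && min(diff(mz)) < 2 * tol) {
    stop("Reporter extraction windows overlap: tolerance ", tol,
         " Th is too large for the plex channel spacing (min spacing ",
         signif(min(diff(mz)), 4), " Th)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Extract reporter intensities for all PSMs of a run
#'
#' Joins PSMs to their MS2 scans and extracts one reporter intensity per
#' channel per PSM. PSMs whose scan is missing from the spectra set are
#' dropped with a warning.
#'
#' @param psms PSM tibble.
#' @param spectra Spectra tibble from [read_spectra()].
#' @param channels Channel tibble from [plex_channels()].
#' @param tol Extraction window half-width (Th).
#' @return A wide tibble: `psm_id` plus one intensity column per channel label.
#' @export
reporter_intensities <- function(psms, spectra, channels, tol = 0.002) {
  check_reporter_windows(channels, tol)
  idx <- match(psms$scan_id, spectra$scan_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " PSM(s) reference scans absent from the ",
            "spectra file; dropped")
    psms <- psms[!is.na(idx), ]
    idx <- idx[!is.na(idx)]
  }
  mat <- matrix(0, nrow = nrow(psms), ncol = nrow(channels),
                dimnames = list(NULL, channels$label))
  for (i in seq_len(nrow(psms))) {
    p <- spectra$peaks[[idx[i]]]
    mat[i, ] <- vapply(channels$reporter_mz, function(mz) {
      hit <- p$intensity[p$mz >= mz - tol & p$mz <= mz + tol]
      if (length(hit) == 0L) 0 else max(hit)
    }, 0)
  }
  dplyr::bind_cols(tibble::tibble(psm_id = psms$psm_id),
                   tibble::as_tibble(mat))
}

#' Correct reporter intensities for isotope impurities
#'
#' Solves the linear mixing model `M x = observed` for the true channel
#' signals `x`, where `M` is the impurity matrix (entry `(i, j)` = fraction of
#' channel `j`'s signal observed in channel `i`). Negative solution components
#' (possible when observed signal is near zero in a channel that receives
#' leakage) are clamped to zero in a single pass.
#'
#' @param intensities Wide tibble with one column per channel label (extra
#'   columns such as `psm_id` are passed through untouched), as produced by
#'   [reporter_intensities()].
#' @param M An `impurity_matrix` (see [load_correction_matrix()]).
#' @return The input tibble with channel columns replaced by corrected values.
#' @export
correct_impurities <- function(intensities, M) {
  stopifnot(inherits(M, "impurity_matrix"))
  miss <- setdiff(M$channels, names(intensities))
  if (length(miss) > 0L) {
    stop("Intensity table is missing channel column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  raw <- t(as.matrix(intensities[, M$channels]))
  kap <- kappa(M$matrix, exact = FALSE)
  x <- tryCatch(
    solve(M$matrix, raw),
    error = function(e) {
      stop("Impurity matrix is singular or near-singular (condition number ",
           format(kap, digits = 3), "): ", conditionMessage(e), call. = FALSE)
    }
  )
  x[x < 0] <- 0
  out <- intensities
  out[, M$channels] <- tibble::as_tibble(t(x))
  out
}
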