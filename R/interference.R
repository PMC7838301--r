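#' Signal-to-interference (S2I) of a precursor in one MS1 scan
#'
#' S2I is the fraction of the ion signal inside the precursor isolation window
#' that belongs to the targeted precursor and its isotope cluster: the summed
#' intensity of peaks matching `target_mz + k * 1.00335 / charge`
#' (`k = 0..k_max`, within `match_ppm`) and lying inside the window, divided
#' by the summed intensity of *all* peaks inside the window. Values are
#' clipped to [0, 1]; an empty window returns 1 with a warning (no evidence of
#' interference, so downstream noise deduction becomes a no-op).
#'
#' @param ms1_peaks Tibble with `mz`, `intensity` columns (one MS1 scan).
#' @param target_mz Precursor m/z (Th).
#' @param charge Precursor charge (>= 1); `NA` is treated as 1.
#' @param center,width Isolation window centre and total width (Th).
#' @param k_max Isotope-cluster extent (number of +1 neighbours considered),
#'   default 3.
#' @param match_ppm Peak-matching tolerance in ppm, default 10.
#' @return S2I as a single number in \[0, 1\].
#' @export
compute_s2i_single <- function(ms1_peaks, target_mz, charge, center, width,
                               k_max = 3L, match_ppm = 10) {
  stopifnot(k_max >= 0L)
  if (!is.numeric(width) || length(width) != 1L || is.na(width) || width <= 0) {
    stop("Isolation width must be a positive number", call. = FALSE)
  }
  if (is.na(charge) || charge < 1L) charge <- 1L
  lo <- center - width / 2
  hi <- center + width / 2
  inside <- ms1_peaks$mz >= lo & ms1_peaks$mz <= hi
  denom <- sum(ms1_peaks$intensity[inside])
  if (denom <= 0) {
    warning("Empty isolation window at m/z ", signif(center, 6),
            "; S2I set to 1")
    return(1)
  }
  iso_mz <- target_mz + (0:k_max) * 1.00335 / charge
  tol <- iso_mz * match_ppm * 1e-6
  is_signal <- inside & vapply(ms1_peaks$mz, function(mz) {
    any(abs(mz - iso_mz) <= tol)
  }, TRUE)
  num <- sum(ms1_peaks$intensity[is_signal])
  min(max(num / denom, 0), 1)
}

#' Interpolate S2I between flanking MS1 scans
#'
#' Linear interpolation in retention time between the S2I measured in the MS1
#' scans that bracket an MS2 scan. When only the preceding scan exists its
#' value is returned unchanged.
#'
#' @param s2i_before,rt_before S2I and retention time (s) of the preceding MS1.
#' @param s2i_after,rt_after S2I and retention time of the following MS1, or
#'   `NA` when absent.
#' @param rt_ms2 Retention time of the MS2 scan.
#' @return Interpolated S2I in \[0, 1\].
#' @export
interpolate_s2i <- function(s2i_before, rt_before, s2i_after, rt_after,
                            rt_ms2) {
  if (is.na(s2i_before)) {
    if (is.na(s2i_after)) {
      warning("No flanking MS1 scan; S2I set to 1 (noise deduction no-op)")
      return(1)
    }
    return(s2i_after)
  }
  if (is.na(s2i_after) || is.na(rt_after)) return(s2i_before)
  if (rt_after == rt_before) return((s2i_before + s2i_after) / 2)
  w <- (rt_ms2 - rt_before) / (rt_after - rt_before)
  w <- min(max(w, 0), 1)
  s2i_before + w * (s2i_after - s2i_before)
}

#' S2I for every PSM of a run
#'
#' For each PSM's MS2 scan, finds the flanking MS1 scans (the recorded parent
#' scan is used as the preceding MS1 when present, otherwise the nearest MS1
#' earlier in scan order; the following MS1 is the nearest one later in scan
#' order), computes S2I in each with [compute_s2i_single()], and interpolates
#' by retention time. PSMs whose MS2 lacks a precursor descriptor, or with no
#' flanking MS1 at all, get S2I = 1 (ratio-compression correction becomes a
#' no-op for them).
#'
#' @param psms PSM tibble.
#' @param spectra Spectra tibble.
#' @param k_max Isotope-cluster extent.
#' @param match_ppm Peak-matching tolerance (ppm).
#' @param interpolate Interpolate between flanking scans (default) or use the
#'   preceding MS1 only.
#' @return Tibble `psm_id`, `s2i_preceding`, `s2i_following`, `s2i`.
#' @export
compute_s2i <- function(psms, spectra, k_max = 3L, match_ppm = 10,
                        interpolate = TRUE) {
  ord <- order(spectra$retention_time)
  spectra <- spectra[ord, ]
  ms1_pos <- which(spectra$ms_level == 1L)
  idx <- match(psms$scan_id, spectra$scan_id)

  one <- function(i) {
    j <- idx[i]
    if (is.na(j) || is.na(spectra$target_mz[j]) ||
        is.na(spectra$isolation_center[j])) {
      return(c(NA_real_, NA_real_, 1))
    }
    target <- spectra$target_mz[j]
    charge <- spectra$charge[j]
    center <- spectra$isolation_center[j]
    width <- spectra$isolation_width[j]
    prev_pos <- NA_integer_
    parent <- spectra$parent_ms1_scan[j]
    if (!is.na(parent)) {
      pp <- match(parent, spectra$scan_id)
      if (!is.na(pp) && spectra$ms_level[pp] == 1L) prev_pos <- pp
    }
    if (is.na(prev_pos)) {
      before <- ms1_pos[ms1_pos < j]
      if (length(before) > 0L) prev_pos <- max(before)
    }
    after <- ms1_pos[ms1_pos > j]
    next_pos <- if (length(after) > 0L) min(after) else NA_integer_

    s2i_b <- if (!is.na(prev_pos)) {
      compute_s2i_single(spectra$peaks[[prev_pos]], target, charge, center,
                         width, k_max, match_ppm)
    } else NA_real_
    s2i_a <- if (!is.na(next_pos)) {
      compute_s2i_single(spectra$peaks[[next_pos]], target, charge, center,
                         width, k_max, match_ppm)
    } else NA_real_
    s2i <- if (interpolate) {
      interpolate_s2i(s2i_b, if (!is.na(prev_pos)) spectra$retention_time[prev_pos] else NA_real_,
                      s2i_a, if (!is.na(next_pos)) spectra$retention_time[next_pos] else NA_real_,
                      spectra$retention_time[j])
    } else if (!is.na(s2i_b)) s2i_b else if (!is.na(s2i_a)) s2i_a else {
      warning("No flanking MS1 scan; S2I set to 1 (noise deduction no-op)")
      1
    }
    c(s2i_b, s2i_a, s2i)
  }
  res <- vapply(seq_len(nrow(psms)), one, c(0, 0, 0))
  tibble::tibble(
    psm_id = psms$psm_id,
    s2i_preceding = res[1, ],
    s2i_following = res[2, ],
    s2i = res[3, ]
  )
}

#' Ratio-compression correction: deduct co-isolation noise from reporter ions
#'
#' Co-isolated peptides contribute near 1:1 reporter signal that compresses
#' measured ratios toward 1. The total noise in a PSM's reporter ions is
#' estimated as `(1 - S2I)` times the summed reporter intensity; it is split
#' equally across channels (the only split consistent with 1:1-mixed
#' interference) and subtracted, clamping at zero.
#'
#' @param intensities Wide tibble with one column per channel label (extra
#'   columns passed through), e.g. the output of [correct_impurities()].
#' @param s2i Numeric vector of per-row S2I values in \[0, 1\] (recycled if
#'   length 1).
#' @param channels Character vector of channel column names; defaults to every
#'   numeric column except `psm_id`-like identifiers.
#' @return The input tibble with channel columns noise-deducted.
#' @export
apply_rcc <- function(intensities, s2i, channels = NULL) {
  if (is.null(channels)) {
    channels <- names(intensities)[vapply(intensities, is.numeric, TRUE)]
    channels <- setdiff(channels, c("s2i", "retention_time"))
  }
  mat <- as.matrix(intensities[, channels])
  if (length(s2i) == 1L) s2i <- rep(s2i, nrow(mat))
  stopifnot(length(s2i) == nrow(mat))
  if (any(s2i < 0 | s2i > 1, na.rm = TRUE)) {
    stop("S2I values must lie in [0, 1]", call. = FALSE)
  }
  s2i[is.na(s2i)] <- 1
  noise_per_channel <- (1 - s2i) * rowSums(mat) / ncol(mat)
  out_mat <- pmax(mat - noise_per_channel, 0)
  out <- intensities
  out[, channels] <- tibble::as_tibble(out_mat)
  out
}
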