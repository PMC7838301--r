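#' Read centroided MS spectra from mzML or mzXML
#'
#' Reads all scans from an open-format spectra file into a tibble, one row per
#' scan, with the centroided peak list as a list-column. Retention times are
#' normalized to seconds. MS2 rows carry a precursor descriptor (target m/z,
#' charge, isolation window, and the parent MS1 scan when the file records it).
#' When the file lacks explicit isolation-window metadata (always the case for
#' mzXML), the isolation window is centred on the precursor m/z with total
#' width `default_isolation_width`.
#'
#' @param path Path to an mzML or mzXML file.
#' @param format `"auto"` (from the file extension), `"mzml"` or `"mzxml"`.
#'   Only used for validation; parsing is dispatched by file content.
#' @param default_isolation_width Total isolation-window width (Th) assumed
#'   when the file does not state one. Default 2.0 Th.
#' @return A tibble with columns `scan_id`, `ms_level`, `retention_time`
#'   (seconds), `peaks` (list-column of tibbles with `mz`, `intensity`),
#'   `target_mz`, `charge`, `isolation_center`, `isolation_width`,
#'   `parent_ms1_scan`. Precursor columns are `NA` for MS1 scans and for MS2
#'   scans whose precursor is missing from the file (such scans are excluded
#'   from interference estimation but still quantified).
#' @export
read_spectra <- function(path, format = c("auto", "mzml", "mzxml"),
                         default_isolation_width = 2.0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("Spectra file not found: ", path, call. = FALSE)
  handle <- tryCatch(
    mzR::openMSfile(path),
    error = function(e) stop("Failed to parse spectra file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) {
    warning("Spectra file '", path, "' contains no scans")
    return(empty_spectra_tbl())
  }
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  hdr <- hdr[order(hdr$seqNum), , drop = FALSE]
  peaks <- lapply(seq_len(nrow(hdr)), function(i) {
    m <- pk[[hdr$seqNum[i]]]
    tb <- tibble::tibble(mz = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]))
    if (is.unsorted(tb$mz)) tb <- tb[order(tb$mz), ]
    tb
  })

  rt <- as.numeric(hdr$retentionTime) # mzR reports seconds for both formats
  ms_level <- as.integer(hdr$msLevel)
  acq <- as.integer(hdr$acquisitionNum)
  target_mz <- ifelse(ms_level >= 2L, as.numeric(hdr$precursorMZ), NA_real_)
  target_mz[!is.na(target_mz) & target_mz <= 0] <- NA_real_
  charge <- ifelse(ms_level >= 2L, as.integer(hdr$precursorCharge), NA_integer_)
  charge[!is.na(charge) & charge < 1L] <- NA_integer_

  iso_target <- suppressWarnings(as.numeric(hdr$isolationWindowTargetMZ))
  iso_lo <- suppressWarnings(as.numeric(hdr$isolationWindowLowerOffset))
  iso_hi <- suppressWarnings(as.numeric(hdr$isolationWindowUpperOffset))
  center <- ifelse(!is.na(iso_target) & iso_target > 0, iso_target, target_mz)
  width <- ifelse(!is.na(iso_lo) & !is.na(iso_hi) & (iso_lo + iso_hi) > 0,
                  iso_lo + iso_hi, default_isolation_width)
  center[ms_level < 2L] <- NA_real_
  width[ms_level < 2L] <- NA_real_

  parent <- rep(NA_character_, nrow(hdr))
  psn <- suppressWarnings(as.integer(hdr$precursorScanNum))
  has_parent <- ms_level >= 2L & !is.na(psn) & psn > 0L
  parent[has_parent] <- as.character(psn[has_parent])

  n_orphan <- sum(ms_level >= 2L & is.na(target_mz))
  if (n_orphan > 0L) {
    warning(n_orphan, " MS2 scan(s) lack a precursor descriptor; ",
            "they are excluded from interference estimation")
  }

  tibble::tibble(
    scan_id = as.character(acq),
    ms_level = ms_level,
    retention_time = rt,
    peaks = peaks,
    target_mz = target_mz,
    charge = charge,
    isolation_center = ifelse(is.na(target_mz) & ms_level >= 2L, NA_real_, center),
    isolation_width = ifelse(is.na(target_mz) & ms_level >= 2L, NA_real_, width),
    parent_ms1_scan = parent
  )
}

empty_spectra_tbl <- function() {
  tibble::tibble(
    scan_id = character(), ms_level = integer(), retention_time = numeric(),
    peaks = list(), target_mz = numeric(), charge = integer(),
    isolation_center = numeric(), isolation_width = numeric(),
    parent_ms1_scan = character()
  )
}

#' Write a spectra tibble to mzML
#'
#' Serializes a spectra tibble (the in-memory model used throughout the
#' package, see [read_spectra()]) to an mzML file via `mzR`. Used by the
#' synthetic-data generator and by tests to build fixtures programmatically.
#'
#' @param spectra Spectra tibble as returned by [read_spectra()].
#' @param path Output file path (should end in `.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  validate_spectra(spectra)
  n <- nrow(spectra)
  if (n == 0L) stop("Cannot write an empty spectra set", call. = FALSE)
  pk <- lapply(spectra$peaks, function(p) {
    cbind(mz = as.numeric(p$mz), intensity = as.numeric(p$intensity))
  })
  npk <- vapply(pk, nrow, 0L)
  tic <- vapply(pk, function(m) sum(m[, 2]), 0)
  bp <- vapply(seq_len(n), function(i) {
    if (npk[i] == 0L) return(c(0, 0))
    j <- which.max(pk[[i]][, 2]); c(pk[[i]][j, 1], pk[[i]][j, 2])
  }, c(0, 0))
  acq <- suppressWarnings(as.integer(spectra$scan_id))
  if (anyNA(acq)) acq <- seq_len(n)
  is2 <- spectra$ms_level >= 2L
  parent_acq <- suppressWarnings(as.integer(spectra$parent_ms1_scan))
  hdr <- data.frame(
    seqNum = seq_len(n),
    acquisitionNum = acq,
    msLevel = as.integer(spectra$ms_level),
    polarity = rep(1L, n),
    peaksCount = npk,
    totIonCurrent = tic,
    retentionTime = as.numeric(spectra$retention_time),
    basePeakMZ = bp[1, ],
    basePeakIntensity = bp[2, ],
    collisionEnergy = ifelse(is2, 35, 0),
    ionisationEnergy = rep(0, n),
    lowMZ = vapply(pk, function(m) if (nrow(m)) min(m[, 1]) else 0, 0),
    highMZ = vapply(pk, function(m) if (nrow(m)) max(m[, 1]) else 0, 0),
    precursorScanNum = ifelse(is2 & !is.na(parent_acq), parent_acq, 0L),
    precursorMZ = ifelse(is2 & !is.na(spectra$target_mz), spectra$target_mz, 0),
    precursorCharge = ifelse(is2 & !is.na(spectra$charge), spectra$charge, 0L),
    precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n),
    filterString = rep(NA_character_, n),
    spectrumId = paste0("scan=", acq),
    centroided = rep(TRUE, n),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = ifelse(is2, spectra$isolation_center, NA_real_),
    isolationWindowLowerOffset = ifelse(is2, spectra$isolation_width / 2, NA_real_),
    isolationWindowUpperOffset = ifelse(is2, spectra$isolation_width / 2, NA_real_),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(object = pk, file = path, header = hdr)
  invisible(path)
}

validate_spectra <- function(spectra) {
  req <- c("scan_id", "ms_level", "retention_time", "peaks", "target_mz",
           "charge", "isolation_center", "isolation_width", "parent_ms1_scan")
  missing_cols <- setdiff(req, names(spectra))
  if (length(missing_cols) > 0L) {
    stop("Spectra tibble is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(spectra))) {
    p <- spectra$peaks[[i]]
    if (any(p$intensity < 0)) {
      stop("Negative peak intensity in scan ", spectra$scan_id[i], call. = FALSE)
    }
    if (is.unsorted(p$mz)) {
      stop("Peaks not sorted by m/z in scan ", spectra$scan_id[i], call. = FALSE)
    }
  }
  invisible(spectra)
}
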