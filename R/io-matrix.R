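#' Isotope-impurity correction matrices
#'
#' An impurity matrix describes how each label's reporter signal leaks into
#' neighbouring channels because of the isotopic composition of the tag. Entry
#' `(i, j)` is the fraction of channel `j`'s true signal observed in channel
#' `i`; the diagonal is the fraction retained. Columns may sum to less than 1:
#' leakage outside the plex is real signal loss and stays out of the matrix.
#'
#' `load_correction_matrix()` accepts either a preset plex name or a CSV file.
#' Manufacturer impurity values are lot-specific, so presets carry the channel
#' layout with an *identity* matrix (correction is a no-op) and a prominent
#' warning; real runs should always load the certificate-of-analysis CSV.
#' The CSV format is one row per channel, header
#' `channel, minus2, minus1, plus1, plus2`, values in percent: the percentage
#' of that channel's signal appearing two channels below, one below, one
#' above, and two above (by channel order). Leaks that fall outside the plex
#' are dropped from the matrix but still reduce the source channel's diagonal.
#'
#' @param plex_or_path A preset plex name (see [plex_presets()]) or a path to
#'   an impurity CSV.
#' @param plex_name Optional plex label stored on the result when loading from
#'   CSV.
#' @return An object of class `impurity_matrix`: a list with `plex_name`,
#'   `channels` (ordered labels) and `matrix` (square numeric matrix with
#'   dimnames).
#' @examples
#' m <- load_correction_matrix(system.file("extdata",
#'   "example_impurity_tmt6_synthetic.csv", package = "isoquantr"))
#' m$matrix
#' @export
load_correction_matrix <- function(plex_or_path, plex_name = NULL) {
  stopifnot(is.character(plex_or_path), length(plex_or_path) == 1L)
  if (file.exists(plex_or_path) &&
      !normalize_plex_name(plex_or_path) %in% names(.plex_layouts)) {
    return(read_impurity_csv(plex_or_path, plex_name = plex_name))
  }
  key <- normalize_plex_name(plex_or_path)
  if (!key %in% names(.plex_layouts)) {
    stop("Unknown plex or missing file '", plex_or_path,
         "'. Available presets: ", paste(names(.plex_layouts), collapse = ", "),
         call. = FALSE)
  }
  channels <- names(.plex_layouts[[key]])
  warning("Preset '", key, "' ships no manufacturer impurity values ",
          "(they are lot-specific): using an identity matrix, so impurity ",
          "correction is a NO-OP. Load your reagent certificate CSV instead.")
  new_impurity_matrix(diag(length(channels)), channels, key)
}

read_impurity_csv <- function(path, plex_name = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        trim_ws = TRUE)
  names(df) <- tolower(trimws(names(df)))
  req <- c("channel", "minus2", "minus1", "plus1", "plus2")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("Impurity CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  channels <- as.character(df$channel)
  if (anyDuplicated(channels)) {
    stop("Duplicate channel labels in impurity CSV", call. = FALSE)
  }
  pct <- as.matrix(df[, c("minus2", "minus1", "plus1", "plus2")])
  if (any(pct < 0)) stop("Negative impurity percentage in '", path, "'",
                         call. = FALSE)
  frac <- pct / 100
  n <- length(channels)
  offsets <- c(-2L, -1L, 1L, 2L)
  m <- diag(n)
  for (j in seq_len(n)) {
    m[j, j] <- 1 - sum(frac[j, ])
    for (k in seq_along(offsets)) {
      i <- j + offsets[k]
      if (i >= 1L && i <= n) m[i, j] <- frac[j, k]
    }
  }
  if (any(m[cbind(seq_len(n), seq_len(n))] < 0)) {
    stop("Impurity fractions of a channel exceed 100%", call. = FALSE)
  }
  new_impurity_matrix(m, channels,
                      plex_name %||% sub("\\.[^.]*$", "", basename(path)))
}

new_impurity_matrix <- function(m, channels, plex_name) {
  m <- as.matrix(m)
  dimnames(m) <- list(observed = channels, source = channels)
  out <- structure(
    list(plex_name = plex_name, channels = channels, matrix = m),
    class = "impurity_matrix"
  )
  validate_impurity_matrix(out)
}

validate_impurity_matrix <- function(x) {
  m <- x$matrix
  n <- length(x$channels)
  if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
    stop("Impurity matrix must be square with one row/column per channel",
         call. = FALSE)
  }
  if (any(m < 0)) stop("Impurity matrix entries must be non-negative",
                       call. = FALSE)
  if (any(colSums(m) > 1 + 1e-9)) {
    stop("Impurity matrix columns must sum to at most 1", call. = FALSE)
  }
  x
}

#' @export
print.impurity_matrix <- function(x, ...) {
  cat("<impurity_matrix> plex:", x$plex_name,
      "(", length(x$channels), "channels )\n")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Write an impurity percentage table as CSV
#'
#' Serializes a `channel, minus2, minus1, plus1, plus2` percentage table (the
#' same layout [load_correction_matrix()] reads). Used by the synthetic
#' generator to emit fixture matrices.
#'
#' @param impurity_table Tibble with columns `channel`, `minus2`, `minus1`,
#'   `plus1`, `plus2` (percent).
#' @param path Output CSV path.
#' @export
write_impurity_csv <- function(impurity_table, path) {
  req <- c("channel", "minus2", "minus1", "plus1", "plus2")
  miss <- setdiff(req, names(impurity_table))
  if (length(miss) > 0L) {
    stop("Impurity table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(impurity_table[, req], path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
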