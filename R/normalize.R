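#' Reporter-ion level normalization: equalize channel medians
#'
#' Adjusts the reporter intensities of each channel by a single multiplicative
#' factor so that all channel medians become identical, under the assumption
#' that total sample amounts are constant across channels. Zero intensities
#' are excluded from the median computation (a missing reporter carries no
#' information about channel loading). The common target is the median of the
#' per-channel medians; any common target yields identical downstream ratios,
#' so the choice is ratio-neutral.
#'
#' @param intensities Wide tibble with one column per channel label (extra
#'   columns passed through).
#' @param channels Character vector of channel column names; defaults to all
#'   numeric columns.
#' @return The input tibble with channel columns rescaled; afterwards every
#'   channel's (zero-excluded) median equals the target to within 1e-9.
#' @export
normalize_reporter_medians <- function(intensities, channels = NULL) {
  if (is.null(channels)) {
    channels <- names(intensities)[vapply(intensities, is.numeric, TRUE)]
    channels <- setdiff(channels, c("s2i", "retention_time"))
  }
  mat <- as.matrix(intensities[, channels])
  med <- apply(mat, 2, function(v) {
    v <- v[v > 0]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  })
  if (anyNA(med)) {
    stop("Cannot normalize: channel(s) with no positive intensities: ",
         paste(channels[is.na(med)], collapse = ", "), call. = FALSE)
  }
  target <- stats::median(med)
  out <- intensities
  out[, channels] <- tibble::as_tibble(sweep(mat, 2, target / med, `*`))
  out
}

#' Ratio-level normalization: rescale a ratio set to median 1
#'
#' Multiplies every ratio in a peptide- or protein-level ratio set by the
#' reciprocal of the set's median, under the assumption that most peptides
#' (proteins) are not differentially abundant. Afterwards the median of the
#' set is 1 to within 1e-12. Order and all pairwise ratios-of-ratios are
#' preserved.
#'
#' @param ratios A data frame with a ratio column, or a bare numeric vector.
#' @param value_col Name of the ratio column when `ratios` is a data frame.
#' @return The input with the ratio column divided by its median. An empty set
#'   is returned unchanged with a warning.
#' @export
normalize_ratio_set <- function(ratios, value_col = "value") {
  if (is.data.frame(ratios)) {
    v <- ratios[[value_col]]
    if (is.null(v)) stop("No column '", value_col, "' in ratio set",
                         call. = FALSE)
    scaled <- normalize_ratio_vector(v)
    ratios[[value_col]] <- scaled
    return(ratios)
  }
  normalize_ratio_vector(ratios)
}

normalize_ratio_vector <- function(v) {
  obs <- v[!is.na(v)]
  if (length(obs) == 0L) {
    warning("Empty ratio set; normalization is a no-op")
    return(v)
  }
  med <- stats::median(obs)
  if (med <= 0) stop("Median ratio must be positive to normalize",
                     call. = FALSE)
  v / med
}

#' The seven composite normalization strategies
#'
#' Normalization can act at up to three levels: reporter-ion intensities
#' (channel medians equalized), peptide ratios (median forced to 1), and
#' protein ratios (median forced to 1). The supported strategies are the
#' closed set of combinations used throughout the package; peptide+protein
#' without reporter-level normalization is intentionally not offered.
#'
#' @return Character vector of the seven strategy names.
#' @export
normalization_strategies <- function() {
  c("none", "reporter", "peptide", "protein",
    "reporter+peptide", "reporter+protein", "reporter+peptide+protein")
}

strategy_levels <- function(strategy) {
  strategy <- match.arg(strategy, normalization_strategies())
  if (identical(strategy, "none")) character(0)
  else strsplit(strategy, "+", fixed = TRUE)[[1]]
}
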