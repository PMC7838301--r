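#' Ratio-calculation kernels
#'
#' The elementary aggregators from which peptide- and protein-level ratios are
#' built. All kernels operate on the linear ratio scale (no log transform) and
#' return `NA_real_` when the ratio is undefined for the given inputs.
#'
#' * `regression_slope_ratio()`: least-squares slope through the origin of
#'   numerator-channel intensity against denominator-channel intensity across
#'   PSMs, `sum(x * y) / sum(x^2)` with `x` the denominator intensities. With
#'   a single point this reduces to the plain PSM ratio.
#' * `sum_intensity_ratio()`: ratio of summed intensities,
#'   `sum(num) / sum(den)`.
#' * `median_ratio()`: median of ratios (mean of the central pair for even
#'   counts).
#' * `weighted_mean_ratio()`: intensity-weighted mean of ratios,
#'   `sum(w * r) / sum(w)`; falls back to the unweighted mean (with a warning)
#'   when all weights are zero.
#' * `trimmed_mean_ratio()`: removes `floor(trim * n)` of the largest and the
#'   smallest ratios respectively, then takes the mean of the remainder (the
#'   remainder is never empty).
#' * `peptide_weight()`: the weight of a peptide ratio, the median of the
#'   weights of its contributing PSMs.
#'
#' @param num,den Numerator-/denominator-channel intensities across PSMs.
#' @param values Ratio values.
#' @param weights Non-negative weights.
#' @param trim Fraction trimmed from each end (default 0.2).
#' @return A single ratio (or weight), or `NA_real_` when undefined.
#' @name ratio-kernels
NULL

#' @rdname ratio-kernels
#' @export
regression_slope_ratio <- function(den, num) {
  keep <- !is.na(den) & !is.na(num) & den > 0
  if (!any(keep)) return(NA_real_)
  x <- den[keep]; y <- num[keep]
  slope <- sum(x * y) / sum(x^2)
  if (!is.finite(slope) || slope <= 0) return(NA_real_)
  slope
}

#' @rdname ratio-kernels
#' @export
sum_intensity_ratio <- function(num, den) {
  sn <- sum(num, na.rm = TRUE); sd <- sum(den, na.rm = TRUE)
  if (sd <= 0 || sn <= 0) return(NA_real_)
  sn / sd
}

#' @rdname ratio-kernels
#' @export
median_ratio <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(NA_real_)
  stats::median(values)
}

#' @rdname ratio-kernels
#' @export
weighted_mean_ratio <- function(values, weights) {
  keep <- !is.na(values) & !is.na(weights)
  values <- values[keep]; weights <- weights[keep]
  if (length(values) == 0L) return(NA_real_)
  if (any(weights < 0)) stop("Ratio weights must be non-negative", call. = FALSE)
  if (sum(weights) <= 0) {
    warning("All ratio weights are zero; falling back to the unweighted mean")
    return(mean(values))
  }
  sum(weights * values) / sum(weights)
}

#' @rdname ratio-kernels
#' @export
trimmed_mean_ratio <- function(values, trim = 0.2) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) return(NA_real_)
  k <- floor(trim * n)
  sorted <- sort(values)
  mean(sorted[(k + 1):(n - k)])
}

#' @rdname ratio-kernels
#' @export
peptide_weight <- function(weights) {
  weights <- weights[!is.na(weights)]
  if (length(weights) == 0L) return(NA_real_)
  stats::median(weights)
}
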