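#' Pair calculated protein ratios with their ideal values
#'
#' Joins a quantified protein table to a ground-truth table, producing the
#' substrate for all accuracy metrics: one row per (protein, pair) with the
#' calculated ratio `x`, the ideal ratio `y`, and the protein class.
#'
#' @param proteins Tibble with `accession`, `pair`, `value` (e.g.
#'   `quant_result$proteins`).
#' @param truth Tibble with `accession`, `pair`, `ideal` and optionally
#'   `class` (`"standard"` or `"background"`).
#' @return Tibble `accession`, `pair`, `x`, `y`, `class`.
#' @export
eval_input <- function(proteins, truth) {
  stopifnot(all(c("accession", "pair", "ideal") %in% names(truth)))
  if (!"class" %in% names(truth)) truth$class <- NA_character_
  joined <- dplyr::inner_join(proteins, truth,
                              by = c("accession", "pair"))
  if (any(joined$ideal <= 0)) {
    stop("Ideal ratios must be positive", call. = FALSE)
  }
  tibble::tibble(accession = joined$accession, pair = joined$pair,
                 x = joined$value, y = joined$ideal, class = joined$class)
}

filter_class <- function(input, class_filter) {
  if (is.null(class_filter)) return(input)
  input[!is.na(input$class) & input$class == class_filter, ]
}

#' Average relative error of calculated vs ideal ratios
#'
#' The mean of `|x - y| / y` over all (protein, pair) entries. Restricting to
#' the standard-protein class gives ARE_Std, to the background class ARE_Bg.
#' Because the error is relative to the ideal value, ratios at different
#' scales are weighted comparably.
#'
#' @param input Tibble from [eval_input()] (columns `x`, `y`, optional
#'   `class`).
#' @param class_filter Optional class name to restrict to.
#' @return A single non-negative number, or `NA_real_` when no entry remains
#'   after filtering.
#' @export
are <- function(input, class_filter = NULL) {
  input <- filter_class(input, class_filter)
  if (nrow(input) == 0L) {
    warning("No entries to evaluate",
            if (!is.null(class_filter)) paste0(" for class '", class_filter, "'"))
    return(NA_real_)
  }
  mean(abs(input$x - input$y) / input$y)
}

#' Root mean square error of calculated vs ideal ratios
#'
#' `sqrt(sum((x - y)^2) / m)` over the `m` entries; penalizes far-off ratios
#' much more heavily than [are()].
#'
#' @inheritParams are
#' @export
rmse <- function(input, class_filter = NULL) {
  input <- filter_class(input, class_filter)
  if (nrow(input) == 0L) {
    warning("No entries to evaluate")
    return(NA_real_)
  }
  sqrt(mean((input$x - input$y)^2))
}

#' Coverage of protein ratios within a relative deviation
#'
#' The fraction of entries whose relative deviation `|x - y| / y` is at most
#' `d`. This is the y-axis of the coverage-vs-deviation curve.
#'
#' @inheritParams are
#' @param d Deviation bound in \[0, 1\].
#' @export
coverage_at_deviation <- function(input, d, class_filter = NULL) {
  stopifnot(d >= 0, d <= 1)
  input <- filter_class(input, class_filter)
  if (nrow(input) == 0L) {
    warning("No entries to evaluate")
    return(NA_real_)
  }
  mean(abs(input$x - input$y) / input$y <= d)
}

#' Area under the coverage-vs-deviation curve (AUCCD)
#'
#' Trapezoidal integral of [coverage_at_deviation()] over deviations 0 to 100%
#' on a uniform grid, normalized by the range so that perfect quantitation
#' scores exactly 1. Larger values mean more protein ratios lie close to their
#' ideal values.
#'
#' @inheritParams are
#' @param step Grid spacing in (0, 0.1], default 0.01.
#' @return A value in \[0, 1\], or `NA_real_` for an empty input.
#' @export
auccd <- function(input, step = 0.01, class_filter = NULL) {
  stopifnot(step > 0, step <= 0.1)
  input <- filter_class(input, class_filter)
  if (nrow(input) == 0L) {
    warning("No entries to evaluate")
    return(NA_real_)
  }
  grid <- seq(0, 1, by = step)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  dev <- abs(input$x - input$y) / input$y
  cov <- vapply(grid, function(d) mean(dev <= d), 0)
  sum(diff(grid) * (utils::head(cov, -1) + utils::tail(cov, -1)) / 2) /
    (grid[length(grid)] - grid[1])
}

#' Mean and standard deviation of ratios at one ideal value
#'
#' Summarizes the calculated ratios of all entries whose ideal value equals
#' `ideal_value` (e.g. Mean1/SD1 for proteins with ideal ratio 1). The
#' standard deviation uses the sample (n - 1) denominator and is `NA` when
#' fewer than two entries match.
#'
#' @inheritParams are
#' @param ideal_value The ideal ratio selecting the entries.
#' @return A one-row tibble with `ideal`, `mean`, `sd`, `n`.
#' @export
ratio_summary <- function(input, ideal_value) {
  stopifnot(ideal_value > 0)
  x <- input$x[input$y == ideal_value]
  tibble::tibble(
    ideal = ideal_value,
    mean = if (length(x) >= 1L) mean(x) else NA_real_,
    sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
    n = length(x)
  )
}

#' All evaluation metrics for one protein table
#'
#' Convenience wrapper computing AUCCD, ARE (overall and per class), and RMSE
#' against a ground-truth table.
#'
#' @inheritParams eval_input
#' @return One-row tibble: `auccd`, `are`, `are_std`, `are_bg`, `rmse`,
#'   `n_ratios`.
#' @export
evaluate_ratios <- function(proteins, truth) {
  input <- eval_input(proteins, truth)
  has_class <- !all(is.na(input$class))
  tibble::tibble(
    auccd = auccd(input),
    are = are(input),
    are_std = if (has_class && any(input$class == "standard", na.rm = TRUE))
      are(input, "standard") else NA_real_,
    are_bg = if (has_class && any(input$class == "background", na.rm = TRUE))
      are(input, "background") else NA_real_,
    rmse = rmse(input),
    n_ratios = nrow(input)
  )
}

#' Select differentially abundant proteins
#'
#' A protein is called differential when at least one of its channel-pair
#' ratios exceeds the threshold (default 1.5). The literal "above threshold"
#' rule considers up-regulation only; set `symmetric = TRUE` to also select
#' proteins with a ratio below `1 / threshold`.
#'
#' @param proteins Tibble with `accession` and `value` columns (one row per
#'   protein per pair).
#' @param threshold Positive fold-change threshold, default 1.5.
#' @param symmetric Also select down-regulated proteins (default `FALSE`).
#' @return Character vector of selected accessions.
#' @export
select_differential <- function(proteins, threshold = 1.5,
                                symmetric = FALSE) {
  stopifnot(threshold > 0)
  by_acc <- dplyr::summarise(
    dplyr::group_by(proteins, .data$accession),
    hit = any(.data$value > threshold, na.rm = TRUE) ||
      (symmetric && any(.data$value < 1 / threshold, na.rm = TRUE)),
    .groups = "drop"
  )
  sort(by_acc$accession[by_acc$hit])
}

#' Jaccard similarity of two protein lists
#'
#' Size of the intersection divided by the size of the union. Used to compare
#' differential-protein lists produced by different algorithmic combinations.
#'
#' @param list_a,list_b Character vectors (treated as sets).
#' @return A fraction in \[0, 1\]; `NA_real_` with a warning when both sets
#'   are empty.
#' @export
jaccard <- function(list_a, list_b) {
  a <- unique(list_a); b <- unique(list_b)
  u <- union(a, b)
  if (length(u) == 0L) {
    warning("Jaccard similarity of two empty sets is undefined")
    return(NA_real_)
  }
  length(intersect(a, b)) / length(u)
}
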