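#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a quantitation result
#'
#' Returns the protein-level ratio table: one row per (protein, channel pair).
#'
#' @param x A `quant_result`.
#' @param level `"protein"` (default), `"peptide"` or `"psm"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.quant_result <- function(x, level = c("protein", "peptide", "psm"), ...) {
  level <- match.arg(level)
  switch(level,
         protein = x$proteins,
         peptide = x$peptides,
         psm = x$psm_ratios)
}

#' One-row summary of a quantitation result
#'
#' @param x A `quant_result`.
#' @param ... Unused.
#' @return A one-row tibble: the combination fields plus PSM/protein counts.
#' @export
glance.quant_result <- function(x, ...) {
  dplyr::bind_cols(
    x$combination,
    tibble::tibble(
      psms_read = x$counts$psms_read,
      psms_kept = x$counts$psms_kept,
      proteins_quantified = x$counts$proteins_quantified,
      n_pairs = nrow(x$pairs)
    )
  )
}

#' Plot protein-ratio distributions of a quantitation result
#'
#' Boxplots of log2 protein ratios per channel pair.
#'
#' @param object A `quant_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quant_result <- function(object, ...) {
  ggplot2::ggplot(object$proteins,
                  ggplot2::aes(x = .data$pair, y = log2(.data$value))) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "channel pair", y = "log2 protein ratio",
                  title = paste(unlist(object$combination), collapse = " ~ ")) +
    ggplot2::theme_minimal()
}

#' Coverage-vs-deviation curve
#'
#' Plots the fraction of protein ratios within each relative deviation of
#' their ideal values; the area under this curve is the AUCCD metric.
#'
#' @param input Tibble from [eval_input()].
#' @param step Grid spacing for the deviation axis.
#' @return A ggplot object.
#' @export
plot_coverage_deviation <- function(input, step = 0.01) {
  grid <- seq(0, 1, by = step)
  dev <- abs(input$x - input$y) / input$y
  df <- tibble::tibble(
    deviation = grid,
    coverage = vapply(grid, function(d) mean(dev <= d), 0)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$deviation, y = .data$coverage)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "relative deviation from ideal ratio", y = "coverage") +
    ggplot2::theme_minimal()
}

#' Plot a ratio-compression curve
#'
#' Shows the median measured ratio, with and without ratio-compression
#' correction, as a function of the interference fraction, against the true
#' ratio.
#'
#' @param curve Tibble from [compression_curve()].
#' @return A ggplot object.
#' @export
plot_compression_curve <- function(curve) {
  long <- tidyr::pivot_longer(curve, c("uncorrected", "rcc"),
                              names_to = "method", values_to = "ratio")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$interference, y = .data$ratio,
                                     colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$ideal), data = curve,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "interference fraction of reporter signal",
                  y = "median protein ratio") +
    ggplot2::theme_minimal()
}
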