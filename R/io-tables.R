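#' Write quantitation result tables
#'
#' Writes three tab-separated files into `out_dir`: `proteins.tsv` (accession,
#' support counts, one ratio column per channel pair, normalization flag),
#' `peptides.tsv`, and `psms.tsv` (per-stage reporter intensities per channel
#' and S2I). Row order is deterministic (accession, then peptide key, then PSM
#' id) and unquantifiable ratios are written as empty cells, so re-running on
#' identical input produces byte-identical files.
#'
#' @param result A `quant_result` from [quantify()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible character vector of the three file paths.
#' @export
write_quant_tables <- function(result, out_dir) {
  stopifnot(inherits(result, "quant_result"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  pair_col <- function(pair) paste0("ratio_", gsub("/", "_vs_", pair, fixed = TRUE))
  pair_levels <- result$pairs$pair

  prot <- result$proteins
  prot_wide <- tidyr::pivot_wider(
    dplyr::mutate(prot, pair = pair_col(.data$pair)),
    id_cols = "accession",
    names_from = "pair", values_from = "value"
  )
  missing_cols <- setdiff(pair_col(pair_levels), names(prot_wide))
  for (mc in missing_cols) prot_wide[[mc]] <- NA_real_
  support <- dplyr::summarise(
    dplyr::group_by(prot, .data$accession),
    n_peptides = max(.data$n_peptides), n_psms = max(.data$n_psms),
    .groups = "drop"
  )
  prot_out <- dplyr::left_join(support, prot_wide, by = "accession")
  prot_out <- prot_out[, c("accession", "n_peptides", "n_psms",
                           pair_col(pair_levels))]
  prot_out$normalization <- result$combination$normalization
  prot_out <- dplyr::arrange(prot_out, .data$accession)

  pep <- result$peptides
  pep_wide <- tidyr::pivot_wider(
    dplyr::mutate(pep, pair = pair_col(.data$pair)),
    id_cols = c("accession", "peptide_key"),
    names_from = "pair", values_from = "value"
  )
  for (mc in setdiff(pair_col(pair_levels), names(pep_wide))) {
    pep_wide[[mc]] <- NA_real_
  }
  pep_support <- dplyr::summarise(
    dplyr::group_by(pep, .data$accession, .data$peptide_key),
    n_psms = max(.data$n_psms), .groups = "drop"
  )
  pep_out <- dplyr::left_join(pep_support, pep_wide,
                              by = c("accession", "peptide_key"))
  pep_out <- dplyr::arrange(pep_out, .data$accession, .data$peptide_key)

  psm_out <- dplyr::arrange(result$psms, .data$psm_id)

  paths <- file.path(out_dir, c("proteins.tsv", "peptides.tsv", "psms.tsv"))
  readr::write_tsv(prot_out, paths[1], na = "", progress = FALSE)
  readr::write_tsv(pep_out, paths[2], na = "", progress = FALSE)
  readr::write_tsv(psm_out, paths[3], na = "", progress = FALSE)
  invisible(paths)
}
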