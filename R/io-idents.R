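#' Read validated PSMs from a pepXML file
#'
#' Parses TPP-style pepXML and returns one record per spectrum query, taken
#' from the top-ranked search hit. The posterior probability is taken from the
#' most downstream analysis present: iProphet (`interprophet_result`) when
#' available, otherwise PeptideProphet (`peptideprophet_result`). Hits carrying
#' no probability are excluded with a warning. The peptide key is the modified
#' peptide string when a modification is recorded, otherwise the bare sequence;
#' charge states of the same modified sequence are treated as one peptide
#' downstream.
#'
#' @param path Path to a pepXML file.
#' @param decoy_prefix Accession prefix marking decoy proteins (default
#'   `"DECOY_"`).
#' @return A tibble of PSM records: `psm_id`, `scan_id`, `peptide_key`,
#'   `charge`, `proteins` (list-column of accessions), `probability`,
#'   `q_value` (`NA` unless provided), `is_decoy` (all mapped proteins are
#'   decoys).
#' @export
read_pepxml <- function(path, decoy_prefix = "DECOY_") {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("Malformed pepXML '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  queries <- xml2::xml_find_all(doc, ".//spectrum_query")
  rows <- purrr::map(queries, function(q) {
    hit <- xml2::xml_find_first(q, "./search_result/search_hit[@hit_rank='1']")
    if (is.na(hit)) hit <- xml2::xml_find_first(q, "./search_result/search_hit")
    if (is.na(hit)) return(NULL)
    prob <- pepxml_probability(hit)
    spectrum <- xml2::xml_attr(q, "spectrum")
    scan <- xml2::xml_attr(q, "start_scan")
    if (is.na(scan)) scan <- spectrum
    if (is.na(prob)) {
      warning("Search hit for spectrum '", spectrum,
              "' carries no probability; excluded")
      return(NULL)
    }
    mod <- xml2::xml_find_first(hit, "./modification_info")
    pep <- xml2::xml_attr(hit, "peptide")
    if (!is.na(mod)) {
      mp <- xml2::xml_attr(mod, "modified_peptide")
      if (!is.na(mp) && nzchar(mp)) pep <- mp
    }
    prots <- c(xml2::xml_attr(hit, "protein"),
               xml2::xml_attr(xml2::xml_find_all(hit, "./alternative_protein"),
                              "protein"))
    prots <- unique(prots[!is.na(prots)])
    tibble::tibble(
      psm_id = spectrum,
      scan_id = as.character(scan),
      peptide_key = pep,
      charge = as.integer(xml2::xml_attr(q, "assumed_charge")),
      proteins = list(prots),
      probability = prob,
      q_value = NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty_psm_tbl())
  out$is_decoy <- vapply(out$proteins,
                         function(p) length(p) > 0L &&
                           all(startsWith(p, decoy_prefix)), TRUE)
  validate_psms(out)
}

pepxml_probability <- function(hit) {
  for (res in c("interprophet_result", "peptideprophet_result")) {
    node <- xml2::xml_find_first(hit, paste0(".//", res))
    if (!is.na(node)) {
      p <- as.numeric(xml2::xml_attr(node, "probability"))
      if (!is.na(p)) return(p)
    }
  }
  NA_real_
}

#' Read protein groups from a protXML file
#'
#' @param path Path to a protXML file.
#' @param decoy_prefix Accession prefix marking decoy proteins.
#' @return A tibble of protein groups: `accession`, `peptides` (list-column of
#'   member peptide keys), `probability`, `is_decoy`. Each `<protein>` entry
#'   becomes one row; filtering (e.g. at 1% FDR) is deferred to
#'   [filter_by_fdr()].
#' @export
read_protxml <- function(path, decoy_prefix = "DECOY_") {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("Malformed protXML '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  prots <- xml2::xml_find_all(doc, ".//protein_group/protein")
  rows <- purrr::map(prots, function(p) {
    peps <- xml2::xml_find_all(p, "./peptide")
    keys <- vapply(peps, function(pe) {
      mod <- xml2::xml_find_first(pe, "./modification_info")
      key <- xml2::xml_attr(pe, "peptide_sequence")
      if (!is.na(mod)) {
        mp <- xml2::xml_attr(mod, "modified_peptide")
        if (!is.na(mp) && nzchar(mp)) key <- mp
      }
      key
    }, "")
    tibble::tibble(
      accession = xml2::xml_attr(p, "protein_name"),
      peptides = list(unique(keys)),
      probability = as.numeric(xml2::xml_attr(p, "probability"))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty_protein_tbl())
  out$is_decoy <- startsWith(out$accession, decoy_prefix)
  validate_proteins(out)
}

#' Read or write PSMs as a generic tab-separated table
#'
#' The generic PSM table substitutes for tool-specific export dialects.
#' Mandatory columns: `psm_id`, `scan_id`, `peptide`, `charge`, `proteins`
#' (";"-separated accessions), `probability`; optional: `q_value` (used
#' directly by the FDR filter when present).
#'
#' @param path Path to a TSV file.
#' @param decoy_prefix Accession prefix marking decoy proteins.
#' @return `read_psm_table()`: a PSM tibble (see [read_pepxml()]).
#' @export
read_psm_table <- function(path, decoy_prefix = "DECOY_") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("psm_id", "scan_id", "peptide", "charge", "proteins", "probability")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("PSM table '", path, "' is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    psm_id = as.character(df$psm_id),
    scan_id = as.character(df$scan_id),
    peptide_key = as.character(df$peptide),
    charge = as.integer(df$charge),
    proteins = strsplit(as.character(df$proteins), ";", fixed = TRUE),
    probability = as.numeric(df$probability),
    q_value = if ("q_value" %in% names(df)) as.numeric(df$q_value) else NA_real_
  )
  out$is_decoy <- vapply(out$proteins,
                         function(p) length(p) > 0L &&
                           all(startsWith(p, decoy_prefix)), TRUE)
  validate_psms(out)
}

#' @rdname read_psm_table
#' @param psms PSM tibble to serialize.
#' @export
write_psm_table <- function(psms, path) {
  validate_psms(psms)
  df <- tibble::tibble(
    psm_id = psms$psm_id,
    scan_id = psms$scan_id,
    peptide = psms$peptide_key,
    charge = psms$charge,
    proteins = vapply(psms$proteins, paste, "", collapse = ";"),
    probability = psms$probability,
    q_value = psms$q_value
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read or write protein groups as a tab-separated table
#'
#' Columns: `accession`, `peptides` (";"-separated peptide keys),
#' `probability`, optional `is_decoy`.
#'
#' @param path Path to a TSV file.
#' @param decoy_prefix Accession prefix marking decoy proteins.
#' @export
read_protein_table <- function(path, decoy_prefix = "DECOY_") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("accession", "peptides", "probability")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("Protein table '", path, "' is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    accession = as.character(df$accession),
    peptides = strsplit(as.character(df$peptides), ";", fixed = TRUE),
    probability = as.numeric(df$probability),
    is_decoy = if ("is_decoy" %in% names(df)) as.logical(df$is_decoy)
               else startsWith(as.character(df$accession), decoy_prefix)
  )
  validate_proteins(out)
}

#' @rdname read_protein_table
#' @param proteins Protein-group tibble to serialize.
#' @export
write_protein_table <- function(proteins, path) {
  validate_proteins(proteins)
  df <- tibble::tibble(
    accession = proteins$accession,
    peptides = vapply(proteins$peptides, paste, "", collapse = ";"),
    probability = proteins$probability,
    is_decoy = proteins$is_decoy
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

empty_psm_tbl <- function() {
  tibble::tibble(psm_id = character(), scan_id = character(),
                 peptide_key = character(), charge = integer(),
                 proteins = list(), probability = numeric(),
                 q_value = numeric(), is_decoy = logical())
}

empty_protein_tbl <- function() {
  tibble::tibble(accession = character(), peptides = list(),
                 probability = numeric(), is_decoy = logical())
}

validate_psms <- function(psms) {
  if (nrow(psms) == 0L) return(psms)
  if (any(psms$probability < 0 | psms$probability > 1, na.rm = TRUE)) {
    stop("PSM probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(lengths(psms$proteins) == 0L)) {
    stop("Every PSM must map to at least one protein", call. = FALSE)
  }
  psms
}

validate_proteins <- function(proteins) {
  if (nrow(proteins) == 0L) return(proteins)
  if (any(lengths(proteins$peptides) == 0L)) {
    stop("Every protein group must have at least one member peptide",
         call. = FALSE)
  }
  proteins
}
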