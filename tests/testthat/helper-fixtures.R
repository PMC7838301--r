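# Shared toy builders used across test files.

toy_channels <- function(n = 2) {
  plex_channels("tmt6")[seq_len(n), ]
}

toy_psms <- function(ids, scan_ids = ids, proteins = as.list(rep("P1", length(ids))),
                     probability = rep(1, length(ids)),
                     q_value = rep(NA_real_, length(ids)),
                     peptide_key = paste0("PEP", seq_along(ids))) {
  tibble::tibble(
    psm_id = as.character(ids),
    scan_id = as.character(scan_ids),
    peptide_key = peptide_key,
    charge = 2L,
    proteins = proteins,
    probability = probability,
    q_value = q_value,
    is_decoy = FALSE
  )
}

toy_spectrum_row <- function(scan_id, mz, intensity, ms_level = 2L,
                             retention_time = 1) {
  tibble::tibble(
    scan_id = as.character(scan_id),
    ms_level = as.integer(ms_level),
    retention_time = retention_time,
    peaks = list(tibble::tibble(mz = mz, intensity = intensity)),
    target_mz = NA_real_,
    charge = NA_integer_,
    isolation_center = NA_real_,
    isolation_width = NA_real_,
    parent_ms1_scan = NA_character_
  )
}

# A 2-channel impurity matrix M = [[0.9, 0.1], [0.1, 0.9]].
toy_impurity_2ch <- function() {
  isoquantr:::new_impurity_matrix(
    matrix(c(0.9, 0.1, 0.1, 0.9), nrow = 2),
    channels = c("126", "127"), plex_name = "toy"
  )
}

# Minimal pepXML with two spectrum queries: one iProphet+PeptideProphet hit
# with a modification and an alternative protein, one decoy-only hit.
toy_pepxml <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<msms_pipeline_analysis xmlns="http://regis-web.systemsbiology.net/pepXML">',
    ' <msms_run_summary>',
    '  <spectrum_query spectrum="run.00001.00001.2" start_scan="1" assumed_charge="2">',
    '   <search_result>',
    '    <search_hit hit_rank="1" peptide="PEPTIDEK" protein="sp|P1|PROT1">',
    '     <alternative_protein protein="sp|P2|PROT2"/>',
    '     <modification_info modified_peptide="PEPTIDEK[229]"/>',
    '     <analysis_result analysis="peptideprophet">',
    '      <peptideprophet_result probability="0.50"/>',
    '     </analysis_result>',
    '     <analysis_result analysis="interprophet">',
    '      <interprophet_result probability="0.99"/>',
    '     </analysis_result>',
    '    </search_hit>',
    '   </search_result>',
    '  </spectrum_query>',
    '  <spectrum_query spectrum="run.00002.00002.3" start_scan="2" assumed_charge="3">',
    '   <search_result>',
    '    <search_hit hit_rank="1" peptide="DECOYSEQ" protein="DECOY_P9">',
    '     <analysis_result analysis="peptideprophet">',
    '      <peptideprophet_result probability="0.20"/>',
    '     </analysis_result>',
    '    </search_hit>',
    '   </search_result>',
    '  </spectrum_query>',
    ' </msms_run_summary>',
    '</msms_pipeline_analysis>'
  ), path)
  path
}

toy_protxml <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<protein_summary xmlns="http://regis-web.systemsbiology.net/protXML">',
    ' <protein_group group_number="1" probability="0.99">',
    '  <protein protein_name="sp|P1|PROT1" probability="0.99">',
    '   <peptide peptide_sequence="PEPTIDEK">',
    '    <modification_info modified_peptide="PEPTIDEK[229]"/>',
    '   </peptide>',
    '  </protein>',
    ' </protein_group>',
    ' <protein_group group_number="2" probability="0.10">',
    '  <protein protein_name="DECOY_P9" probability="0.10">',
    '   <peptide peptide_sequence="DECOYSEQ"/>',
    '  </protein>',
    ' </protein_group>',
    '</protein_summary>'
  ), path)
  path
}

# Noise-free two-protein TMT-6 dataset with known ratios, built directly from
# tibbles (no file I/O), for pipeline-exactness tests.
toy_dataset <- function(ratio = c(1, 1, 2, 1, 1, 4), n_psms = 3) {
  channels <- plex_channels("tmt6")
  spec_rows <- list(); psm_rows <- list()
  for (s in seq_len(n_psms)) {
    intensity <- 1000 * s * ratio
    spec_rows[[s]] <- toy_spectrum_row(s, channels$reporter_mz, intensity,
                                       retention_time = s)
    psm_rows[[s]] <- toy_psms(sprintf("PSM%03d", s), scan_ids = s,
                              peptide_key = sprintf("PEPTIDE%d", s))
  }
  quant_dataset(dplyr::bind_rows(spec_rows), dplyr::bind_rows(psm_rows),
                plex = "tmt6")
}
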