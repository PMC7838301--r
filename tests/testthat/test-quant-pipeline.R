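# Hand-built 2-channel noise-free dataset: protein A ratio 2, B ratio 0.5,
# C ratio 1, equal bases, so channel medians are equal and the peptide- and
# protein-ratio medians are exactly 1 (every normalization is neutral).
balanced_2ch_dataset <- function() {
  ch <- toy_channels(2)
  values <- list(A = c(1000, 2000), B = c(2000, 1000), C = c(1500, 1500))
  spec_rows <- list(); psm_rows <- list()
  k <- 0
  for (acc in names(values)) {
    for (s in 1:2) {
      k <- k + 1
      spec_rows[[k]] <- toy_spectrum_row(k, ch$reporter_mz, values[[acc]])
      psm_rows[[k]] <- toy_psms(sprintf("PSM%02d", k), scan_ids = k,
                                proteins = list(acc),
                                peptide_key = paste0("PEP_", acc))
    }
  }
  quant_dataset(dplyr::bind_rows(spec_rows), dplyr::bind_rows(psm_rows),
                channels = ch)
}

test_that("psm_ratios computes values and both weight schemes", {
  tbl <- tibble::tibble(psm_id = c("a", "b"),
                        `126` = c(100, 0), `127` = c(200, 50),
                        `128` = c(300, 60))
  pr <- psm_ratios(tbl, "127/126")
  expect_equal(pr$value, c(2, NA))
  expect_equal(pr$weight, c(300, 50))
  pr_all <- psm_ratios(tbl, "127/126", weight_scheme = "all")
  expect_equal(pr_all$weight, c(600, 110))
  expect_error(psm_ratios(tbl, "135/126"), "not found")
})

test_that("the combination lattice enumerates 336 / 48 / 12", {
  full <- enumerate_combinations()
  expect_equal(nrow(full), 336)
  expect_equal(nrow(enumerate_combinations("none")), 48)
  nci_style <- enumerate_combinations("none", peptide = "MedianPsmRatio")
  expect_equal(nrow(nci_style), 12)
  expect_equal(anyDuplicated(full$combination_id), 0)
  # deterministic lexicographic order by the canonical enumerations
  expect_equal(full$peptide_kernel[1], peptide_kernels()[1])
  expect_false(full$rcc[1])
  expect_true(full$rcc[2])
  expect_error(enumerate_combinations("bogus"))
  expect_error(enumerate_combinations(character(0)))
})

test_that("all 336 combinations are exact on a normalization-neutral dataset", {
  qd <- balanced_2ch_dataset()
  truth <- tibble::tibble(accession = c("A", "B", "C"), pair = "127/126",
                          ideal = c(2, 0.5, 1))
  sw <- sweep_quant(qd, "127/126", enumerate_combinations(), truth = truth)
  expect_equal(nrow(sw), 336)
  expect_lt(max(sw$are), 1e-9)
  expect_equal(sw$auccd, rep(1, 336))
})

test_that("equal-abundance data gives ratio 1 under any combination", {
  qd <- toy_dataset(ratio = rep(1, 6))
  some <- enumerate_combinations()[c(1, 50, 150, 250, 336), ]
  for (i in seq_len(nrow(some))) {
    res <- quantify(qd, c("128/126", "131/126"),
                    peptide_kernel = some$peptide_kernel[i],
                    protein_kernel = some$protein_kernel[i],
                    normalization = some$normalization[i],
                    rcc = some$rcc[i])
    expect_equal(res$proteins$value, rep(1, nrow(res$proteins)),
                 tolerance = 1e-9)
  }
})

test_that("noise-free generator data is recovered exactly without reporter normalization", {
  spec <- synth_spec(n_proteins = 20, peptides_per_protein = c(2, 2),
                     psms_per_peptide = c(2, 2), cv_noise = 0, seed = 8)
  ds <- generate_dataset(spec)
  qd <- as_quant_dataset(ds)
  pairs <- c("128/126", "130/126")
  truth <- ground_truth_ratios(ds$truth, pairs)
  combos <- enumerate_combinations(c("none", "peptide", "protein"))
  sw <- sweep_quant(qd, pairs, combos, truth = truth)
  expect_lt(max(sw$are), 1e-9)
})

test_that("PSM-level protein kernels are independent of the peptide kernel", {
  spec <- synth_spec(n_proteins = 8, peptides_per_protein = c(2, 3),
                     psms_per_peptide = c(1, 3), cv_noise = 0.2, seed = 13)
  qd <- as_quant_dataset(generate_dataset(spec))
  for (prot_kernel in c("MedianPsmRatio", "TrimmedMeanPsmRatio")) {
    a <- quantify(qd, "131/126", peptide_kernel = "LinearRegression",
                  protein_kernel = prot_kernel)
    b <- quantify(qd, "131/126", peptide_kernel = "WeightedPsmRatio",
                  protein_kernel = prot_kernel)
    expect_equal(a$proteins, b$proteins)
  }
})

test_that("unique-peptide mode excludes PSMs shared between protein groups", {
  ch <- toy_channels(2)
  spectra <- dplyr::bind_rows(
    toy_spectrum_row(1, ch$reporter_mz, c(100, 200)),
    toy_spectrum_row(2, ch$reporter_mz, c(100, 300))
  )
  psms <- toy_psms(c("u", "s"), scan_ids = 1:2,
                   proteins = list("P1", c("P1", "P2")))
  qd <- quant_dataset(spectra, psms, channels = ch)
  res <- quantify(qd, "127/126")
  expect_equal(res$proteins$accession, "P1")
  expect_equal(res$proteins$value, 2)
  res2 <- quantify(qd, "127/126", unique_peptides_only = FALSE,
                   protein_kernel = "MedianPsmRatio")
  expect_setequal(res2$proteins$accession, c("P1", "P2"))
  expect_equal(res2$proteins$value[res2$proteins$accession == "P2"], 3)
})

test_that("RCC brings interfered ratios closer to truth on a paired run", {
  spec <- synth_spec(n_proteins = 10, peptides_per_protein = c(2, 2),
                     psms_per_peptide = c(2, 2), cv_noise = 0,
                     interference_fraction = 0.4, seed = 9)
  ds <- generate_dataset(spec)
  qd <- as_quant_dataset(ds)
  truth <- ground_truth_ratios(ds$truth, "130/126")
  on <- quantify(qd, "130/126", rcc = TRUE)
  off <- quantify(qd, "130/126", rcc = FALSE)
  cmp <- dplyr::inner_join(
    dplyr::inner_join(on$proteins, off$proteins,
                      by = c("accession", "pair"), suffix = c("_on", "_off")),
    truth, by = c("accession", "pair"))
  varying <- cmp[cmp$ideal != 1, ]
  expect_gt(nrow(varying), 0)
  expect_true(all(abs(varying$value_on - varying$ideal) <
                    abs(varying$value_off - varying$ideal)))
  # noise-free RCC recovers the truth exactly
  expect_equal(cmp$value_on, cmp$ideal, tolerance = 1e-9)
})

test_that("require_complete_channels drops PSMs with any missing reporter", {
  ch <- toy_channels(2)
  spectra <- dplyr::bind_rows(
    toy_spectrum_row(1, ch$reporter_mz, c(100, 200)),
    toy_spectrum_row(2, ch$reporter_mz[1], 100)  # channel 127 missing
  )
  psms <- toy_psms(c("a", "b"), scan_ids = 1:2)
  qd <- quant_dataset(spectra, psms, channels = ch)
  expect_message(res <- quantify(qd, "127/126",
                                 require_complete_channels = TRUE),
                 "dropped")
  expect_equal(res$counts$psms_kept, 1)
  res2 <- quantify(qd, "127/126")
  expect_equal(res2$counts$psms_kept, 2)
})

test_that("quant_result accessors: tidy, glance, print, autoplot", {
  qd <- balanced_2ch_dataset()
  res <- quantify(qd, "127/126", normalization = "reporter", rcc = TRUE)
  expect_equal(nrow(tidy(res)), 3)
  expect_true(all(c("accession", "pair", "value") %in% names(tidy(res))))
  expect_gt(nrow(tidy(res, "peptide")), 0)
  expect_gt(nrow(tidy(res, "psm")), 0)
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_equal(g$proteins_quantified, 3)
  expect_equal(g$normalization, "reporter")
  expect_output(print(res), "quant_result")
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("sweep_quant returns one metrics row per combination, in order", {
  qd <- balanced_2ch_dataset()
  truth <- tibble::tibble(accession = c("A", "B", "C"), pair = "127/126",
                          ideal = c(2, 0.5, 1))
  combos <- enumerate_combinations("none", peptide = "MedianPsmRatio")
  sw <- sweep_quant(qd, "127/126", combos, truth = truth)
  expect_equal(sw$combination_id, combos$combination_id)
  expect_true(all(c("auccd", "are", "are_std", "are_bg", "rmse", "n_ratios")
                  %in% names(sw)))
})
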