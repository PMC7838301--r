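test_that("probability-based FDR keeps the longest prefix within threshold", {
  # sorted descending: running mean of (1 - p) = 0.01, 0.015, 0.17 -> keep 1
  psms <- toy_psms(1:3, probability = c(0.99, 0.98, 0.50))
  kept <- filter_by_fdr(psms, threshold = 0.01)$psms
  expect_equal(kept$psm_id, "1")
  # at threshold 0.02 the first two pass
  kept2 <- filter_by_fdr(psms, threshold = 0.02)$psms
  expect_setequal(kept2$psm_id, c("1", "2"))
  # nothing passes an impossible threshold
  expect_warning(none <- filter_by_fdr(psms, threshold = 0.001)$psms,
                 "No PSM")
  expect_equal(nrow(none), 0)
})

test_that("q_value takes precedence over probability when present", {
  psms <- toy_psms(1:3, probability = c(0.5, 0.5, 0.5),
                   q_value = c(0.001, 0.05, 0.009))
  kept <- filter_by_fdr(psms)$psms
  expect_setequal(kept$psm_id, c("1", "3"))
})

test_that("PSMs whose every protein fails the protein filter are dropped", {
  psms <- toy_psms(1:2, proteins = list("P1", "P2"))
  prots <- tibble::tibble(accession = c("P1", "P2"),
                          peptides = list("PEP1", "PEP2"),
                          probability = c(0.999, 0.30),
                          is_decoy = FALSE)
  res <- filter_by_fdr(psms, prots, threshold = 0.01)
  expect_equal(res$proteins$accession, "P1")
  expect_equal(res$psms$psm_id, "1")
})

test_that("reporter extraction picks the most intense in-window peak", {
  ch <- toy_channels(2)
  peaks <- tibble::tibble(
    mz = c(126.1277, 126.1290, 127.1248, 500),
    intensity = c(1000, 400, 500, 9e9)
  )
  out <- extract_reporter_ions(peaks, ch, tol = 0.002)
  expect_equal(out$intensity, c(1000, 500))
  # empty window -> 0
  out2 <- extract_reporter_ions(peaks[4, ], ch, tol = 0.002)
  expect_equal(out2$intensity, c(0, 0))
})

test_that("overlapping reporter windows are a fatal error", {
  expect_error(extract_reporter_ions(tibble::tibble(mz = 1, intensity = 1),
                                     plex_channels("tmt10"), tol = 0.01),
               "overlap")
  expect_silent(check_reporter_windows(plex_channels("tmt10"), 0.002))
})

test_that("reporter_intensities joins PSMs to scans and warns on orphans", {
  ch <- toy_channels(2)
  spectra <- toy_spectrum_row("10", c(126.1277, 127.1248), c(300, 100))
  psms <- toy_psms(c("a", "b"), scan_ids = c("10", "999"))
  expect_warning(wide <- reporter_intensities(psms, spectra, ch), "absent")
  expect_equal(nrow(wide), 1)
  expect_equal(wide$`126`, 300)
  expect_equal(wide$`127`, 100)
})

test_that("impurity correction solves the mixing model and clamps negatives", {
  M <- toy_impurity_2ch()
  tbl <- tibble::tibble(psm_id = c("a", "b"),
                        `126` = c(0.9, 0.05), `127` = c(0.1, 1.0))
  out <- correct_impurities(tbl, M)
  # M x = [0.9, 0.1] has exact solution x = [1, 0]
  expect_equal(out$`126`[1], 1, tolerance = 1e-12)
  expect_equal(out$`127`[1], 0, tolerance = 1e-12)
  # [0.05, 1.0] solves to a negative 126 component, clamped to 0;
  # the 127 component keeps its algebraic value 1.11875
  expect_equal(out$`126`[2], 0)
  expect_equal(out$`127`[2], 1.11875, tolerance = 1e-9)
})

test_that("impurity correction requires matching channel columns", {
  M <- toy_impurity_2ch()
  expect_error(correct_impurities(tibble::tibble(`126` = 1), M), "missing")
})
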