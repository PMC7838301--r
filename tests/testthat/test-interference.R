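test_that("S2I is signal over window total", {
  # precursor at 500, charge 2, isotope at +0.501675; interferer at 500.7
  peaks <- tibble::tibble(mz = c(500, 500.501675, 500.7),
                          intensity = c(600, 200, 200))
  s2i <- compute_s2i_single(peaks, 500, 2L, 500, 2)
  expect_equal(s2i, 800 / 1000)
  # all signal -> 1; all interference -> 0
  expect_equal(compute_s2i_single(peaks[1:2, ], 500, 2L, 500, 2), 1)
  expect_equal(compute_s2i_single(peaks[3, , drop = FALSE], 500, 2L, 500, 2), 0)
})

test_that("S2I honours the isolation window and ppm matching", {
  peaks <- tibble::tibble(mz = c(500, 502.5), intensity = c(100, 1e6))
  # 502.5 lies outside the +-1 window, so it affects nothing
  expect_equal(compute_s2i_single(peaks, 500, 1L, 500, 2), 1)
  # a peak 0.01 Th off the isotope position is not matched at 10 ppm
  near <- tibble::tibble(mz = c(500, 500.01), intensity = c(100, 100))
  expect_equal(compute_s2i_single(near, 500, 1L, 500, 2), 0.5)
})

test_that("an empty isolation window yields S2I 1 with a warning", {
  peaks <- tibble::tibble(mz = 900, intensity = 100)
  expect_warning(s2i <- compute_s2i_single(peaks, 500, 2L, 500, 2), "Empty")
  expect_equal(s2i, 1)
})

test_that("S2I interpolation is linear in retention time", {
  expect_equal(interpolate_s2i(0.8, 10, 0.6, 12, 10.5), 0.75)
  expect_equal(interpolate_s2i(0.8, 10, 0.6, 12, 12), 0.6)
  # missing following scan -> preceding value
  expect_equal(interpolate_s2i(0.8, 10, NA, NA, 10.5), 0.8)
  # missing preceding scan -> following value
  expect_equal(interpolate_s2i(NA, NA, 0.6, 12, 10.5), 0.6)
  expect_warning(one <- interpolate_s2i(NA, NA, NA, NA, 10), "No flanking")
  expect_equal(one, 1)
})

test_that("compute_s2i reproduces the generator's per-PSM interference", {
  f <- 0.3
  ds <- generate_dataset(synth_spec(n_proteins = 3,
                                    peptides_per_protein = c(1, 2),
                                    psms_per_peptide = c(1, 2),
                                    interference_fraction = f, seed = 5))
  s2i <- compute_s2i(ds$psms, ds$spectra)
  expect_equal(s2i$psm_id, ds$psm_truth$psm_id)
  expect_equal(s2i$s2i, ds$psm_truth$s2i_true, tolerance = 1e-12)
})

test_that("RCC subtracts equally split noise and clamps at zero", {
  tbl <- tibble::tibble(psm_id = "a", c1 = 100, c2 = 300, c3 = 200, c4 = 400)
  out <- apply_rcc(tbl, 0.8, channels = c("c1", "c2", "c3", "c4"))
  # noise = 0.2 * 1000 / 4 = 50 per channel
  expect_equal(unlist(out[, -1], use.names = FALSE), c(50, 250, 150, 350))

  low <- tibble::tibble(c1 = 10, c2 = 990)
  out2 <- apply_rcc(low, 0.5, channels = c("c1", "c2"))
  # noise per channel = 0.5 * 1000 / 2 = 250; c1 clamps at 0
  expect_equal(unlist(out2, use.names = FALSE), c(0, 740))
})

test_that("RCC conserves total signal when nothing clamps", {
  set.seed(99)
  m <- tibble::tibble(c1 = runif(20, 500, 1000), c2 = runif(20, 500, 1000),
                      c3 = runif(20, 500, 1000))
  s2i <- runif(20, 0.7, 1)
  out <- apply_rcc(m, s2i, channels = c("c1", "c2", "c3"))
  expect_equal(rowSums(as.matrix(out)), s2i * rowSums(as.matrix(m)),
               tolerance = 1e-12)
})

test_that("RCC rejects invalid S2I values and S2I 1 is a no-op", {
  tbl <- tibble::tibble(c1 = 1, c2 = 2)
  expect_error(apply_rcc(tbl, 1.5, channels = c("c1", "c2")), "\\[0, 1\\]")
  expect_equal(apply_rcc(tbl, 1, channels = c("c1", "c2")), tbl)
})
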