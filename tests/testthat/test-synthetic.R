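test_that("synth_spec validates its inputs", {
  expect_error(synth_spec(class_fractions = c(standard_a = 1)), "setequal")
  expect_error(synth_spec(ratios = list(a = c(1, 2)),
                          class_fractions = c(a = 1)))
  expect_error(synth_spec(cv_noise = -0.1))
  expect_error(synth_spec(noise_correlation = 1.5))
  expect_error(synth_spec(interference_fraction = 1))
  s <- synth_spec()
  expect_s3_class(s, "synth_spec")
  expect_equal(sum(s$class_fractions), 1)
})

test_that("the default panel is a balanced spike-in design", {
  s <- synth_spec()
  # every channel carries the same total spike mass
  spike <- Reduce(`+`, Map(function(r, f) r * f,
                           s$ratios, as.list(s$class_fractions[names(s$ratios)])))
  expect_lt(diff(range(spike)), 1e-12)
  # sub-classes all report the "standard" truth class
  ds <- generate_dataset(synth_spec(n_proteins = 10, seed = 2))
  expect_setequal(unique(ds$truth$class), c("standard", "background"))
  expect_equal(sum(ds$truth$class == "standard"), 3)
})

test_that("class assignment uses exact largest-remainder counts", {
  cls <- isoquantr:::assign_classes(50, c(a = 0.1, b = 0.1, c = 0.1, bg = 0.7))
  expect_equal(unname(table(cls)[c("a", "b", "c", "bg")]),
               as.integer(c(5, 5, 5, 35)), ignore_attr = TRUE)
})

test_that("generation is deterministic in the seed", {
  a <- generate_dataset(synth_spec(n_proteins = 3, seed = 4))
  b <- generate_dataset(synth_spec(n_proteins = 3, seed = 4))
  c <- generate_dataset(synth_spec(n_proteins = 3, seed = 5))
  expect_equal(a$spectra, b$spectra)
  expect_equal(a$psms, b$psms)
  expect_false(isTRUE(all.equal(a$spectra, c$spectra)))
})

test_that("noise-free PSM intensities follow the abundance model exactly", {
  spec <- synth_spec(n_proteins = 4, peptides_per_protein = c(1, 1),
                     psms_per_peptide = c(1, 1), cv_noise = 0, seed = 6)
  ds <- generate_dataset(spec)
  qd <- as_quant_dataset(ds)
  wide <- reporter_intensities(ds$psms, ds$spectra, ds$channels)
  labels <- ds$channels$label
  mat <- as.matrix(wide[, labels])
  # each PSM's channel profile is proportional to its protein's abundances
  for (i in seq_len(nrow(mat))) {
    acc <- ds$psms$proteins[[i]][1]
    abund <- as.numeric(ds$truth[ds$truth$accession == acc, labels])
    profile <- mat[i, ] / sum(mat[i, ])
    expect_equal(unname(profile), abund / sum(abund), tolerance = 1e-9)
  }
})

test_that("interference is flat 1:1 and sized to the requested fraction", {
  f <- 0.25
  spec <- synth_spec(n_proteins = 2, peptides_per_protein = c(1, 1),
                     psms_per_peptide = c(1, 1), cv_noise = 0,
                     interference_fraction = f, seed = 7)
  ds <- generate_dataset(spec)
  expect_equal(ds$psm_truth$s2i_true, rep(1 - f, nrow(ds$psm_truth)))
  # the generated MS1 scans realize exactly that S2I
  s2i <- compute_s2i(ds$psms, ds$spectra)
  expect_equal(s2i$s2i, rep(1 - f, nrow(s2i)), tolerance = 1e-12)
})

test_that("an impurity table is folded into the observed spectra", {
  imp <- tibble::tibble(channel = plex_channels("tmt6")$label,
                        minus2 = 0, minus1 = 1, plus1 = 2, plus2 = 0)
  spec <- synth_spec(n_proteins = 2, peptides_per_protein = c(1, 1),
                     psms_per_peptide = c(1, 1), cv_noise = 0,
                     impurity_table = imp, seed = 10)
  ds <- generate_dataset(spec)
  qd <- as_quant_dataset(ds)
  # correcting with the dataset's own matrix recovers the true profile
  wide <- reporter_intensities(ds$psms, ds$spectra, ds$channels)
  corr <- correct_impurities(wide, ds$matrix)
  labels <- ds$channels$label
  acc <- ds$psms$proteins[[1]][1]
  abund <- as.numeric(ds$truth[ds$truth$accession == acc, labels])
  profile <- as.numeric(corr[1, labels]) / sum(corr[1, labels])
  expect_equal(profile, abund / sum(abund), tolerance = 1e-9)
})

test_that("fixture files round-trip through the package's own readers", {
  dir <- tempfile()
  ds <- generate_dataset(synth_spec(n_proteins = 4,
                                    peptides_per_protein = c(1, 2),
                                    psms_per_peptide = c(1, 2), seed = 12))
  write_fixture_files(ds, dir)
  expect_true(all(file.exists(file.path(
    dir, c("spectra.mzML", "psms.tsv", "proteins.tsv", "impurity.csv",
           "truth.tsv", "psm_truth.tsv", "dataset.yaml")))))
  back <- read_fixture_dataset(dir)
  expect_s3_class(back$dataset, "quant_dataset")
  expect_equal(back$truth$accession, ds$truth$accession)
  # quantifying the read-back dataset matches the in-memory dataset
  mem <- quantify(as_quant_dataset(ds), "131/126")
  disk <- quantify(back$dataset, "131/126")
  expect_equal(disk$proteins$value, mem$proteins$value, tolerance = 1e-5)
})

test_that("the compression curve matches the closed form and RCC undoes it", {
  # 4 channels, abundances (1,1,1,2): with interference fraction f the
  # uncorrected ratio is (a_j/S + c) / (a_k/S + c), c = f / ((1-f) * n_ch)
  spec <- synth_spec(n_proteins = 4, peptides_per_protein = c(1, 1),
                     psms_per_peptide = c(2, 2), plex = "itraq4",
                     ratios = list(standard = c(1, 1, 1, 2),
                                   background = rep(1, 4)),
                     class_fractions = c(standard = 0.5, background = 0.5),
                     cv_noise = 0, seed = 18)
  curve <- compression_curve(spec, c(0, 0.5), pair = "117/114")
  expect_equal(curve$ideal, c(2, 2))
  expect_equal(curve$uncorrected[1], 2, tolerance = 1e-9)
  cc <- 0.5 / (0.5 * 4)
  expect_equal(curve$uncorrected[2], (2 / 5 + cc) / (1 / 5 + cc),
               tolerance = 1e-9)
  expect_equal(curve$rcc, c(2, 2), tolerance = 1e-9)
  expect_false(any(curve$clamped))
  p <- plot_compression_curve(curve)
  expect_s3_class(p, "ggplot")
})
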