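mk_input <- function(x, y, class = NA_character_) {
  tibble::tibble(accession = paste0("P", seq_along(x)),
                 pair = "127/126", x = x, y = y,
                 class = rep_len(class, length(x)))
}

test_that("ARE matches the hand examples and is scale-invariant", {
  expect_equal(are(mk_input(c(2.2, 0.9), c(2, 1))), 0.1)
  expect_equal(are(mk_input(c(1, 2), c(1, 2))), 0)
  expect_equal(are(mk_input(1.1, 1)), are(mk_input(11, 10)))
})

test_that("class filters give ARE_Std and ARE_Bg", {
  input <- mk_input(c(4.4, 1.1), c(4, 1), class = c("standard", "background"))
  expect_equal(are(input, "standard"), 0.1)
  expect_equal(are(input, "background"), 0.1)
  expect_warning(empty <- are(input, "nonexistent"), "No entries")
  expect_true(is.na(empty))
})

test_that("RMSE matches hand examples", {
  expect_equal(rmse(mk_input(c(1.1, 0.9), c(1, 1))), 0.1)
  expect_equal(rmse(mk_input(3, 1)), 2)
  expect_equal(rmse(mk_input(c(1, 2), c(1, 2))), 0)
})

test_that("coverage_at_deviation counts entries within the bound", {
  input <- mk_input(c(1.05, 1.5), c(1, 1))
  expect_equal(coverage_at_deviation(input, 0.1), 0.5)
  expect_equal(coverage_at_deviation(mk_input(c(1, 2), c(1, 2)), 0), 1)
  expect_equal(coverage_at_deviation(input, 1), 1)
  expect_error(coverage_at_deviation(input, 1.5))
})

test_that("AUCCD closed forms hold", {
  expect_equal(auccd(mk_input(c(1, 2, 4), c(1, 2, 4))), 1)
  # point mass at deviation 0.25: area of the step function = 0.75
  expect_equal(auccd(mk_input(c(1.25, 2.5), c(1, 2))), 0.75, tolerance = 0.01)
  # everything further than 100% off
  expect_lte(auccd(mk_input(c(10, 20), c(1, 2))), 0.01)
})

test_that("ratio_summary reports sample mean/SD at one ideal value", {
  input <- mk_input(c(1.1, 0.9, 4), c(1, 1, 4))
  s <- ratio_summary(input, 1)
  expect_equal(s$mean, 1)
  expect_equal(s$sd, sd(c(1.1, 0.9)))
  expect_equal(s$n, 2)
  s4 <- ratio_summary(input, 4)
  expect_equal(s4$mean, 4)
  expect_true(is.na(s4$sd))
})

test_that("evaluate_ratios aggregates all metrics in one row", {
  proteins <- tibble::tibble(accession = c("P1", "P2"), pair = "127/126",
                             value = c(2.2, 0.9))
  truth <- tibble::tibble(accession = c("P1", "P2"), pair = "127/126",
                          ideal = c(2, 1), class = c("standard", "background"))
  m <- evaluate_ratios(proteins, truth)
  expect_equal(m$are, 0.1)
  expect_equal(m$are_std, 0.1)
  expect_equal(m$are_bg, 0.1)
  expect_equal(m$n_ratios, 2)
  expect_error(evaluate_ratios(proteins,
                               dplyr::mutate(truth, ideal = c(2, 0))),
               "positive")
})

test_that("differential selection and Jaccard behave as set operations", {
  proteins <- tibble::tibble(
    accession = c("A", "A", "B", "C"),
    value = c(1.0, 1.6, 1.2, 0.5)
  )
  expect_equal(select_differential(proteins), "A")
  expect_equal(select_differential(proteins, symmetric = TRUE), c("A", "C"))
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard(c("A", "A"), c("A")), 1)
  expect_warning(j <- jaccard(character(0), character(0)), "empty")
  expect_true(is.na(j))
})
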