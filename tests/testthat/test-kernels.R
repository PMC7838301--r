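test_that("kernel closed forms match hand computations", {
  # regression slope through origin of (den, num) = (1,2), (2,4), (3,7)
  expect_equal(regression_slope_ratio(c(1, 2, 3), c(2, 4, 7)), 31 / 14)
  # a single point reduces to the plain ratio
  expect_equal(regression_slope_ratio(100, 200), 2)
  expect_equal(sum_intensity_ratio(c(200, 100), c(100, 50)), 2)
  expect_equal(median_ratio(c(1, 2, 3, 4, 100)), 3)
  expect_equal(median_ratio(c(1, 3)), 2)
  expect_equal(weighted_mean_ratio(c(2, 1), c(300, 100)), 1.75)
  # trimmed mean, 20% per side: 1..10 trims {1,2} and {9,10}
  expect_equal(trimmed_mean_ratio(1:10), mean(3:8))
  expect_equal(trimmed_mean_ratio(c(5, 5, 5)), 5)
  expect_equal(peptide_weight(c(100, 300, 500)), 300)
})

test_that("kernels return NA on undefined input and validate weights", {
  expect_true(is.na(regression_slope_ratio(numeric(0), numeric(0))))
  expect_true(is.na(regression_slope_ratio(c(0, 0), c(1, 2))))
  expect_true(is.na(sum_intensity_ratio(c(0, 0), c(1, 2))))
  expect_true(is.na(sum_intensity_ratio(c(1, 2), c(0, 0))))
  expect_true(is.na(median_ratio(NA_real_)))
  expect_error(weighted_mean_ratio(c(1, 2), c(-1, 1)), "non-negative")
  expect_warning(w <- weighted_mean_ratio(c(1, 3), c(0, 0)), "zero")
  expect_equal(w, 2)
})

test_that("all kernels return the common value on identical ratios", {
  v <- rep(2.5, 7)
  expect_equal(median_ratio(v), 2.5)
  expect_equal(weighted_mean_ratio(v, runif(7, 1, 10)), 2.5)
  expect_equal(trimmed_mean_ratio(v), 2.5)
  den <- runif(7, 10, 100)
  expect_equal(regression_slope_ratio(den, 2.5 * den), 2.5)
  expect_equal(sum_intensity_ratio(2.5 * den, den), 2.5)
})

test_that("kernels are invariant under PSM permutation", {
  set.seed(21)
  v <- runif(9, 0.2, 5); w <- runif(9, 1, 100)
  den <- runif(9, 10, 1000); num <- v * den
  p <- sample(9)
  expect_equal(median_ratio(v[p]), median_ratio(v))
  expect_equal(weighted_mean_ratio(v[p], w[p]), weighted_mean_ratio(v, w))
  expect_equal(trimmed_mean_ratio(v[p]), trimmed_mean_ratio(v))
  expect_equal(regression_slope_ratio(den[p], num[p]),
               regression_slope_ratio(den, num))
  expect_equal(sum_intensity_ratio(num[p], den[p]),
               sum_intensity_ratio(num, den))
})

test_that("median and trimmed mean are robust to inflating the largest ratio", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    v <- sort(runif(n, 0.5, 4))
    v2 <- v
    v2[n] <- v[n] * runif(1, 1, 1000)
    expect_equal(median_ratio(v2), median_ratio(v))
    expect_equal(trimmed_mean_ratio(v2), trimmed_mean_ratio(v))
  }
})

test_that("reciprocal symmetry holds where the math guarantees it", {
  set.seed(23)
  num <- runif(8, 10, 1000); den <- runif(8, 10, 1000)
  expect_equal(sum_intensity_ratio(num, den) * sum_intensity_ratio(den, num), 1)
  # median of inverted ratios is the inverse of the median for odd counts
  v <- runif(7, 0.2, 5)
  expect_equal(median_ratio(1 / v), 1 / median_ratio(v))
})
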