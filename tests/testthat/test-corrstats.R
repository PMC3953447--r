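test_that("fisher_ci reproduces the published interval and the closed form", {
  ## published: WC-VAT r = 0.80 at n = 598 -> (0.77, 0.83)
  ci <- fisher_ci(0.80, 598)
  expect_equal(round(ci$ci_low, 2), 0.77)
  expect_equal(round(ci$ci_high, 2), 0.83)
  ## direct evaluation of the formula: atanh(0.5) -/+ 1.959964/sqrt(100)
  ci2 <- fisher_ci(0.5, 103)
  expect_equal(ci2$ci_low, tanh(atanh(0.5) - qnorm(0.975) / 10), tolerance = 1e-12)
  expect_equal(round(ci2$ci_low, 5), 0.33931)
  expect_equal(round(ci2$ci_high, 5), 0.63234)
  ## symmetry about zero
  ci0 <- fisher_ci(0, 1000)
  expect_equal(ci0$ci_low, -ci0$ci_high)
})

test_that("fisher_ci interval contains r and narrows with n", {
  rs <- c(-0.9, -0.3, 0, 0.42, 0.8, 0.97)
  ns <- c(10, 30, 100, 300, 1000)
  prev_width <- rep(Inf, length(rs))
  for (n in ns) {
    ci <- fisher_ci(rs, n)
    expect_true(all(ci$ci_low <= rs & rs <= ci$ci_high))
    expect_true(all(ci$ci_low >= -1 & ci$ci_high <= 1))
    width <- ci$ci_high - ci$ci_low
    expect_true(all(width < prev_width))
    prev_width <- width
  }
})

test_that("fisher_ci edge cases", {
  expect_warning(ci <- fisher_ci(1, 100), "degenerate")
  expect_equal(c(ci$ci_low, ci$ci_high), c(1, 1))
  expect_error(fisher_ci(0.5, 3), "exceed 3")
  expect_error(fisher_ci(0.5, 60, k = 57), "exceed 3")
})

test_that("nearest_psd leaves PSD matrices alone and repairs indefinite ones", {
  expect_identical(nearest_psd(diag(3)), diag(3))
  ## the published matrices are near-PSD already: repair is a no-op
  men <- reference_correlations("male")$r
  expect_identical(nearest_psd(men), men)
  ## known-indefinite 3x3
  bad <- matrix(c(1, .9, .9, .9, 1, -.9, .9, -.9, 1), 3, 3)
  expect_lt(min(eigen(bad, only.values = TRUE)$values), 0)
  rep1 <- nearest_psd(bad)
  expect_gte(min(eigen(rep1, only.values = TRUE)$values), 0)
  expect_equal(diag(rep1), rep(1, 3))
  expect_equal(nearest_psd(rep1), rep1, tolerance = 1e-12)  # idempotent
  expect_error(nearest_psd(matrix(1:4, 2, 2)), "symmetric")
})

test_that("multiple_r2_from_corr matches hand-computable cases", {
  expect_equal(multiple_r2_from_corr(c(0, 0, 0), diag(3)), 0)
  expect_equal(multiple_r2_from_corr(c(0.3, 0.4, 0), diag(3)), 0.25)
  sing <- matrix(1, 2, 2)
  expect_error(multiple_r2_from_corr(c(.5, .5), sing), "singular")
})

test_that("R2 from a correlation matrix equals R2 of an OLS fit on a matching sample", {
  R <- random_corr(4, seed = 11)
  colnames(R) <- rownames(R) <- c("y", "x1", "x2", "x3")
  d <- sample_with_exact_corr(200, R, seed = 3)
  fit <- fit_compartment_model(d, "y", c("x1", "x2", "x3"))
  r2_mat <- multiple_r2_from_corr(R["y", -1], R[-1, -1])
  expect_equal(fit$r_squared, r2_mat, tolerance = 1e-8)
})

test_that("partial correlation: precision and increment routes agree", {
  for (s in 1:25) {
    p <- sample(3:6, 1)
    R <- random_corr(p, seed = s)
    i <- 1; j <- sample(2:p, 1)
    a <- partial_corr_from_corr(R, i, j, method = "precision")
    b <- partial_corr_from_corr(R, i, j, method = "increment")
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("partial correlation reduces to marginal r under block independence", {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.6
  expect_equal(partial_corr_from_corr(R, 1, 2), 0.6, tolerance = 1e-12)
})

test_that("pearson_matrix computes product-moment correlations with CIs", {
  d <- tibble::tibble(a = rnorm(50), b = rnorm(50))
  d$c <- 2 * d$a  # exactly proportional
  suppressWarnings(cm <- pearson_matrix(d))
  expect_s3_class(cm, "corr_matrix")
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm$r["a", "c"], 1, tolerance = 1e-12)
  expect_equal(cm$r["a", "b"], cor(d$a, d$b))
  td <- tidy(cm)
  expect_true(all(td$ci_low <= td$r & td$r <= td$ci_high))
  d$z <- 1
  expect_error(pearson_matrix(d), "zero-variance.*z")
  d$z <- NULL; d$b[1] <- NA
  expect_error(pearson_matrix(d), "missing values in: b")
})

test_that("formatting follows the published table conventions", {
  men <- reference_correlations("male")
  tab <- format_corr_table(men)
  expect_equal(tab["VAT", "WC"], "0.80 (0.77-0.83)")
  expect_equal(tab["BMI", "VAT"], "")  # upper triangle empty
})
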