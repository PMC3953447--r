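test_that("sample_with_exact_corr forces the sample correlation matrix", {
  R <- random_corr(5, seed = 21)
  colnames(R) <- rownames(R) <- paste0("v", 1:5)
  d <- sample_with_exact_corr(120, R, seed = 1)
  expect_equal(unclass(cor(as.matrix(d))), unclass(R), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("published-table-matched samples reproduce the printed model numbers", {
  men <- reference_correlations("male")$r
  d <- sample_with_exact_corr(598, men, seed = 10)
  fit_smt <- fit_compartment_model(d, "SMT", c("BMI", "WC", "HC"))
  expect_equal(round(fit_smt$r_squared, 2), 0.45)
  fit_vat <- fit_compartment_model(d, "VAT", c("BMI", "WC", "HC"))
  expect_equal(round(fit_vat$r_squared, 2), 0.65)
  wc_partial <- fit_vat$partials$partial_r[fit_vat$partials$term == "WC"]
  expect_equal(round(wc_partial, 3), 0.438)
  ## partial CI at the study n reproduces the printed interval (0.37-0.50)
  ci <- fit_vat$partials[fit_vat$partials$term == "WC", ]
  expect_equal(round(ci$ci_low, 2), 0.37)
  expect_equal(round(ci$ci_high, 2), 0.50)
})

test_that("orthogonal predictors give unit VIFs and marginal partials", {
  R <- diag(4)
  colnames(R) <- rownames(R) <- c("y", "x1", "x2", "x3")
  R["y", "x1"] <- R["x1", "y"] <- 0.5
  d <- sample_with_exact_corr(150, R, seed = 2)
  fit <- fit_compartment_model(d, "y", c("x1", "x2", "x3"))
  expect_equal(fit$partials$vif, rep(1, 3), tolerance = 1e-10)
  expect_equal(fit$partials$partial_r[1], 0.5, tolerance = 1e-8)
})

test_that("VIF matches the closed form for two correlated predictors", {
  R <- diag(3)
  colnames(R) <- rownames(R) <- c("y", "x1", "x2")
  R["x1", "x2"] <- R["x2", "x1"] <- 0.9
  R["y", "x1"] <- R["x1", "y"] <- 0.3
  d <- sample_with_exact_corr(100, R, seed = 5)
  fit <- fit_compartment_model(d, "y", c("x1", "x2"))
  expect_equal(fit$partials$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-8)
})

test_that("sample R2 equals the correlation-matrix R2 and never decreases with predictors", {
  for (s in 1:8) {
    R <- random_corr(5, seed = 100 + s)
    colnames(R) <- rownames(R) <- c("y", "x1", "x2", "x3", "x4")
    d <- sample_with_exact_corr(80, R, seed = s)
    r2 <- numeric(4)
    for (p in 1:4) {
      fit <- fit_compartment_model(d, "y", paste0("x", 1:p))
      r2[p] <- fit$r_squared
    }
    expect_true(all(diff(r2) >= -1e-12))
    r2_mat <- multiple_r2_from_corr(R["y", -1], R[-1, -1])
    expect_equal(r2[4], r2_mat, tolerance = 1e-10)
  }
})

test_that("type II partials agree with the matrix route on random samples", {
  for (s in 1:10) {
    d <- tibble::as_tibble(as.data.frame(matrix(rnorm(200 * 4), 200, 4)))
    names(d) <- c("y", "a", "b", "c")
    agg <- check_partial_agreement(d, "y", c("a", "b", "c"))
    expect_lt(max(agg$diff), 1e-10)
  }
})

test_that("collinearity beyond tolerance raises with the offending predictor", {
  d <- tibble::tibble(y = rnorm(50), x1 = rnorm(50))
  d$x2 <- d$x1  # exact copy
  expect_error(fit_compartment_model(d, "y", c("x1", "x2"), vif_tol = 1e6),
               "VIF")
})

test_that("optimism bootstrap: corrected = apparent - optimism, positive on average", {
  d <- random_toy_cohort(n = 120, seed = 3)
  ob <- optimism_bootstrap(d, "y1", c("age_substudy", "height_cm"),
                           B = 60, seed = 1)
  expect_equal(ob$corrected, ob$apparent - ob$optimism)
  ## expectation over seeds: corrected below apparent
  opts <- vapply(1:20, function(s)
    optimism_bootstrap(d, "y1", c("age_substudy", "height_cm"),
                       B = 25, seed = s)$optimism, numeric(1))
  expect_gt(mean(opts), 0)
})

test_that("pure-noise optimism matches the brute-force oracle", {
  ## independent brute-force simulation of the same estimator gives a mean
  ## optimism of ~0.376 for n = 20, p = 3 pure-noise predictors (the naive
  ## p/(n-1) heuristic only covers the apparent-R2 half of the difference)
  opts <- vapply(1:25, function(s) {
    d <- withr::with_seed(1000 + s, tibble::as_tibble(
      as.data.frame(matrix(rnorm(20 * 4), 20, 4))))
    names(d) <- c("y", "a", "b", "c")
    optimism_bootstrap(d, "y", c("a", "b", "c"), B = 200, seed = s)$optimism
  }, numeric(1))
  expect_equal(mean(opts), 0.376, tolerance = 0.2)
})

test_that("bootstrap resampling respects strata", {
  d <- random_toy_cohort(n = 80, seed = 9)
  ob <- optimism_bootstrap(d, "y1", c("age_substudy", "height_cm"),
                           B = 10, seed = 2, by = "sex")
  expect_s3_class(ob, "optimism_result")
  expect_true(is.finite(ob$optimism))
})

test_that("broom methods return tidy tibbles", {
  d <- random_toy_cohort(n = 60, seed = 12)
  fit <- fit_compartment_model(d, "y1", c("y2", "y3"))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("outcome", "term", "estimate", "partial_r", "ci_low",
                     "ci_high", "vif"))
  gl <- glance(fit)
  expect_equal(gl$r.squared, fit$r_squared)
  expect_true(all(td$partial_r >= td$ci_low & td$partial_r <= td$ci_high))
})
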