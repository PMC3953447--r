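test_that("derive_sd applies the range rule", {
  ## men 35-44 band weight: mean 85.9, range (53.4, 128.5)
  m <- tibble::tibble(mean = 85.9, min = 53.4, max = 128.5)
  expect_equal(derive_sd(m, "range4")$sd, 18.775)
  expect_equal(derive_sd(tibble::tibble(mean = 3, min = 0, max = 6),
                         "range6")$sd, 1.0)
  expect_error(derive_sd(tibble::tibble(mean = 0, min = 0, max = 0)),
               "degenerate range")
})

test_that("triple_measure averages noisy readings", {
  expect_equal(triple_measure(c(99.2, 85), noise_sd = 0), c(99.2, 85))
  ## variance of a mean of three readings is noise_sd^2 / 3
  out <- withr::with_seed(4, triple_measure(rep(100, 10000), noise_sd = 0.3))
  expect_equal(sd(out), 0.3 / sqrt(3), tolerance = 0.05)
  expect_equal(mean(c(100.0, 100.3, 99.7)), 100.0)  # recorded value is the mean
  expect_error(triple_measure(1, noise_sd = -1), "noise_sd")
})

test_that("shipped calibrations reproduce the published correlation targets", {
  for (s in c("male", "female")) {
    cal <- reference_calibration(s)
    err <- max(abs(induced_correlation(cal) - reference_correlations(s)$r))
    expect_lt(err, 0.006)
    ## latent covariance is a valid covariance matrix
    expect_gte(min(eigen(cal$Lambda, only.values = TRUE)$values), -1e-10)
  }
})

test_that("default design yields the sub-study shape with exact identities", {
  cohort <- simulate_cohort(seed = 123)
  expect_equal(nrow(cohort), 1200)
  expect_equal(sum(cohort$sex == "male"), 600)
  expect_equal(sum(cohort$sex == "female"), 600)
  counts <- dplyr::count(cohort, sex, center, age_band)
  expect_equal(nrow(counts), 12)
  expect_true(all(counts$n == 100))
  ## additivity holds exactly, not just within tolerance
  expect_identical(cohort$tat_l, cohort$vat_l + cohort$sat_l + cohort$cat_l)
  expect_identical(cohort$tbv_l, cohort$tat_l + cohort$smt_l + cohort$rest_l)
  expect_true(all(cohort$vat_l > 0 & cohort$sat_l > 0 & cohort$cat_l > 0 &
                    cohort$smt_l > 0 & cohort$rest_l > 0))
  expect_equal(cohort$bmi, cohort$weight_kg / (cohort$height_cm / 100)^2)
  expect_false(anyDuplicated(cohort$subject_id) > 0)
  ## ages: baseline within band, sub-study lag within [14, 17]
  lag <- cohort$age_substudy - cohort$age_baseline
  expect_true(all(lag >= 14 & lag <= 17))
  bb <- cbind(lo = as.numeric(sub("-.*", "", cohort$age_band)))
  expect_true(all(cohort$age_baseline >= bb[, "lo"] &
                    cohort$age_baseline <= bb[, "lo"] + 10))
})

test_that("same seed and config give an identical cohort", {
  a <- simulate_cohort(cohort_design(10L), seed = 7)
  b <- simulate_cohort(cohort_design(10L), seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "config_digest"), attr(b, "config_digest"))
  c2 <- simulate_cohort(cohort_design(10L), seed = 8)
  expect_false(identical(a$bmi, c2$bmi))
})

test_that("marginal means track the published per-sex values", {
  cohort <- simulate_cohort(cohort_design(200L), seed = 31)
  pool <- anthroval:::.pooled_marginals(reference_marginals(), "male")
  men <- cohort[cohort$sex == "male", ]
  cols <- variable_columns()
  for (v in c("BMI", "WC", "HC", "TAT", "VAT", "SAT", "CAT", "SMT", "TBV")) {
    target <- pool$mean[pool$variable == v]
    expect_equal(mean(men[[cols[[v]]]]), target, tolerance = 0.06)
  }
})

test_that("apply_exclusions drops a deterministic count at random", {
  cohort <- simulate_cohort(cohort_design(10L), seed = 3)  # 120 rows
  kept <- apply_exclusions(cohort, 42 / 1234, seed = 1)
  expect_equal(nrow(kept), 120 - round(120 * 42 / 1234))
  expect_equal(attr(kept, "n_excluded"), round(120 * 42 / 1234))
  expect_identical(nrow(apply_exclusions(cohort, 0)), nrow(cohort))
  expect_error(apply_exclusions(cohort, 1), "below 1")
  ## forced arithmetic: 3% of 100 -> 97 usable
  kept2 <- apply_exclusions(cohort[1:100, ], 0.03, seed = 2)
  expect_equal(nrow(kept2), 97)
})

test_that("weight change is present with the expected missingness rate", {
  cohort <- simulate_cohort(cohort_design(150L), seed = 17)  # 1800 rows
  frac <- mean(is.na(cohort$weight_change_kg))
  expect_lt(abs(frac - 97 / 1192), 0.005)
})

test_that("generator errors are informative", {
  expect_error(simulate_cohort(cohort_design(5L),
                               calibration = list(male = reference_calibration("male"))),
               "calibration missing for: female")
  marg <- reference_marginals()
  expect_error(
    simulate_cohort(cohort_design(5L), seed = 1,
                    marginals = marg[marg$variable != "VAT", ]),
    "marginal missing")
  ## a wildly indefinite target cannot be calibrated
  bad <- reference_correlations("male")$r
  bad[lower.tri(bad)] <- -bad[lower.tri(bad)]
  bad[upper.tri(bad)] <- t(bad)[upper.tri(bad)]
  expect_error(calibrate_cohort_model(bad, sex = "male"), "non-repairable")
})
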