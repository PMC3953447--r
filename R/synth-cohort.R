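#' Derive a spread parameter from a published mean (min, max) summary
#'
#' Validation-study descriptive tables often print mean and range but no
#' standard deviation. For roughly Gaussian samples of a few hundred
#' observations the range spans about four standard deviations, so the
#' default rule is `(max - min) / 4`; `"range6"` uses `(max - min) / 6`.
#'
#' @param marginals Data frame with columns `mean`, `min`, `max` (e.g. from
#'   [reference_marginals()]).
#' @param rule `"range4"` (default) or `"range6"`.
#' @return The input with an added `sd` column.
#' @export
derive_sd <- function(marginals, rule = c("range4", "range6")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(marginals),
            all(c("mean", "min", "max") %in% names(marginals)))
  if (any(marginals$min >= marginals$max)) {
    bad <- which(marginals$min >= marginals$max)
    stop("degenerate range (min >= max) in row(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(marginals$mean <= marginals$min | marginals$mean >= marginals$max)) {
    stop("mean must lie strictly between min and max")
  }
  div <- switch(rule, range4 = 4, range6 = 6)
  out <- marginals
  out$sd <- (out$max - out$min) / div
  out
}

#' Mean of repeated noisy readings
#'
#' Emulates the anthropometric protocol in which waist and hip
#' circumferences are measured three times and the arithmetic mean is
#' recorded; the recorded value has measurement variance
#' `noise_sd^2 / n_readings`.
#'
#' @param true_value Vector of true values.
#' @param noise_sd Standard deviation of a single reading's error (>= 0).
#' @param n_readings Number of readings averaged (default 3).
#' @return Vector of recorded means, same length as `true_value`.
#' @export
triple_measure <- function(true_value, noise_sd = 0.3, n_readings = 3L) {
  stopifnot(noise_sd >= 0, n_readings >= 1)
  n <- length(true_value)
  readings <- matrix(stats::rnorm(n * n_readings, mean = true_value,
                                  sd = noise_sd),
                     nrow = n, ncol = n_readings)
  rowMeans(readings)
}

#' Tunable constants of the cohort generator
#'
#' All the generator's calibration constants in one place, with defaults
#' chosen to emulate the validation sub-study's design and measurement
#' protocol. See the methods vignette for the rationale behind each value.
#'
#' @param follow_up_lag Range (years) of the uniform lag between baseline
#'   recruitment and the MRI sub-study.
#' @param wc_noise_sd Per-reading measurement error (cm) for waist and hip
#'   circumference.
#' @param n_readings Circumference readings averaged per subject.
#' @param height_r Target unadjusted within-sex correlations with height for
#'   the Gaussian components; the BMI value of 0.2 reproduces the low
#'   BMI-height correlation reported for sex-stratified cohorts.
#' @param vol_height_loggrad Multiplicative height gradient (per cm of
#'   height residual) of the adipose compartment volumes.
#' @param weight_gain_mean,weight_gain_sd Mean and SD (kg) of simulated
#'   weight gain since early adulthood.
#' @param recall_sd Recall noise (kg) added to self-reported early-adult
#'   weight.
#' @param weight_change_missing_rate Fraction of subjects with missing
#'   weight change (97/1192 in the sub-study).
#' @param volume_floor Lower clamp (liters) for Gaussian-generated volumes
#'   (SMT, rest); hit with negligible probability under the defaults.
#' @return Named list of generator constants.
#' @export
generator_control <- function(follow_up_lag = c(14, 17),
                              wc_noise_sd = 0.3,
                              n_readings = 3L,
                              height_r = c(bmi = 0.2, wc = 0.15, hc = 0.20,
                                           smt = 0.55, rest = 0.50),
                              vol_height_loggrad = 0.004,
                              weight_gain_mean = 10,
                              weight_gain_sd = 6,
                              recall_sd = 2,
                              weight_change_missing_rate = 97 / 1192,
                              volume_floor = 0.05) {
  list(follow_up_lag = follow_up_lag, wc_noise_sd = wc_noise_sd,
       n_readings = n_readings, height_r = height_r,
       vol_height_loggrad = vol_height_loggrad,
       weight_gain_mean = weight_gain_mean, weight_gain_sd = weight_gain_sd,
       recall_sd = recall_sd,
       weight_change_missing_rate = weight_change_missing_rate,
       volume_floor = volume_floor)
}

.band_bounds <- function(age_band) {
  lo <- as.numeric(sub("-.*", "", age_band))
  cbind(lo = lo, hi = lo + 10)
}

## Weighted linear fit of per-band means against mean attained age; returns
## a function age -> mean.
.age_trend <- function(band_means, band_ages, weights) {
  fit <- stats::lm.wfit(cbind(1, band_ages), band_means, w = weights)
  b <- fit$coefficients
  function(age) b[1] + b[2] * age
}

#' Simulate a synthetic validation cohort
#'
#' Generates per-subject anthropometry and MRI compartment volumes whose
#' design (sex x center x 10-year age band strata), marginal means and
#' ranges, and sex-stratified age/height-adjusted correlation structure
#' match the published validation sub-study. Volume additivity holds
#' exactly for every record: `tat_l = vat_l + sat_l + cat_l` and
#' `tbv_l = tat_l + smt_l + rest_l`, because the adipose compartments are
#' drawn (log-normally, hence strictly positive) and the aggregates are
#' computed sums. Waist and hip circumferences are recorded as the mean of
#' three noisy readings; `bmi = weight_kg / (height_cm/100)^2` exactly.
#'
#' @param design Stratum table from [cohort_design()].
#' @param seed Integer seed; the same seed and configuration give an
#'   identical cohort.
#' @param marginals Marginal table, default [reference_marginals()].
#' @param calibration Named list with elements `male` and/or `female` of
#'   `cohort_calibration` objects; defaults to the shipped
#'   [reference_calibration()] per sex.
#' @param control Generator constants from [generator_control()].
#' @param truncate If `TRUE`, clamp generated component values to the
#'   pooled published ranges for display realism (off by default: clamping
#'   distorts correlations; aggregates are re-summed so additivity is
#'   preserved).
#' @return A tibble with one row per subject and the cohort CSV schema
#'   columns (see [write_cohort()]), plus attributes `seed` and
#'   `config_digest`.
#' @export
simulate_cohort <- function(design = cohort_design(), seed = 1,
                            marginals = reference_marginals(),
                            calibration = NULL,
                            control = generator_control(),
                            truncate = FALSE) {
  stopifnot(is.data.frame(design),
            all(c("sex", "center", "age_band", "n_target") %in% names(design)),
            all(design$n_target > 0))
  sexes <- unique(design$sex)
  if (is.null(calibration)) {
    calibration <- lapply(setNames(sexes, sexes), reference_calibration)
  }
  if (!all(sexes %in% names(calibration))) {
    stop("calibration missing for: ",
         paste(setdiff(sexes, names(calibration)), collapse = ", "))
  }
  digest <- rlang::hash(list(design, marginals_digest = rlang::hash(marginals),
                             control, seed))
  out <- withr::with_seed(seed, {
    dplyr::bind_rows(lapply(sexes, function(s) {
      .simulate_sex(design[design$sex == s, ], s, marginals,
                    calibration[[s]], control, truncate)
    }))
  })
  out$subject_id <- sprintf("S%05d", seq_len(nrow(out)))
  out <- out[, c("subject_id", setdiff(names(out), "subject_id"))]
  attr(out, "seed") <- seed
  attr(out, "config_digest") <- digest
  out
}

.simulate_sex <- function(design, sex, marginals, calib, control, truncate) {
  stopifnot(inherits(calib, "cohort_calibration"))
  marg <- marginals[marginals$sex == sex, ]
  vars_needed <- c(analysis_variables(), "height_cm")
  missing_vars <- setdiff(vars_needed, unique(marg$variable))
  if (length(missing_vars)) {
    stop("marginal missing for: ", paste(missing_vars, collapse = ", "))
  }
  pool <- .pooled_marginals(marginals, sex)
  get_pool <- function(v, what) pool[[what]][pool$variable == v]

  ## strata and ages
  n_str <- design$n_target
  n <- sum(n_str)
  center <- rep(design$center, n_str)
  age_band <- rep(design$age_band, n_str)
  bb <- .band_bounds(age_band)
  age_baseline <- stats::runif(n, bb[, "lo"], bb[, "hi"])
  lag <- stats::runif(n, control$follow_up_lag[1], control$follow_up_lag[2])
  age <- age_baseline + lag

  ## per-variable age trends from the published per-band means
  band_levels <- sort(unique(marg$age_band))
  band_mid <- .band_bounds(band_levels)[, "lo"] + 5 + mean(control$follow_up_lag)
  trend_for <- function(v, log_scale = FALSE) {
    mv <- marg[marg$variable == v, ]
    mv <- mv[match(band_levels, mv$age_band), ]
    y <- if (log_scale) log(mv$mean) else mv$mean
    .age_trend(y, band_mid, mv$n)
  }

  ## height: linear age trend + Gaussian residual
  h_trend <- trend_for("height_cm")
  sd_h_pool <- get_pool("height_cm", "sd")
  h_slope <- (h_trend(60) - h_trend(50)) / 10
  sd_eH <- sqrt(max(sd_h_pool^2 - h_slope^2 * stats::var(age),
                    (0.5 * sd_h_pool)^2))
  e_H <- stats::rnorm(n, 0, sd_eH)
  height <- h_trend(age) + e_H

  ## latent residual vector
  Z <- matrix(stats::rnorm(n * 8), n, 8) %*% chol(calib$Lambda)
  colnames(Z) <- .latent_names()
  hr <- control$height_r
  beta_h <- function(nm, target_var) hr[[nm]] * sqrt(target_var) / sd_eH

  gauss_var <- function(nm) calib$Lambda[nm, nm]
  bmi <- trend_for("BMI")(age) + beta_h("bmi", get_pool("BMI", "sd")^2) * e_H +
    Z[, "bmi"]
  wc_true <- trend_for("WC")(age) + beta_h("wc", get_pool("WC", "sd")^2) * e_H +
    Z[, "wc"]
  hc_true <- trend_for("HC")(age) + beta_h("hc", get_pool("HC", "sd")^2) * e_H +
    Z[, "hc"]
  smt <- trend_for("SMT")(age) + beta_h("smt", get_pool("SMT", "sd")^2) * e_H +
    Z[, "smt"]
  rest_mean <- get_pool("TBV", "mean") - get_pool("TAT", "mean") -
    get_pool("SMT", "mean")
  rest_slope <- local({
    tb <- trend_for("TBV"); ta <- trend_for("TAT"); sm <- trend_for("SMT")
    (tb(60) - tb(50) - (ta(60) - ta(50)) - (sm(60) - sm(50))) / 10
  })
  rest <- rest_mean + rest_slope * (age - mean(age)) +
    beta_h("rest", gauss_var("rest")) * e_H + Z[, "rest"]
  smt <- pmax(smt, control$volume_floor)
  rest <- pmax(rest, control$volume_floor)

  ## adipose compartments: log-normal with multiplicative age/height trends
  gh <- control$vol_height_loggrad
  vol <- function(nm, lab) {
    lt <- trend_for(lab, log_scale = TRUE)
    s2 <- calib$Lambda[nm, nm]
    ## center so that E[volume | age] follows the fitted trend line
    exp(lt(age) - s2 / 2 - gh^2 * sd_eH^2 / 2 + gh * e_H + Z[, nm])
  }
  vat <- vol("vat", "VAT"); sat <- vol("sat", "SAT"); cat_ <- vol("cat", "CAT")

  if (truncate) {
    clamp <- function(x, v) pmin(pmax(x, get_pool(v, "min")), get_pool(v, "max"))
    bmi <- clamp(bmi, "BMI"); wc_true <- clamp(wc_true, "WC")
    hc_true <- clamp(hc_true, "HC"); smt <- clamp(smt, "SMT")
    vat <- clamp(vat, "VAT"); sat <- clamp(sat, "SAT"); cat_ <- clamp(cat_, "CAT")
  }
  tat <- vat + sat + cat_
  tbv <- tat + smt + rest

  waist <- triple_measure(wc_true, control$wc_noise_sd, control$n_readings)
  hip <- triple_measure(hc_true, control$wc_noise_sd, control$n_readings)
  weight <- bmi * (height / 100)^2

  gain <- stats::rnorm(n, control$weight_gain_mean, control$weight_gain_sd)
  weight_change <- gain + stats::rnorm(n, 0, control$recall_sd)
  n_miss <- round(control$weight_change_missing_rate * n)
  if (n_miss > 0) weight_change[sample.int(n, n_miss)] <- NA_real_

  tibble::tibble(
    center = center, sex = sex, age_band = age_band,
    age_baseline = age_baseline, age_substudy = age,
    height_cm = height, weight_kg = weight,
    bmi = weight / (height / 100)^2,
    waist_cm = waist, hip_cm = hip,
    tbv_l = tbv, tat_l = tat, vat_l = vat, sat_l = sat, cat_l = cat_,
    smt_l = smt, rest_l = rest,
    weight_change_kg = weight_change,
    mri_usable = TRUE
  )
}

#' Flag and drop unusable MRI datasets
#'
#' Emulates scan failures due to artifacts and image-quality problems: a
#' deterministic count `round(rate * n)` of randomly chosen records is
#' flagged unusable, and the usable subset is returned.
#'
#' @param cohort Cohort tibble.
#' @param mri_failure_rate Failure fraction in `[0, 1)`; the sub-study lost
#'   42 of 1,234 scans (about 3%).
#' @param seed Integer seed for the random identity of the failures.
#' @return The usable subset, with attribute `n_excluded`.
#' @export
apply_exclusions <- function(cohort, mri_failure_rate = 42 / 1234, seed = 1) {
  stopifnot(is.data.frame(cohort), mri_failure_rate >= 0)
  if (mri_failure_rate >= 1) stop("mri_failure_rate must be below 1")
  n <- nrow(cohort)
  k <- round(mri_failure_rate * n)
  out <- cohort
  if (k > 0) {
    bad <- withr::with_seed(seed, sample.int(n, k))
    out$mri_usable[bad] <- FALSE
  }
  usable <- out[out$mri_usable, ]
  attr(usable, "n_excluded") <- k
  usable
}
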