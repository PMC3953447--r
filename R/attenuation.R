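#' Simulate relative-risk attenuation from proxy exposure measurement
#'
#' Quantifies the implication of an imperfect calibration model: when an
#' anthropometry-based proxy replaces the true compartment volume in a risk
#' model, the estimated log relative risk per unit of the true exposure is
#' attenuated by a factor equal to the calibration R-squared.
#'
#' The simulation uses the classical errors-in-variables structure under
#' which that statement is exact in the limit: true exposure `T ~ N(0, 1)`,
#' proxy `X = T + e` with independent Gaussian error scaled so that
#' `cor(X, T)^2 = r2_target`, and an outcome with log risk `beta_true * T`
#' (log-linear count model, or logistic under a rare outcome). The naive
#' model regresses the outcome on `X` alone; since the proxy is analyzed on
#' the scale of the true exposure (per unit of `T`), the naive slope
#' converges to `beta_true * r2_target`. (Equivalently: the standardized
#' proxy `sqrt(r2) T + sqrt(1-r2) eps` rescaled by `1/sqrt(r2)`.)
#'
#' @param r2_target Calibration R-squared in `(0, 1]`; `0` is not
#'   identifiable and raises an error.
#' @param beta_true True log relative risk per unit (SD) of exposure.
#' @param n Number of simulated subjects (>= 1000).
#' @param outcome_model `"loglinear"` (Poisson counts) or `"logistic_rare"`.
#' @param seed Integer seed.
#' @param base_rate Marginal outcome rate (events per subject); a logistic
#'   model with event rate above 10% triggers a warning that the
#'   rare-disease approximation degrades.
#' @return An `attenuation_result` tibble row: `calibration_r2`,
#'   `beta_true`, `beta_naive`, `ratio` (naive/true), `mcse` (Monte-Carlo
#'   standard error of the ratio), `n`, `outcome_model`, `seed`.
#' @export
simulate_attenuation <- function(r2_target, beta_true = log(1.5), n = 1e5,
                                 outcome_model = c("loglinear", "logistic_rare"),
                                 seed = 1, base_rate = 0.05) {
  outcome_model <- match.arg(outcome_model)
  stopifnot(length(r2_target) == 1, n >= 1000)
  if (r2_target <= 0) stop("r2_target must be positive: a zero-R2 proxy carries no signal")
  if (r2_target > 1) stop("r2_target must be at most 1")
  res <- withr::with_seed(seed, {
    tru <- stats::rnorm(n)
    err_sd <- sqrt((1 - r2_target) / r2_target)
    x <- tru + stats::rnorm(n, 0, err_sd)
    if (outcome_model == "loglinear") {
      a <- log(base_rate) - beta_true^2 / 2
      y <- stats::rpois(n, exp(a + beta_true * tru))
      fit <- stats::glm.fit(cbind(1, x), y, family = stats::poisson())
    } else {
      a <- stats::qlogis(base_rate) - beta_true^2 / 2
      y <- stats::rbinom(n, 1, stats::plogis(a + beta_true * tru))
      if (mean(y) > 0.1) {
        warning("event rate ", round(mean(y), 3),
                " exceeds 10%: rare-disease approximation degrades")
      }
      fit <- stats::glm.fit(cbind(1, x), y, family = stats::binomial())
    }
    ## slope standard error from the IRLS working weights
    W <- fit$weights
    XtWX <- crossprod(cbind(1, x) * sqrt(W))
    se <- sqrt(diag(solve(XtWX)))[2]
    list(beta_naive = fit$coefficients[2], se = se)
  })
  tibble::new_tibble(
    tibble::tibble(
      calibration_r2 = r2_target,
      beta_true = beta_true,
      beta_naive = unname(res$beta_naive),
      se_naive = unname(res$se),
      ratio = if (beta_true != 0) unname(res$beta_naive) / beta_true else NA_real_,
      mcse = if (beta_true != 0) unname(res$se) / abs(beta_true) else NA_real_,
      n = n, outcome_model = outcome_model, seed = seed),
    class = "attenuation_result")
}

#' Expected attenuation factor from a fitted calibration model
#'
#' Returns the calibration model's R-squared as the predicted multiplicative
#' bias on a log relative risk estimated with the anthropometric proxy in
#' place of the true compartment volume, optionally alongside the
#' bootstrap-corrected variant.
#'
#' @param fit A `compartment_fit` from [fit_compartment_model()].
#' @param optimism Optional `optimism_result` from [optimism_bootstrap()]
#'   for the same model.
#' @return A tibble: `outcome`, `attenuation` (= apparent R-squared) and,
#'   if `optimism` is supplied, `attenuation_corrected`.
#' @export
attenuation_from_validation <- function(fit, optimism = NULL) {
  stopifnot(inherits(fit, "compartment_fit"))
  out <- tibble::tibble(outcome = fit$outcome, attenuation = fit$r_squared)
  if (!is.null(optimism)) {
    stopifnot(inherits(optimism, "optimism_result"))
    out$attenuation_corrected <- optimism$corrected
  }
  out
}
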