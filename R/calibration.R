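## Generator calibration.
##
## The cohort generator draws, per sex, a latent 8-dimensional residual
## vector: Gaussian components for BMI, WC, HC, SMT and the "rest" volume
## (bones, organs, liquids, air), and log-scale Gaussian components for the
## three adipose compartments VAT, SAT, CAT (exponentiated to strictly
## positive volumes). TAT and TBV are never sampled: TAT = VAT + SAT + CAT
## and TBV = TAT + SMT + rest hold exactly by construction.
##
## Because the aggregate rows (TAT, TBV) of a published correlation matrix
## are over-determined once the components must sum exactly, the latent
## covariance is chosen by penalized least squares so that the closed-form
## *induced* correlation matrix of the nine observed variables matches the
## published target as closely as possible. For a mixed Gaussian/log-normal
## latent vector all induced moments are available in closed form:
##   Cov(e^Zi, e^Zj) = mi mj (exp(Lam_ij) - 1),  Cov(e^Zi, Zk) = mi Lam_ik.

.latent_names <- function() c("bmi", "wc", "hc", "smt", "rest", "vat", "sat", "cat")
.latent_gauss <- function() 1:5
.latent_logn <- function() 6:8

## Raw-scale covariance of the nine observed variables implied by a latent
## covariance Lambda, log-normal component means mL = (VAT, SAT, CAT), and
## circumference measurement-noise variance (added to WC and HC).
.induced_observed_cov <- function(Lambda, mL, noise_var) {
  G <- .latent_gauss(); L <- .latent_logn()
  S <- matrix(0, 8, 8)
  S[G, G] <- Lambda[G, G]
  for (i in L) for (k in G) S[i, k] <- S[k, i] <- mL[i - 5L] * Lambda[i, k]
  for (i in L) for (j in L) S[i, j] <- mL[i - 5L] * mL[j - 5L] * (exp(Lambda[i, j]) - 1)
  labs <- analysis_variables()
  A <- matrix(0, 9, 8, dimnames = list(labs, .latent_names()))
  A["BMI", "bmi"] <- 1; A["WC", "wc"] <- 1; A["HC", "hc"] <- 1
  A["SMT", "smt"] <- 1
  A["VAT", "vat"] <- 1; A["SAT", "sat"] <- 1; A["CAT", "cat"] <- 1
  A["TAT", c("vat", "sat", "cat")] <- 1
  A["TBV", c("vat", "sat", "cat", "smt", "rest")] <- 1
  Sig <- A %*% S %*% t(A)
  Sig["WC", "WC"] <- Sig["WC", "WC"] + noise_var
  Sig["HC", "HC"] <- Sig["HC", "HC"] + noise_var
  Sig
}

.new_cohort_calibration <- function(Lambda, mL, noise_var, sex, target = NULL) {
  dimnames(Lambda) <- list(.latent_names(), .latent_names())
  obj <- structure(
    list(Lambda = Lambda, mL = mL, noise_var = noise_var, sex = sex,
         target = target),
    class = "cohort_calibration")
  obj
}

#' Adjusted-scale correlation matrix implied by a generator calibration
#'
#' The correlation matrix of the nine observed variables (on the residual,
#' age/height-adjusted scale) that cohorts drawn from this calibration
#' converge to as n grows, computed in closed form from the latent
#' covariance.
#'
#' @param calibration A `cohort_calibration` (see [calibrate_cohort_model()]
#'   or [reference_calibration()]).
#' @return A 9x9 correlation matrix labeled by [analysis_variables()].
#' @export
induced_correlation <- function(calibration) {
  stopifnot(inherits(calibration, "cohort_calibration"))
  stats::cov2cor(.induced_observed_cov(
    calibration$Lambda, calibration$mL, calibration$noise_var))
}

#' @export
print.cohort_calibration <- function(x, ...) {
  cat(sprintf("<cohort_calibration: sex = %s>\n", x$sex))
  if (!is.null(x$target)) {
    err <- max(abs(induced_correlation(x) - x$target))
    cat(sprintf("  max |induced - target| correlation error: %.4f\n", err))
  }
  invisible(x)
}

## Pooled (across age bands) mean / min / max / sd per variable for one sex.
## Means are weighted by per-band n; sds come from the range rule applied to
## the pooled range.
.pooled_marginals <- function(marginals, sex, rule = "range4") {
  m <- marginals[marginals$sex == sex, ]
  if (!nrow(m)) stop("no marginals for sex '", sex, "'")
  pooled <- m |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(
      mean = sum(.data$mean * .data$n) / sum(.data$n),
      min = min(.data$min), max = max(.data$max), .groups = "drop")
  derive_sd(pooled, rule = rule)
}

#' Calibrate the cohort generator to a target correlation matrix
#'
#' Fits the latent covariance of the generator's mixed Gaussian/log-normal
#' residual model so that the induced correlation matrix of the nine
#' observed variables (with TAT and TBV as exact sums of their components)
#' reproduces `corr_target`. The fit is a penalized least-squares problem
#' over a Cholesky parameterization of the latent correlation plus per-
#' component log standard deviations, weakly penalized toward the
#' range-rule spreads of `marginals`.
#'
#' Shipped calibrations for the published study targets are available via
#' [reference_calibration()]; this function is needed only for custom
#' targets.
#'
#' @param corr_target Target correlation matrix (a [corr_matrix] or plain
#'   matrix labeled by [analysis_variables()]). Eigenvalues below -0.05
#'   are considered non-repairable and raise an error; mild indefiniteness
#'   is repaired with [nearest_psd()].
#' @param marginals Marginal table as from [reference_marginals()].
#' @param sex `"male"` or `"female"` (selects rows of `marginals`).
#' @param noise_var Measurement-noise variance added to WC and HC
#'   (triple-measurement mean; default `0.3^2/3`).
#' @param penalty Weight of the log-sd penalty.
#' @param maxit,restarts BFGS iteration budget and number of warm restarts.
#' @return A `cohort_calibration` object.
#' @export
calibrate_cohort_model <- function(corr_target, marginals = reference_marginals(),
                                   sex, noise_var = 0.3^2 / 3,
                                   penalty = 3e-4, maxit = 5000, restarts = 6) {
  labs <- analysis_variables()
  R <- if (inherits(corr_target, "corr_matrix")) corr_target$r else corr_target
  stopifnot(is.matrix(R), all(labs %in% rownames(R)))
  R <- R[labs, labs]
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -0.05) {
    stop("correlation target is non-repairable (eigenvalue ", round(min(ev), 4),
         " < -0.05)")
  }
  R <- nearest_psd(R)
  pool <- .pooled_marginals(marginals, sex)
  missing_vars <- setdiff(labs, pool$variable)
  if (length(missing_vars)) {
    stop("marginal missing for: ", paste(missing_vars, collapse = ", "))
  }
  get_m <- function(v) pool$mean[pool$variable == v]
  get_s <- function(v) pool$sd[pool$variable == v]
  mL <- vapply(c("VAT", "SAT", "CAT"), get_m, numeric(1))
  rest_mean <- get_m("TBV") - get_m("TAT") - get_m("SMT")
  tgt_s <- c(get_s("BMI"), get_s("WC"), get_s("HC"), get_s("SMT"),
             rest_mean / 5,  # no published spread for the rest volume
             get_s("VAT"), get_s("SAT"), get_s("CAT"))
  G <- .latent_gauss(); L <- .latent_logn()
  par2lam <- function(p) {
    Lch <- diag(8); k <- 1
    for (i in 2:8) { Lch[i, 1:(i - 1)] <- p[k:(k + i - 2)]; k <- k + i - 1 }
    Lch <- Lch / sqrt(rowSums(Lch^2))
    C <- Lch %*% t(Lch)
    s <- exp(p[29:36])
    lat_sd <- numeric(8)
    lat_sd[G] <- s[G]
    lat_sd[L] <- sqrt(log(1 + (s[L] / mL)^2))
    C * tcrossprod(lat_sd)
  }
  objective <- function(p) {
    Sig <- .induced_observed_cov(par2lam(p), mL, noise_var)
    d <- (stats::cov2cor(Sig) - R)[upper.tri(R)]
    sum(d^2) + penalty * sum((p[29:36] - log(tgt_s))^2)
  }
  ## warm start: latent correlation = target correlation of the matching
  ## observed variables, spreads at the range-rule targets
  free <- .latent_names()
  map <- c(bmi = "BMI", wc = "WC", hc = "HC", smt = "SMT",
           vat = "VAT", sat = "SAT", cat = "CAT")
  C0 <- diag(8)
  for (i in 1:8) for (j in 1:8) {
    if (i != j && free[i] %in% names(map) && free[j] %in% names(map)) {
      C0[i, j] <- R[map[free[i]], map[free[j]]]
    }
  }
  C0 <- nearest_psd(C0, floor = 1e-4)
  L0 <- t(chol(C0)); p0 <- numeric(36); k <- 1
  for (i in 2:8) { p0[k:(k + i - 2)] <- L0[i, 1:(i - 1)] / L0[i, i]; k <- k + i - 1 }
  p0[29:36] <- log(tgt_s)
  fit <- stats::optim(p0, objective, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-15))
  for (it in seq_len(restarts)) {
    fit2 <- stats::optim(fit$par, objective, method = "BFGS",
                         control = list(maxit = maxit, reltol = 1e-15))
    done <- abs(fit$value - fit2$value) < 1e-12
    fit <- fit2
    if (done) break
  }
  .new_cohort_calibration(par2lam(fit$par), mL, noise_var, sex, target = R)
}

#' Shipped generator calibrations for the published study targets
#'
#' Latent covariances pre-fitted (with [calibrate_cohort_model()], see
#' `tools/calibrate-reference.R`) to the published per-sex correlation
#' matrices and marginals, so that [simulate_cohort()] with default targets
#' needs no optimization at run time.
#'
#' @param sex `"male"` or `"female"`.
#' @return A `cohort_calibration` object.
#' @export
reference_calibration <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  cc <- .calibration_constants[[sex]]
  .new_cohort_calibration(cc$Lambda, cc$mL, cc$noise_var, sex,
                          target = reference_correlations(sex)$r)
}
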