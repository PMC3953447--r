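#' Fit one MRI compartment on the anthropometric predictors
#'
#' Ordinary least squares of a (residual-adjusted) outcome on the
#' (residual-adjusted) predictors, returning the model R-squared, signed
#' partial correlations with Fisher-z confidence intervals, and variance
#' inflation factors.
#'
#' Partial correlations follow the type II sum-of-squares route: for
#' predictor j, `r_j^2 = (SSE_without_j - SSE_full) / SSE_without_j`, signed
#' by the full-model coefficient -- the standard equivalence between the
#' type II SSE reduction and the squared partial correlation. Confidence
#' intervals use the Fisher z transform with standard error
#' `1/sqrt(n - k - 3)`, `k` being the number of conditioned covariates.
#' `VIF_j = 1 / (1 - R^2)` of predictor j regressed on the others.
#'
#' @param data Data frame of adjusted variables (e.g. from
#'   [residual_adjust()]), one column per variable.
#' @param outcome Outcome column name.
#' @param predictors Predictor column names.
#' @param alpha Two-sided level for the partial-correlation intervals.
#' @param vif_tol Collinearity guard: error if any VIF exceeds this.
#' @return A `compartment_fit` object with components `outcome`,
#'   `predictors`, `n`, `coefficients`, `r_squared`, `partials` (tibble:
#'   `term`, `estimate`, `partial_r`, `ci_low`, `ci_high`, `vif`).
#' @export
fit_compartment_model <- function(data, outcome, predictors, alpha = 0.05,
                                  vif_tol = 1e8) {
  stopifnot(is.data.frame(data), length(predictors) >= 1)
  missing_cols <- setdiff(c(outcome, predictors), names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  }
  d <- data[c(outcome, predictors)]
  if (anyNA(d)) stop("missing values in model columns")
  n <- nrow(d)
  p <- length(predictors)
  if (n <= p + 1) stop("n = ", n, " too small for ", p, " predictors")
  y <- d[[outcome]]
  X <- as.matrix(d[predictors])
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  sse_full <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("outcome has zero variance")
  r2 <- 1 - sse_full / sst

  vif <- vapply(seq_len(p), function(j) {
    if (p == 1) return(1)
    fj <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ssej <- sum(fj$residuals^2)
    sstj <- sum((X[, j] - mean(X[, j]))^2)
    1 / max(1 - (1 - ssej / sstj), .Machine$double.eps)  # = sstj/ssej
  }, numeric(1))
  if (any(vif > vif_tol)) {
    j <- which.max(vif)
    stop("collinear predictors: VIF of '", predictors[j], "' is ",
         format(vif[j], digits = 3))
  }

  partial <- vapply(seq_len(p), function(j) {
    Xr <- cbind(1, X[, -j, drop = FALSE])
    sse_red <- sum(stats::lm.fit(Xr, y)$residuals^2)
    r_p <- sqrt(max((sse_red - sse_full) / sse_red, 0))
    sign(fit$coefficients[j + 1]) * r_p
  }, numeric(1))
  k <- p - 1  # covariates conditioned on for each partial correlation
  ci <- fisher_ci(pmin(pmax(partial, -1), 1), n = n, alpha = alpha, k = k)
  structure(
    list(outcome = outcome, predictors = predictors, n = n,
         coefficients = stats::setNames(fit$coefficients,
                                        c("(Intercept)", predictors)),
         r_squared = r2,
         partials = tibble::tibble(
           term = predictors,
           estimate = fit$coefficients[-1],
           partial_r = partial,
           ci_low = ci$ci_low, ci_high = ci$ci_high,
           vif = vif),
         alpha = alpha),
    class = "compartment_fit")
}

#' @export
print.compartment_fit <- function(x, ...) {
  cat(sprintf("<compartment_fit: %s ~ %s, n = %d, R2 = %.3f>\n",
              x$outcome, paste(x$predictors, collapse = " + "),
              x$n, x$r_squared))
  print(as.data.frame(x$partials), digits = 3)
  invisible(x)
}

#' @method tidy compartment_fit
#' @export
tidy.compartment_fit <- function(x, ...) {
  dplyr::mutate(x$partials, outcome = x$outcome, .before = 1)
}

#' @method glance compartment_fit
#' @export
glance.compartment_fit <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, r.squared = x$r_squared, n = x$n,
                 max_vif = max(x$partials$vif))
}

#' Cross-check sample partial correlations against the matrix route
#'
#' Computes the maximum absolute difference between the type II
#' sum-of-squares partial correlations of [fit_compartment_model()] and
#' [partial_corr_from_corr()] applied to the sample correlation matrix of
#' the same columns. The two routes are algebraically identical, so the
#' difference is numerical noise (~1e-12).
#'
#' @inheritParams fit_compartment_model
#' @return A tibble with one row per predictor: `term`, `partial_sample`,
#'   `partial_matrix`, `diff`.
#' @export
check_partial_agreement <- function(data, outcome, predictors) {
  fit <- fit_compartment_model(data, outcome, predictors)
  R <- stats::cor(as.matrix(data[c(outcome, predictors)]))
  pm <- vapply(predictors, function(pj)
    partial_corr_from_corr(R, outcome, pj), numeric(1))
  tibble::tibble(
    term = predictors,
    partial_sample = fit$partials$partial_r,
    partial_matrix = unname(pm),
    diff = abs(fit$partials$partial_r - unname(pm)))
}

#' Bootstrap optimism correction of R-squared
#'
#' Internal validation of the model fit: for each of `B` bootstrap
#' replicates, rows are resampled with replacement (within `by` strata if
#' given), the model is refit, and the optimism contribution is the
#' bootstrap-sample R-squared minus the R-squared of that bootstrap model
#' evaluated on the original sample. The optimism estimate is the mean of
#' these differences and the corrected R-squared is
#' `apparent - optimism`.
#'
#' @inheritParams fit_compartment_model
#' @param B Number of bootstrap replicates (study default 100).
#' @param seed Integer seed.
#' @param by Optional stratification column resampled within (e.g. sex).
#' @return An `optimism_result`: list with `apparent`, `optimism`,
#'   `corrected`, `B`, `seed`, `n`.
#' @export
optimism_bootstrap <- function(data, outcome, predictors, B = 100, seed = 1,
                               by = NULL) {
  stopifnot(B >= 1)
  fit0 <- fit_compartment_model(data, outcome, predictors)
  y <- data[[outcome]]
  X <- cbind(1, as.matrix(data[predictors]))
  sst0 <- sum((y - mean(y))^2)
  n <- nrow(data)
  strata <- if (is.null(by)) rep(1L, n) else as.integer(factor(data[[by]]))
  idx_by <- split(seq_len(n), strata)
  opt <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      for (try in 1:10) {
        idx <- unlist(lapply(idx_by, function(ii)
          ii[sample.int(length(ii), length(ii), replace = TRUE)]),
          use.names = FALSE)
        yb <- y[idx]
        if (stats::var(yb) > 0) break
        if (try == 10) stop("bootstrap outcome variance zero after 10 retries")
        warning("bootstrap sample with zero-variance outcome; resampling")
      }
      Xb <- X[idx, , drop = FALSE]
      fb <- stats::lm.fit(Xb, yb)
      r2_boot <- 1 - sum(fb$residuals^2) / sum((yb - mean(yb))^2)
      res_orig <- y - X %*% fb$coefficients
      r2_orig <- 1 - sum(res_orig^2) / sst0
      r2_boot - r2_orig
    }, numeric(1))
  })
  structure(
    list(apparent = fit0$r_squared, optimism = mean(opt),
         corrected = fit0$r_squared - mean(opt),
         B = B, seed = seed, n = n, outcome = outcome),
    class = "optimism_result")
}

#' @export
print.optimism_result <- function(x, ...) {
  cat(sprintf(
    "<optimism_result: %s, B = %d>\n  apparent R2 %.4f, optimism %.4f, corrected R2 %.4f\n",
    x$outcome, x$B, x$apparent, x$optimism, x$corrected))
  invisible(x)
}

#' @method glance optimism_result
#' @export
glance.optimism_result <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, apparent = x$apparent,
                 optimism = x$optimism, corrected = x$corrected,
                 B = x$B, n = x$n, seed = x$seed)
}

#' Gaussian sample with an exact target sample correlation matrix
#'
#' Draws a Gaussian matrix and linearly transforms it so that its *sample*
#' correlation matrix equals `R` exactly (not just in expectation). This
#' turns published correlation tables into deterministic worked examples:
#' any regression on such a sample reproduces the R-squared and partial
#' correlations implied by the table.
#'
#' @param n Number of rows (must exceed `ncol(R)`).
#' @param R Target correlation matrix (made PSD with [nearest_psd()] if
#'   needed); dimnames become column names.
#' @param seed Integer seed.
#' @return A tibble with `n` rows whose sample correlation matrix is `R` to
#'   machine precision.
#' @export
sample_with_exact_corr <- function(n, R, seed = 1) {
  stopifnot(is.matrix(R), n > ncol(R) + 1)
  R <- nearest_psd(R, floor = 1e-10)
  p <- ncol(R)
  X <- withr::with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  X <- scale(X, center = TRUE, scale = FALSE)
  ## whiten the realized sample covariance, then color with chol(R)
  S <- crossprod(X) / (n - 1)
  X <- X %*% solve(chol(S))
  X <- X %*% chol(R + diag(1e-12, p))
  colnames(X) <- colnames(R)
  tibble::as_tibble(X)
}
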