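#' Labeled correlation matrix with confidence intervals
#'
#' Container for a symmetric Pearson correlation matrix together with the
#' sample size it was estimated from and per-entry confidence bounds.
#'
#' @param r Symmetric numeric matrix with unit diagonal and dimnames.
#' @param n Sample size.
#' @param ci_low,ci_high Matrices of confidence bounds matching `r`, or
#'   `NULL` to compute them with [fisher_ci()].
#' @param alpha Two-sided significance level for the intervals.
#' @return An object of class `corr_matrix`: a list with elements `r`,
#'   `ci_low`, `ci_high`, `n`, `alpha`, `labels`.
#' @export
new_corr_matrix <- function(r, n, ci_low = NULL, ci_high = NULL, alpha = 0.05) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (max(abs(r - t(r))) > 1e-12) stop("correlation matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-12) stop("correlation matrix must have unit diagonal")
  if (is.null(ci_low) || is.null(ci_high)) {
    ci <- fisher_ci(r[upper.tri(r)], n = n, alpha = alpha)
    ci_low <- ci_high <- diag(nrow(r))
    ci_low[upper.tri(ci_low)] <- ci$ci_low
    ci_high[upper.tri(ci_high)] <- ci$ci_high
    ci_low <- ci_low + t(ci_low) - diag(diag(ci_low))
    ci_high <- ci_high + t(ci_high) - diag(diag(ci_high))
    dimnames(ci_low) <- dimnames(ci_high) <- dimnames(r)
  }
  structure(
    list(r = r, ci_low = ci_low, ci_high = ci_high,
         n = n, alpha = alpha, labels = rownames(r)),
    class = "corr_matrix"
  )
}

#' @export
print.corr_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<corr_matrix: %d variables, n = %d, %d%% CI>\n",
              length(x$labels), x$n, round(100 * (1 - x$alpha))))
  print(round(x$r, digits))
  invisible(x)
}

#' Tidy a correlation matrix into long form
#'
#' @param x A [corr_matrix].
#' @param ... Unused.
#' @return A tibble with one row per unordered variable pair: `var1`, `var2`,
#'   `r`, `ci_low`, `ci_high`, `n`.
#' @method tidy corr_matrix
#' @export
tidy.corr_matrix <- function(x, ...) {
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = x$labels[idx[, 1]],
    var2 = x$labels[idx[, 2]],
    r = x$r[idx],
    ci_low = x$ci_low[idx],
    ci_high = x$ci_high[idx],
    n = x$n
  )
}

#' Format a correlation matrix the way validation studies print them
#'
#' Lower-triangular table with cells `"r (lo-hi)"`, correlations rounded to
#' two decimals (round half up, matching the published tables).
#'
#' @param x A [corr_matrix].
#' @return A data frame of character cells, empty above the diagonal.
#' @export
format_corr_table <- function(x) {
  stopifnot(inherits(x, "corr_matrix"))
  p <- length(x$labels)
  out <- matrix("", p, p, dimnames = list(x$labels, x$labels))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i > j) {
      out[i, j] <- sprintf("%.2f (%.2f-%.2f)",
                           round_half_up(x$r[i, j], 2),
                           round_half_up(x$ci_low[i, j], 2),
                           round_half_up(x$ci_high[i, j], 2))
    }
  }
  as.data.frame(out)
}

## round half away from zero, as the published tables do (base round() is
## half-to-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' Transforms `r` to `z = atanh(r)`, uses standard error `1/sqrt(n - 3)`
#' (or `1/sqrt(n - k - 3)` for a partial correlation conditioning on `k`
#' covariates) with a normal quantile, and back-transforms. This reproduces
#' the intervals printed in the validation study's tables, e.g.
#' r = 0.80 at n = 598 gives (0.77, 0.83).
#'
#' @param r Correlation(s), `|r| < 1` (at `|r| = 1` a degenerate interval is
#'   returned with a warning).
#' @param n Sample size(s), must exceed `k + 3`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param k Number of conditioned covariates (0 for a marginal correlation).
#' @return A tibble with columns `r`, `n`, `ci_low`, `ci_high`, `alpha`.
#' @export
fisher_ci <- function(r, n, alpha = 0.05, k = 0) {
  stopifnot(alpha > 0, alpha < 1, all(abs(r) <= 1))
  if (any(n - k <= 3)) stop("n - k must exceed 3 for a Fisher-z interval")
  res <- tibble::tibble(r = r, n = n, ci_low = NA_real_, ci_high = NA_real_,
                        alpha = alpha)
  degen <- abs(r) == 1
  if (any(degen)) {
    warning("|r| = 1: returning degenerate interval [r, r]")
    res$ci_low[degen] <- r[degen]
    res$ci_high[degen] <- r[degen]
  }
  ok <- !degen
  if (any(ok)) {
    z <- atanh(r[ok])
    half <- stats::qnorm(1 - alpha / 2) / sqrt(n - k - 3)
    if (length(half) > 1) half <- half[ok]
    res$ci_low[ok] <- tanh(z - half)
    res$ci_high[ok] <- tanh(z + half)
  }
  res
}

#' Repair a correlation matrix to positive semidefiniteness
#'
#' Published correlation matrices rounded to two decimals can be slightly
#' indefinite. This clips eigenvalues at a small floor and re-normalizes to
#' unit diagonal. An already-PSD matrix is returned unchanged, so the
#' operation is idempotent.
#'
#' @param m Symmetric correlation matrix.
#' @param floor Eigenvalue floor (default `1e-8`).
#' @return Positive semidefinite correlation matrix with unit diagonal.
#' @export
nearest_psd <- function(m, floor = 1e-8) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8) stop("input matrix is not symmetric")
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -1e-12) return(m)  # already PSD (incl. a prior repair)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

#' Multiple R-squared from a correlation matrix
#'
#' For an outcome with predictor-correlation vector `c` and predictor
#' intercorrelation matrix `Rxx`, the proportion of outcome variance
#' explained by the joint linear model is `t(c) %*% solve(Rxx) %*% c`.
#' This lets published correlation tables be turned directly into the model
#' R-squared values a regression on the underlying data would give.
#'
#' @param c Numeric vector of outcome-predictor correlations.
#' @param Rxx Predictor intercorrelation matrix (same order as `c`).
#' @return R-squared, clipped to `[0, 1]`.
#' @export
multiple_r2_from_corr <- function(c, Rxx) {
  stopifnot(is.numeric(c), is.matrix(Rxx), length(c) == nrow(Rxx),
            nrow(Rxx) == ncol(Rxx))
  beta <- tryCatch(solve(Rxx, c),
                   error = function(e) stop(
                     "predictor correlation matrix is singular; ",
                     "consider nearest_psd() repair", call. = FALSE))
  min(max(sum(c * beta), 0), 1)
}

#' Partial correlation from a correlation matrix
#'
#' Correlation between `outcome` and `predictor` after removing the linear
#' influence of all other variables in the matrix. Two algebraically
#' equivalent routes are provided: the precision-matrix formula
#' `-P[i,j]/sqrt(P[i,i] P[j,j])`, and the R-squared-increment (type II
#' sum of squares) formula
#' `r_p^2 = (R2_full - R2_reduced) / (1 - R2_reduced)` signed by the
#' standardized full-model coefficient.
#'
#' @param R Full correlation matrix including outcome and all predictors.
#' @param outcome,predictor Labels (or indices) of the outcome and the
#'   predictor of interest; all remaining variables are conditioned on.
#' @param method `"precision"` (default) or `"increment"`.
#' @return Signed partial correlation.
#' @export
partial_corr_from_corr <- function(R, outcome, predictor,
                                   method = c("precision", "increment")) {
  method <- match.arg(method)
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (is.character(outcome)) outcome <- match(outcome, rownames(R))
  if (is.character(predictor)) predictor <- match(predictor, rownames(R))
  stopifnot(!is.na(outcome), !is.na(predictor), outcome != predictor)
  if (method == "precision") {
    P <- tryCatch(solve(R),
                  error = function(e) stop(
                    "correlation matrix is singular; consider nearest_psd()",
                    call. = FALSE))
    return(-P[outcome, predictor] / sqrt(P[outcome, outcome] * P[predictor, predictor]))
  }
  preds <- setdiff(seq_len(nrow(R)), outcome)
  others <- setdiff(preds, predictor)
  r2_full <- multiple_r2_from_corr(R[outcome, preds], R[preds, preds, drop = FALSE])
  r2_red <- if (length(others)) {
    multiple_r2_from_corr(R[outcome, others], R[others, others, drop = FALSE])
  } else 0
  if (1 - r2_red < 1e-12) {
    stop("reduced model already explains all variance (degenerate collinearity)")
  }
  beta <- solve(R[preds, preds, drop = FALSE], R[outcome, preds])
  b_j <- beta[match(predictor, preds)]
  sign(b_j) * sqrt(max((r2_full - r2_red) / (1 - r2_red), 0))
}

#' Pearson correlation matrix of a data frame
#'
#' Product-moment correlations between the given columns, with Fisher-z
#' confidence intervals on every entry.
#'
#' @param data A data frame.
#' @param vars Columns to correlate (character). Default: all numeric columns.
#' @param alpha Two-sided significance level for the intervals.
#' @return A [corr_matrix].
#' @export
pearson_matrix <- function(data, vars = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  missing <- setdiff(vars, names(data))
  if (length(missing)) stop("columns not found: ", paste(missing, collapse = ", "))
  m <- as.matrix(data[vars])
  if (anyNA(m)) stop("missing values in: ",
                     paste(vars[colSums(is.na(m)) > 0], collapse = ", "))
  n <- nrow(m)
  if (n < 4) stop("need at least 4 observations")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ", paste(vars[sds == 0], collapse = ", "))
  }
  r <- stats::cor(m)
  r[abs(r) > 1] <- sign(r[abs(r) > 1])  # guard tiny numeric overshoot
  new_corr_matrix(r, n = n, alpha = alpha)
}
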