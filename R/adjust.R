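#' Residual-method adjustment for age and height
#'
#' Removes the linear influence of a set of covariates (by default age and
#' height) from every requested variable by ordinary least squares: each
#' variable is regressed on an intercept plus the covariates, within each
#' stratum, and replaced by its residuals. Applied to predictors and
#' outcomes alike -- including BMI, which despite being a weight-for-height
#' index retains a small height correlation (around 0.2 in sex-stratified
#' cohorts) and is therefore adjusted like any other variable.
#'
#' Residuals are left at mean zero (no grand-mean add-back): every statistic
#' computed downstream here (correlation, R-squared, partial correlation) is
#' location-invariant.
#'
#' @param data A data frame (e.g. a cohort from [simulate_cohort()]).
#' @param variables Character vector of columns to adjust.
#' @param covariates Character vector of adjustment covariates
#'   (default sub-study age and height).
#' @param by Stratification column(s), default `"sex"`; use `NULL` for a
#'   pooled adjustment.
#' @param suffix Suffix appended to adjusted column names.
#' @return A tibble with the `by` columns, any `subject_id`, the covariates,
#'   and one `<variable><suffix>` column per adjusted variable. The fitted
#'   per-stratum regression coefficients are attached as attribute
#'   `"coefficients"` (a tibble), the covariate labels as `"covariates"`.
#' @export
residual_adjust <- function(data, variables,
                            covariates = c("age_substudy", "height_cm"),
                            by = "sex", suffix = "_adj") {
  stopifnot(is.data.frame(data), length(variables) > 0, length(covariates) > 0)
  needed <- c(variables, covariates, by)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  }
  for (v in c(variables, covariates)) {
    if (anyNA(data[[v]])) {
      stop("missing values in column '", v,
           "'; subset to complete cases before adjusting")
    }
  }
  strata <- if (is.null(by)) list(data) else split(data, data[by], drop = TRUE)
  adj_one <- function(d) {
    n <- nrow(d)
    if (n <= length(covariates) + 1) {
      stop("stratum with n = ", n, " is too small for ",
           length(covariates), " covariates")
    }
    X <- as.matrix(d[covariates])
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance covariate(s): ",
           paste(covariates[sds == 0], collapse = ", "))
    }
    qrX <- qr(cbind(`(Intercept)` = 1, X))
    Y <- as.matrix(d[variables])
    res <- qr.resid(qrX, Y)
    cf <- qr.coef(qrX, Y)
    keep <- intersect(c("subject_id", by, covariates), names(d))
    out <- tibble::as_tibble(d[keep])
    for (i in seq_along(variables)) {
      out[[paste0(variables[i], suffix)]] <- res[, i]
    }
    list(out = out, coef = cf)
  }
  fits <- lapply(strata, adj_one)
  out <- dplyr::bind_rows(lapply(fits, `[[`, "out"))
  coefs <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
    cf <- fits[[i]]$coef
    tibble::tibble(
      stratum = if (is.null(by)) "all" else names(fits)[i],
      variable = rep(colnames(cf), each = nrow(cf)),
      term = rep(rownames(cf), times = ncol(cf)),
      estimate = as.vector(cf)
    )
  }))
  attr(out, "covariates") <- covariates
  attr(out, "adjusted") <- paste0(variables, suffix)
  attr(out, "coefficients") <- coefs
  out
}
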