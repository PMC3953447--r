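#' Variable labels used throughout the package
#'
#' The nine analysis variables of the validation study: three anthropometric
#' indices (BMI, waist and hip circumference) and six MRI-derived body
#' compartment volumes (total body volume, total / subcutaneous / visceral /
#' coronary adipose tissue, skeletal muscle tissue).
#'
#' @return Character vector of the nine variable labels in table order.
#' @export
analysis_variables <- function() {
  c("BMI", "WC", "HC", "TBV", "TAT", "SAT", "VAT", "CAT", "SMT")
}

#' Map analysis labels to cohort CSV column names
#'
#' @return Named character vector mapping the labels of
#'   [analysis_variables()] to the column names of the cohort table schema
#'   (see [write_cohort()]).
#' @export
variable_columns <- function() {
  c(BMI = "bmi", WC = "waist_cm", HC = "hip_cm",
    TBV = "tbv_l", TAT = "tat_l", SAT = "sat_l",
    VAT = "vat_l", CAT = "cat_l", SMT = "smt_l")
}

## Published per-band marginals: mean (min, max) by sex and baseline age band.
## Bands are 10-year baseline age groups; at the time of the MRI sub-study
## (14-17 years after baseline) the corresponding attained-age groups overlap.
.reference_marginal_data <- function() {
  band <- c("35-44", "45-54", "55-64")
  row <- function(sex, variable, means, mins, maxs) {
    tibble::tibble(sex = sex, age_band = band, variable = variable,
                   mean = means, min = mins, max = maxs)
  }
  dplyr::bind_rows(
    row("male", "weight_kg", c(85.9, 85.5, 80.8), c(53.4, 55.6, 56.9), c(128.5, 125.9, 113.5)),
    row("male", "height_cm", c(177.6, 175.5, 173.2), c(160.0, 156.9, 155.2), c(197.5, 198.6, 191.1)),
    row("male", "BMI", c(27.2, 27.7, 26.9), c(18.6, 20.2, 19.1), c(40.8, 38.3, 38.9)),
    row("male", "WC",  c(99.2, 102.1, 101.1), c(73.3, 82.9, 74.3), c(130.3, 139.7, 130.6)),
    row("male", "HC",  c(101.8, 102.2, 101.1), c(85.5, 78.3, 86.9), c(123.0, 122.0, 127.1)),
    row("male", "TBV", c(73.3, 73.8, 70.1), c(48.2, 48.4, 50.4), c(110.0, 109.4, 98.5)),
    row("male", "TAT", c(20.7, 22.1, 20.9), c(4.9, 6.6, 5.2), c(45.5, 41.0, 42.5)),
    row("male", "VAT", c(4.8, 5.4, 5.5), c(0.48, 1.39, 0.24), c(11.5, 10.5, 10.5)),
    row("male", "SAT", c(15.5, 16.1, 14.9), c(3.9, 5.1, 4.9), c(36.6, 34.3, 34.9)),
    row("male", "CAT", c(0.42, 0.50, 0.51), c(0.07, 0.10, 0.10), c(0.96, 1.1, 1.5)),
    row("male", "SMT", c(25.4, 24.3, 22.6), c(16.6, 17.9, 16.4), c(35.4, 33.1, 29.5)),
    row("female", "weight_kg", c(71.0, 70.3, 68.6), c(44.4, 43.9, 42.1), c(116.2, 116.7, 107.0)),
    row("female", "height_cm", c(164.8, 162.5, 161.3), c(152.0, 142.5, 147.1), c(183.1, 180.2, 179.0)),
    row("female", "BMI", c(26.2, 26.6, 26.3), c(17.1, 18.0, 17.1), c(40.8, 42.1, 40.5)),
    row("female", "WC",  c(88.9, 91.3, 90.9), c(63.6, 66.2, 63.6), c(126.0, 128.3, 119.0)),
    row("female", "HC",  c(103.3, 104.2, 103.3), c(80.0, 84.8, 83.6), c(137.7, 141.2, 129.6)),
    row("female", "TBV", c(63.4, 63.4, 61.8), c(38.2, 37.5, 37.1), c(104.1, 110.6, 95.3)),
    row("female", "TAT", c(24.3, 25.1, 24.0), c(6.4, 9.4, 8.3), c(50.9, 62.7, 44.1)),
    row("female", "VAT", c(2.7, 3.0, 3.2), c(0.30, 0.47, 0.63), c(7.3, 7.5, 7.9)),
    row("female", "SAT", c(21.4, 21.7, 20.5), c(5.9, 8.2, 7.2), c(43.6, 56.4, 36.9)),
    row("female", "CAT", c(0.24, 0.31, 0.32), c(0.01, 0.04, 0.04), c(0.60, 1.2, 1.3)),
    row("female", "SMT", c(16.9, 16.2, 15.8), c(11.4, 11.2, 10.7), c(23.3, 22.4, 20.7))
  )
}

## Sub-study participant counts by sex and baseline age band.
.reference_band_n <- function(sex) {
  switch(sex, male = c(191, 194, 213), female = c(207, 196, 191),
         stop("unknown sex: ", sex))
}

#' Published marginal summaries of the validation sub-study
#'
#' Mean, minimum and maximum of each anthropometric and MRI variable by sex
#' and 10-year baseline age band, as reported for the 1,192 participants of
#' the German EPIC whole-body MRI sub-study, together with the number of
#' participants per cell.
#'
#' @param sex `"male"`, `"female"` or `"both"` (default).
#' @return A tibble with columns `sex`, `age_band`, `variable`, `mean`,
#'   `min`, `max`, `n`.
#' @export
reference_marginals <- function(sex = "both") {
  out <- .reference_marginal_data()
  out <- dplyr::left_join(
    out,
    dplyr::bind_rows(
      tibble::tibble(sex = "male", age_band = c("35-44", "45-54", "55-64"),
                     n = .reference_band_n("male")),
      tibble::tibble(sex = "female", age_band = c("35-44", "45-54", "55-64"),
                     n = .reference_band_n("female"))
    ),
    by = c("sex", "age_band")
  )
  if (!identical(sex, "both")) out <- out[out$sex == sex, ]
  out
}

## Published age/height-adjusted Pearson correlation matrices with 95% CIs,
## lower triangle as printed, by sex. n = 598 men, 594 women.
.reference_corr_entries <- function(sex) {
  ## each row: var1 var2 r lo hi
  men <- list(
    c("WC","BMI",.91,.89,.92),
    c("HC","BMI",.86,.83,.88), c("HC","WC",.82,.80,.85),
    c("TBV","BMI",.96,.96,.97), c("TBV","WC",.92,.90,.93), c("TBV","HC",.87,.85,.89),
    c("TAT","BMI",.89,.87,.91), c("TAT","WC",.91,.89,.92), c("TAT","HC",.84,.82,.86),
    c("TAT","TBV",.92,.91,.93),
    c("SAT","BMI",.87,.85,.89), c("SAT","WC",.87,.85,.89), c("SAT","HC",.85,.83,.87),
    c("SAT","TBV",.90,.88,.91), c("SAT","TAT",.97,.97,.98),
    c("VAT","BMI",.75,.72,.79), c("VAT","WC",.80,.77,.83), c("VAT","HC",.64,.59,.68),
    c("VAT","TBV",.78,.75,.81), c("VAT","TAT",.85,.82,.87), c("VAT","SAT",.70,.66,.74),
    c("CAT","BMI",.65,.60,.70), c("CAT","WC",.70,.65,.74), c("CAT","HC",.55,.50,.61),
    c("CAT","TBV",.67,.62,.71), c("CAT","TAT",.75,.72,.79), c("CAT","SAT",.65,.60,.69),
    c("CAT","VAT",.80,.76,.82),
    c("SMT","BMI",.63,.58,.67), c("SMT","WC",.49,.42,.54), c("SMT","HC",.46,.40,.52),
    c("SMT","TBV",.62,.57,.67), c("SMT","TAT",.33,.25,.40), c("SMT","SAT",.28,.20,.35),
    c("SMT","VAT",.38,.31,.44), c("SMT","CAT",.24,.16,.31)
  )
  women <- list(
    c("WC","BMI",.89,.88,.91),
    c("HC","BMI",.93,.92,.94), c("HC","WC",.85,.83,.87),
    c("TBV","BMI",.98,.98,.98), c("TBV","WC",.89,.88,.91), c("TBV","HC",.94,.93,.95),
    c("TAT","BMI",.95,.94,.96), c("TAT","WC",.88,.86,.90), c("TAT","HC",.94,.93,.95),
    c("TAT","TBV",.97,.96,.97),
    c("SAT","BMI",.94,.93,.95), c("SAT","WC",.85,.83,.87), c("SAT","HC",.94,.93,.95),
    c("SAT","TBV",.96,.95,.96), c("SAT","TAT",.99,.99,.99),
    c("VAT","BMI",.77,.73,.80), c("VAT","WC",.80,.77,.83), c("VAT","HC",.70,.65,.74),
    c("VAT","TBV",.78,.75,.81), c("VAT","TAT",.80,.77,.83), c("VAT","SAT",.71,.67,.75),
    c("CAT","BMI",.61,.56,.66), c("CAT","WC",.65,.60,.69), c("CAT","HC",.56,.50,.61),
    c("CAT","TBV",.62,.57,.67), c("CAT","TAT",.64,.59,.68), c("CAT","SAT",.57,.51,.62),
    c("CAT","VAT",.75,.72,.79),
    c("SMT","BMI",.69,.65,.73), c("SMT","WC",.63,.57,.67), c("SMT","HC",.56,.50,.61),
    c("SMT","TBV",.68,.63,.72), c("SMT","TAT",.53,.47,.58), c("SMT","SAT",.50,.44,.56),
    c("SMT","VAT",.50,.44,.56), c("SMT","CAT",.39,.32,.46)
  )
  switch(sex, male = men, female = women, stop("unknown sex: ", sex))
}

#' Published age/height-adjusted correlation matrices
#'
#' The sex-stratified Pearson correlation matrices (with 95% confidence
#' intervals) between the anthropometric indices and MRI compartment volumes,
#' all adjusted for age and height by the residual method, as published for
#' the validation sub-study (n = 598 men, n = 594 women).
#'
#' @param sex `"male"` or `"female"`.
#' @return A [corr_matrix] object.
#' @export
reference_correlations <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  labs <- analysis_variables()
  p <- length(labs)
  r <- diag(p); lo <- diag(p); hi <- diag(p)
  dimnames(r) <- dimnames(lo) <- dimnames(hi) <- list(labs, labs)
  for (e in .reference_corr_entries(sex)) {
    i <- e[1]; j <- e[2]
    v <- as.numeric(e[3:5])
    r[i, j] <- r[j, i] <- v[1]
    lo[i, j] <- lo[j, i] <- v[2]
    hi[i, j] <- hi[j, i] <- v[3]
  }
  n <- switch(sex, male = 598L, female = 594L)
  new_corr_matrix(r, n = n, ci_low = lo, ci_high = hi, alpha = 0.05)
}

#' Default sampling design of the validation sub-study
#'
#' A rectangular design: two centers, both sexes, equal numbers in each of
#' three 10-year baseline age bands. The default of 100 participants per
#' stratum gives 1,200 subjects, approximating the sub-study target of
#' roughly 300 men and 300 women per center.
#'
#' @param n_per_stratum Target count per (sex, center, age band) stratum.
#' @return A tibble with columns `sex`, `center`, `age_band`, `n_target`.
#' @export
cohort_design <- function(n_per_stratum = 100L) {
  stopifnot(length(n_per_stratum) == 1, n_per_stratum > 0)
  out <- tidyr::expand_grid(
    sex = c("male", "female"),
    center = c("A", "B"),
    age_band = c("35-44", "45-54", "55-64")
  )
  out$n_target <- as.integer(n_per_stratum)
  out
}
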