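## Cohort CSV schema, analysis pipeline, and configuration plumbing.

.cohort_schema <- function() {
  c("subject_id", "center", "sex", "age_baseline", "age_substudy",
    "height_cm", "weight_kg", "bmi", "waist_cm", "hip_cm",
    "tbv_l", "tat_l", "vat_l", "sat_l", "cat_l", "smt_l", "rest_l",
    "weight_change_kg", "mri_usable")
}

#' Validate a cohort table against the pipeline schema
#'
#' Checks column presence, types, volume additivity and the BMI identity,
#' and reports every offending column or row group in one error message.
#'
#' @param data Cohort data frame.
#' @param tol Numeric tolerance for the additivity and BMI identities.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(data, tol = 1e-6) {
  problems <- character()
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop("cohort is empty or not a data frame")
  }
  missing_cols <- setdiff(.cohort_schema(), names(data))
  if (length(missing_cols)) {
    problems <- c(problems,
                  paste("missing columns:", paste(missing_cols, collapse = ", ")))
  } else {
    num <- c("age_baseline", "age_substudy", "height_cm", "weight_kg", "bmi",
             "waist_cm", "hip_cm", "tbv_l", "tat_l", "vat_l", "sat_l",
             "cat_l", "smt_l", "rest_l")
    not_num <- num[!vapply(data[num], is.numeric, logical(1))]
    if (length(not_num)) {
      problems <- c(problems,
                    paste("non-numeric columns:", paste(not_num, collapse = ", ")))
    } else {
      vols <- c("tbv_l", "tat_l", "vat_l", "sat_l", "cat_l", "smt_l", "rest_l")
      neg <- vols[vapply(data[vols], function(x) any(x <= 0), logical(1))]
      if (length(neg)) {
        problems <- c(problems,
                      paste("non-positive volumes in:", paste(neg, collapse = ", ")))
      }
      d1 <- abs(data$tat_l - (data$vat_l + data$sat_l + data$cat_l))
      d2 <- abs(data$tbv_l - (data$tat_l + data$smt_l + data$rest_l))
      d3 <- abs(data$bmi - data$weight_kg / (data$height_cm / 100)^2)
      if (any(d1 > tol)) problems <- c(problems, "tat_l != vat_l + sat_l + cat_l")
      if (any(d2 > tol)) problems <- c(problems, "tbv_l != tat_l + smt_l + rest_l")
      if (any(d3 > tol)) problems <- c(problems, "bmi != weight_kg / height^2")
      if (anyDuplicated(data$subject_id)) {
        problems <- c(problems, "duplicate subject_id values")
      }
      bad_sex <- setdiff(unique(data$sex), c("male", "female"))
      if (length(bad_sex)) {
        problems <- c(problems, paste("unknown sex values:",
                                      paste(bad_sex, collapse = ", ")))
      }
    }
  }
  if (length(problems)) {
    stop("cohort schema violations:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(data)
}

#' Write / read a cohort CSV
#'
#' One header row, decimal point, UTF-8, empty field for missing
#' `weight_change_kg`. Provenance (seed and configuration digest, when
#' present as attributes) is embedded as `#`-prefixed comment lines before
#' the header; [read_cohort()] restores them as attributes.
#'
#' @param cohort Cohort tibble (e.g. from [simulate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  hdr <- character()
  if (!is.null(attr(cohort, "seed"))) {
    hdr <- c(hdr, paste0("# seed: ", attr(cohort, "seed")))
  }
  if (!is.null(attr(cohort, "config_digest"))) {
    hdr <- c(hdr, paste0("# config_digest: ", attr(cohort, "config_digest")))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(hdr)) writeLines(hdr, con)
  utils::write.csv(cohort[.cohort_schema()], con, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @param guess_max Passed to the CSV reader.
#' @return For `read_cohort()`: a validated cohort tibble.
#' @export
read_cohort <- function(path, guess_max = 10000) {
  first <- readLines(path, n = 20)
  hdr <- grep("^#", first, value = TRUE)
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         guess_max = guess_max)
  out$mri_usable <- as.logical(out$mri_usable)
  validate_cohort(out)
  seed_line <- grep("^# seed:", hdr, value = TRUE)
  if (length(seed_line)) {
    attr(out, "seed") <- as.integer(sub("^# seed:\\s*", "", seed_line[1]))
  }
  dig <- grep("^# config_digest:", hdr, value = TRUE)
  if (length(dig)) {
    attr(out, "config_digest") <- sub("^# config_digest:\\s*", "", dig[1])
  }
  out
}

#' Run the full validation analysis on a cohort
#'
#' Reproduces the study's analysis flow, separately for men and women:
#' residual-method adjustment of all nine variables for age and height,
#' the full adjusted correlation matrix with Fisher-z intervals, a
#' regression of each MRI compartment on BMI + WC + HC with type II partial
#' correlations and VIFs, and bootstrap optimism correction of each model
#' R-squared.
#'
#' @param cohort Cohort tibble conforming to the schema (only rows with
#'   `mri_usable` are analyzed).
#' @param sexes Sexes to analyze; sexes absent from the cohort are skipped
#'   with a warning.
#' @param covariates Adjustment covariates (default sub-study age and
#'   height).
#' @param outcomes MRI compartment labels to model.
#' @param predictors Anthropometric predictor labels.
#' @param B Bootstrap replicates for the optimism correction (0 to skip).
#' @param alpha Two-sided level for all intervals.
#' @param seed Seed for the bootstrap.
#' @return A `cohort_analysis` object: list with `correlations` (named list
#'   of [corr_matrix] per sex), `models` (tidy tibble: one row per sex x
#'   outcome x predictor with model R-squared, corrected R-squared, partial
#'   correlations, VIFs) and `meta`.
#' @export
analyze_cohort <- function(cohort, sexes = c("male", "female"),
                           covariates = c("age_substudy", "height_cm"),
                           outcomes = c("TBV", "TAT", "SAT", "VAT", "CAT", "SMT"),
                           predictors = c("BMI", "WC", "HC"),
                           B = 100, alpha = 0.05, seed = 1) {
  validate_cohort(cohort)
  cohort <- cohort[cohort$mri_usable, ]
  cols <- variable_columns()
  stopifnot(all(c(outcomes, predictors) %in% names(cols)))
  present <- intersect(sexes, unique(cohort$sex))
  absent <- setdiff(sexes, present)
  if (length(absent)) {
    warning("no rows for: ", paste(absent, collapse = ", "),
            "; reporting remaining sex(es) only")
  }
  if (!length(present)) stop("no rows for any requested sex")

  vars <- cols[c(predictors, outcomes)]
  adjusted <- residual_adjust(cohort, variables = unname(vars),
                              covariates = covariates, by = "sex")
  adj_names <- stats::setNames(paste0(unname(vars), "_adj"), names(vars))

  correlations <- list()
  model_rows <- list()
  for (s in present) {
    d <- adjusted[adjusted$sex == s, ]
    cm <- pearson_matrix(d, vars = unname(adj_names), alpha = alpha)
    ## relabel to analysis variable names
    dimnames(cm$r) <- dimnames(cm$ci_low) <- dimnames(cm$ci_high) <-
      list(names(adj_names), names(adj_names))
    cm$labels <- names(adj_names)
    correlations[[s]] <- cm
    for (o in outcomes) {
      fit <- fit_compartment_model(d, adj_names[[o]],
                                   unname(adj_names[predictors]), alpha = alpha)
      corrected <- NA_real_
      if (B > 0) {
        ob <- optimism_bootstrap(d, adj_names[[o]],
                                 unname(adj_names[predictors]), B = B,
                                 seed = seed)
        corrected <- ob$corrected
      }
      tt <- fit$partials
      tt$term <- predictors
      model_rows[[paste(s, o)]] <- dplyr::mutate(
        tt, sex = s, outcome = o, r_squared = fit$r_squared,
        r_squared_corrected = corrected, n = fit$n, .before = 1)
    }
  }
  structure(
    list(correlations = correlations,
         models = dplyr::bind_rows(model_rows),
         meta = list(covariates = covariates, predictors = predictors,
                     outcomes = outcomes, B = B, alpha = alpha, seed = seed,
                     n_by_sex = table(cohort$sex))),
    class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>\n  sexes:",
      paste(names(x$correlations), collapse = ", "), "\n")
  smry <- dplyr::distinct(x$models, .data$sex, .data$outcome,
                          .data$r_squared, .data$r_squared_corrected)
  print(as.data.frame(smry), digits = 3)
  invisible(x)
}

#' Round an analysis for report display
#'
#' Applies the presentation conventions of the study's tables and figures:
#' correlations and partial correlations to two decimals (half up), model
#' R-squared to whole percent.
#'
#' @param analysis A `cohort_analysis`.
#' @return Tibble of the model table with display columns added.
#' @export
report_models <- function(analysis) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  dplyr::mutate(
    analysis$models,
    r2_percent = round_half_up(100 * .data$r_squared),
    partial_display = sprintf("%.2f (%.2f-%.2f)",
                              round_half_up(.data$partial_r, 2),
                              round_half_up(.data$ci_low, 2),
                              round_half_up(.data$ci_high, 2)))
}

## ---- configuration-driven entry points (used by the CLI script) ----

#' Default pipeline configuration
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return Named list understood by [run_simulate()], [run_analyze()] and
#'   [run_attenuate()].
#' @export
default_config <- function(seed = 1, out_dir = ".") {
  list(seed = seed, out_dir = out_dir,
       n_per_stratum = 100, mri_failure_rate = 42 / 1234,
       sexes = c("male", "female"),
       covariates = c("age_substudy", "height_cm"),
       predictors = c("BMI", "WC", "HC"),
       outcomes = c("TBV", "TAT", "SAT", "VAT", "CAT", "SMT"),
       bootstrap_B = 100, alpha = 0.05,
       attenuation = list(r2 = 0.65, rr = 1.5, n = 1e5,
                          outcome_model = "loglinear"))
}

#' Read a YAML pipeline configuration
#'
#' Unknown keys raise an error; missing keys take defaults from
#' [default_config()].
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(base, cfg)
}

#' Configuration-driven pipeline stages
#'
#' Thin wrappers tying the stages together for scripted use: `run_simulate`
#' writes a cohort CSV, `run_analyze` writes the per-sex correlation tables
#' and the model summary table, `run_attenuate` writes a one-row attenuation
#' result. All outputs embed the seed and configuration digest.
#'
#' @param config Configuration list (see [default_config()]).
#' @param cohort_path For `run_analyze()`: cohort CSV to analyze.
#' @return Invisibly, the path(s) written.
#' @export
run_simulate <- function(config = default_config()) {
  cohort <- simulate_cohort(design = cohort_design(config$n_per_stratum),
                            seed = config$seed)
  cohort <- apply_exclusions(cohort, config$mri_failure_rate,
                             seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, "cohort.csv")
  write_cohort(cohort, path)
  message("wrote ", path, " (", nrow(cohort), " usable subjects)")
  invisible(path)
}

#' @rdname run_simulate
#' @export
run_analyze <- function(config = default_config(), cohort_path) {
  cohort <- read_cohort(cohort_path)
  res <- analyze_cohort(cohort, sexes = config$sexes,
                        covariates = config$covariates,
                        outcomes = config$outcomes,
                        predictors = config$predictors,
                        B = config$bootstrap_B, alpha = config$alpha,
                        seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (s in names(res$correlations)) {
    p <- file.path(config$out_dir, paste0("correlations_", s, ".csv"))
    utils::write.csv(format_corr_table(res$correlations[[s]]), p)
    paths <- c(paths, p)
  }
  p <- file.path(config$out_dir, "models.csv")
  utils::write.csv(report_models(res), p, row.names = FALSE)
  paths <- c(paths, p)
  message("wrote: ", paste(paths, collapse = ", "))
  invisible(paths)
}

#' @rdname run_simulate
#' @export
run_attenuate <- function(config = default_config()) {
  at <- config$attenuation
  res <- simulate_attenuation(r2_target = at$r2, beta_true = log(at$rr),
                              n = at$n, outcome_model = at$outcome_model,
                              seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(config$out_dir, "attenuation.csv")
  utils::write.csv(res, p, row.names = FALSE)
  message("wrote ", p)
  invisible(p)
}
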