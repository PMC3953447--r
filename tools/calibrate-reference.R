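#!/usr/bin/env Rscript
## Regenerates R/calib-constants.R: the latent covariances of the cohort
## generator fitted to the published per-sex correlation matrices and
## marginals. Deterministic (BFGS from a fixed warm start); takes a few
## minutes. Run from the package root:
##   Rscript tools/calibrate-reference.R
pkgload::load_all(".", quiet = TRUE)

fit <- lapply(c(male = "male", female = "female"), function(s) {
  cal <- calibrate_cohort_model(reference_correlations(s), sex = s)
  err <- max(abs(induced_correlation(cal) - reference_correlations(s)$r))
  message(sprintf("%s: max |induced - target| = %.5f", s, err))
  cal[c("Lambda", "mL", "noise_var")]
})

out <- file("R/calib-constants.R", "wt")
writeLines(c(
  "## Generated by tools/calibrate-reference.R -- do not edit by hand.",
  "## Latent covariances of the cohort generator fitted to the published",
  "## per-sex adjusted correlation matrices (see calibrate_cohort_model).",
  ".calibration_constants <-"), out)
dput(fit, out, control = "exact")
close(out)
message("wrote R/calib-constants.R")
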