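Package: anthroval
Title: Validation of Anthropometric Adiposity Indices Against Whole-Body
    MRI Body Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anthropometry-versus-imaging validation studies in
    epidemiological cohorts. Implements residual-method adjustment of
    predictors and outcomes for age and height, Pearson correlation
    matrices with Fisher-z confidence intervals, exact multiple-R-squared
    and signed partial correlations computed either from samples or
    directly from published correlation matrices, variance-inflation
    diagnostics, bootstrap optimism correction of R-squared, and a
    measurement-error simulation quantifying the attenuation of log
    relative-risk estimates when an anthropometry-based proxy replaces a
    true adipose-tissue volume. A calibrated synthetic-cohort generator
    reproduces the design, marginal distributions and age/height-adjusted
    correlation structure of the German EPIC whole-body MRI sub-study with
    exact adipose-compartment additivity, so the full pipeline can be
    exercised and tested without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
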