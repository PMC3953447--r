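## Shared fixtures, built in code.

## Small random cohort-like data frame with age/height structure, for
## adjustment and property tests (not a full schema cohort).
random_toy_cohort <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    age <- runif(n, 50, 80)
    height <- 175 - 0.2 * (age - 65) + rnorm(n, 0, 8)
    tibble::tibble(
      sex = rep(c("male", "female"), length.out = n),
      age_substudy = age,
      height_cm = height,
      y1 = 0.1 * age + 0.3 * height + rnorm(n),
      y2 = -0.05 * age + rnorm(n),
      y3 = rnorm(n)
    )
  })
}

## Random PSD correlation matrix of dimension p.
random_corr <- function(p, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(p * (p + 2)), p + 2, p)
    stats::cov2cor(crossprod(A))
  })
}

## Small simulated cohort shared across test files (generation is fast but
## not free; reuse one).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(cohort_design(25L), seed = 99)
    }
    cache
  }
})
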