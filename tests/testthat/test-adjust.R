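test_that("residuals match an independent normal-equations oracle", {
  ## 6-subject toy set with a hand-specified alternating error
  d <- tibble::tibble(
    sex = "male",
    height_cm = c(160, 165, 170, 175, 180, 185),
    age_substudy = c(40, 47, 50, 54, 61, 65),
    y = c(160, 165, 170, 175, 180, 185) + c(40, 47, 50, 54, 61, 65) +
      c(1, -1, 1, -1, 1, -1)
  )
  adj <- residual_adjust(d, "y", c("age_substudy", "height_cm"))
  ## brute-force normal equations
  X <- cbind(1, d$age_substudy, d$height_cm)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  oracle <- as.vector(d$y - X %*% beta)
  expect_equal(adj$y_adj, oracle, tolerance = 1e-10)
})

test_that("perfect fit gives zero residuals; orthogonal variable is centered", {
  d <- tibble::tibble(sex = "male",
                      height_cm = c(160, 165, 170, 175, 180),
                      age_substudy = 50 + 1:5,
                      y = 2 * c(160, 165, 170, 175, 180))
  adj <- residual_adjust(d, "y", "height_cm")
  expect_equal(adj$y_adj, rep(0, 5), tolerance = 1e-10)

  ## a variable exactly orthogonal in-sample to the centered covariates
  d2 <- tibble::tibble(sex = "male",
                       height_cm = c(-2, -1, 0, 1, 2) + 170,
                       age_substudy = c(1, -2, 0, 2, -1) + 60)
  v <- c(1, 1, -4, 1, 1)  # orthogonal to both centered covariates
  stopifnot(abs(sum(v * (d2$height_cm - mean(d2$height_cm)))) < 1e-12,
            abs(sum(v * (d2$age_substudy - mean(d2$age_substudy)))) < 1e-12)
  d2$y <- v + 10
  adj2 <- residual_adjust(d2, "y", c("age_substudy", "height_cm"))
  expect_equal(adj2$y_adj, v - mean(v), tolerance = 1e-10)
})

test_that("residual columns are mean-zero and orthogonal to covariates", {
  for (s in 1:10) {
    d <- random_toy_cohort(n = 80, seed = s)
    adj <- residual_adjust(d, c("y1", "y2", "y3"),
                           c("age_substudy", "height_cm"), by = "sex")
    for (grp in split(adj, adj$sex)) {
      for (v in c("y1_adj", "y2_adj", "y3_adj")) {
        r <- grp[[v]]
        expect_lt(abs(mean(r)), 1e-10 * max(sd(r), 1))
        for (cv in c("age_substudy", "height_cm")) {
          scale <- sd(r) * sd(grp[[cv]])
          expect_lt(abs(sum(r * (grp[[cv]] - mean(grp[[cv]])))) / nrow(grp),
                    1e-10 * max(scale, 1))
        }
      }
    }
  }
})

test_that("adjustment is idempotent", {
  d <- random_toy_cohort(n = 100, seed = 5)
  adj1 <- residual_adjust(d, c("y1", "y2"), c("age_substudy", "height_cm"))
  adj2 <- residual_adjust(adj1, c("y1_adj", "y2_adj"),
                          c("age_substudy", "height_cm"))
  expect_equal(adj2$y1_adj_adj, adj1$y1_adj, tolerance = 1e-10)
  expect_equal(adj2$y2_adj_adj, adj1$y2_adj, tolerance = 1e-10)
})

test_that("adjusted BMI is uncorrelated with height by construction", {
  cohort <- small_cohort()
  adj <- residual_adjust(cohort, "bmi", c("age_substudy", "height_cm"))
  for (grp in split(adj, adj$sex)) {
    expect_lt(abs(cor(grp$bmi_adj, grp$height_cm)), 1e-10)
  }
})

test_that("adjustment errors are informative", {
  d <- random_toy_cohort(n = 30)
  expect_error(residual_adjust(d, "nope", "height_cm"), "nope")
  d$y1[3] <- NA
  expect_error(residual_adjust(d, "y1", "height_cm"), "missing values.*y1")
  d$y1[3] <- 0; d$const <- 5
  expect_error(residual_adjust(d, "y2", "const"), "zero-variance")
  expect_error(residual_adjust(d[1:3, ], "y2", c("age_substudy", "height_cm")),
               "too small")
})

test_that("downstream correlations are invariant to residual location shifts", {
  d <- random_toy_cohort(n = 60, seed = 2)
  adj <- residual_adjust(d, c("y1", "y2"), "height_cm", by = NULL)
  r0 <- cor(adj$y1_adj, adj$y2_adj)
  expect_equal(cor(adj$y1_adj + 100, adj$y2_adj - 7), r0, tolerance = 1e-12)
})
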