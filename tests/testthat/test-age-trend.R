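test_that("cell aggregation averages per (age, sex) and drops missing values", {
  d <- data.frame(age = c(30, 30, 30, 40), sex = c(0, 0, 1, 1),
                  v = c(1, 3, 5, NA), peak = c(9, NA, 10, 11))
  cells <- aggregate_cells(d, "v")
  expect_equal(cells$value[cells$age == 30 & cells$sex == 0], 2)
  expect_equal(cells$n[cells$age == 30 & cells$sex == 0], 2)
  expect_equal(nrow(cells), 2)  # the all-NA cell disappears
  # a user without a peak reduces the peak cell count but not others
  pc <- aggregate_cells(d, "peak")
  expect_equal(pc$n[pc$age == 30 & pc$sex == 0], 1)
  expect_error(aggregate_cells(d, "missing_col"), "missing_col")
})

test_that("noiseless data reproduce generative coefficients exactly", {
  ages <- rep(c(20, 35, 50, 65, 80), each = 2)
  d <- expand.grid(age = ages, sex = c(0, 1))
  beta <- c(9.5, -0.02, 1e-4, 0.06, -0.005, 2e-5)
  d$v <- drop(trend_design(d$age, d$sex) %*% beta)
  fit <- suppressWarnings(fit_age_trend(d, "v"))  # perfect-fit lm warning
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("hand-solved linear case: slope 1/22 across ages 20-42-64(-86)", {
  d <- expand.grid(age = c(20, 42, 64, 86), sex = c(0, 1))
  d$v <- (d$age - 20) / 22 + 1  # exactly linear, identical for both sexes
  fit <- suppressWarnings(fit_age_trend(d, "v"))  # perfect-fit lm warning
  expect_equal(unname(coef(fit)["age_c"]), 1 / 22, tolerance = 1e-12)
  expect_equal(unname(coef(fit)["age_c2"]), 0, tolerance = 1e-12)
  expect_equal(unname(coef(fit)["sex"]), 0, tolerance = 1e-12)
})

test_that("cell-level WLS equals user-level OLS from the normal equations", {
  for (seed in c(1, 2)) {
    d <- simulated_cohort(300, c(0.47, 0.0002, -2e-5, 0.05, 5e-4, 1e-4),
                          noise_sd = 0.3, seed = seed)
    fit <- fit_age_trend(d, "value")
    oracle <- ols_oracle(d$age, d$sex, d$value)
    expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-8)

    # and the cell-level R^2 dominates the user-level R^2
    d$age_c <- d$age - 42; d$age_c2 <- d$age_c^2
    user_r2 <- summary(lm(value ~ age_c + age_c2 + sex + age_c:sex +
                            age_c2:sex, data = d))$r.squared
    expect_gte(fit$r_squared, user_r2)
  }
})

test_that("the intercept is the prediction for a male at the centring age", {
  d <- simulated_cohort(250, c(1, 0.001, 0, 0.1, 0, 0), noise_sd = 0.2, seed = 3)
  fit <- fit_age_trend(d, "value")
  expect_equal(unname(predict(fit, data.frame(age = 42, sex = 0))),
               unname(coef(fit)["(Intercept)"]))
  # and methods behave like a model object
  expect_length(residuals(fit), fit$n_cells)
  expect_equal(length(fitted(fit)), fit$n_cells)
  expect_output(print(fit), "Age-trend WLS")
  expect_output(print(summary(fit)), "R\\^2")
})

test_that("stars are a pure function of p at the four thresholds", {
  p <- c(0.2, 0.049, 0.0099, 0.00099, 9e-5, NA)
  expect_equal(significance_stars(p), c("", "*", "**", "***", "****", ""))
})

test_that("a strong sex interaction triggers per-sex refits that recover it", {
  beta <- c(9.54, -0.019, 0, 0.06, -0.009, 0)  # female slope -0.028
  d <- simulated_cohort(3000, beta, noise_sd = 0.5, seed = 7)
  fit <- fit_age_trend(d, "value")
  expect_true(fit$refit_triggered)
  m <- fit$sex_fits$male; f <- fit$sex_fits$female
  m_slope <- m$estimate[m$term == "age_c"]
  f_slope <- f$estimate[f$term == "age_c"]
  m_se <- m$se[m$term == "age_c"]; f_se <- f$se[f$term == "age_c"]
  expect_lt(abs(m_slope - (-0.019)), 3 * m_se)
  expect_lt(abs(f_slope - (-0.028)), 3 * f_se)
})

test_that("refit trigger size is near its nominal level on null data", {
  beta <- c(1, 0.001, 0, 0.05, 0, 0)  # no interaction
  fired <- vapply(1:150, function(i) {
    d <- simulated_cohort(250, beta, noise_sd = 0.3, seed = 100 + i)
    fit_age_trend(d, "value")$refit_triggered
  }, logical(1))
  rate <- mean(fired)
  # 150 replicates: allow ~3 binomial SEs around 0.05
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.11)
  # boundary: joint p just above alpha must not trigger
  d <- simulated_cohort(400, beta, noise_sd = 0.3, seed = 999)
  fit <- fit_age_trend(d, "value", refit_alpha = 0.999 *
                         fit_age_trend(d, "value")$interaction_p[["joint"]])
  expect_false(fit$refit_triggered)
})

test_that("degenerate designs are refused", {
  d <- data.frame(age = c(30, 40, 50), sex = 0, v = 1:3)
  expect_error(fit_age_trend(d, "v"), "cells")
  expect_error(aggregate_cells(data.frame(age = numeric(), sex = numeric(),
                                          v = numeric()), "v"), "usable")
})

test_that("omnibus gate reports interactions up to the four-way term", {
  set.seed(12)
  d <- expand.grid(age = seq(20, 80, by = 4), sex = c(0, 1),
                   task = c("CAL", "NFB"),
                   channel = c("TP9", "AF7", "AF8", "TP10"))
  d$v <- rnorm(nrow(d))
  an <- fit_omnibus(d, "v")
  expect_true("age_c:sex:task:channel" %in% rownames(an))
})
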