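test_that("zscore matches hand arithmetic and is idempotent", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(91)
  z <- zscore(rnorm(20, 5, 3))
  expect_equal(zscore(z), z, tolerance = 1e-12)
  expect_error(zscore(rep(2, 10)), "constant|variance")
  expect_error(zscore(1), ">= 2")
})

test_that("tiny-n fits match the brute-force Efron partial likelihood", {
  # two-group pattern with tied event times (finite interior MLE)
  dat <- data.frame(time_years = c(1, 2, 2, 3, 3, 4, 5, 6),
                    event = c(1, 1, 1, 0, 1, 1, 1, 0),
                    x = c(0, 1, 0, 0, 1, 1, 0, 1))
  fit <- fit_cox(dat, "x", covariates = character(0), zscore_factor = FALSE)
  ref <- oracle_efron_mle(dat$time_years, dat$event, dat$x)
  b <- fit$coefficients$coef[fit$coefficients$term == "x"]
  expect_equal(b, ref$beta, tolerance = 1e-6)
  expect_equal(fit$lr_stat, ref$lr, tolerance = 1e-6)

  # a second, non-grouped fixture with ties
  set.seed(93)
  dat2 <- data.frame(time_years = c(2, 2, 2, 5, 5, 7, 8, 9),
                     event = c(1, 1, 0, 1, 1, 0, 1, 1),
                     x = rnorm(8))
  fit2 <- fit_cox(dat2, "x", covariates = character(0), zscore_factor = FALSE)
  ref2 <- oracle_efron_mle(dat2$time_years, dat2$event, dat2$x)
  expect_equal(fit2$coefficients$coef[fit2$coefficients$term == "x"],
               ref2$beta, tolerance = 1e-6)
  expect_equal(fit2$lr_stat, ref2$lr, tolerance = 1e-6)
})

test_that("the brain-factor hazard ratio is invariant to time rescaling", {
  rec <- simulate_survival_records(150, c(bf = 0.6), baseline_hazard = 0.1,
                                   censor_time = 8, seed = 7)
  fit_y <- fit_cox(rec, "bf")
  rec$time_years <- rec$time_years * 12  # months
  fit_m <- fit_cox(rec, "bf")
  hr_y <- fit_y$coefficients$hr[fit_y$coefficients$term == "bf"]
  hr_m <- fit_m$coefficients$hr[fit_m$coefficients$term == "bf"]
  expect_equal(hr_y, hr_m, tolerance = 1e-8)
  expect_equal(fit_y$lr_stat, fit_m$lr_stat, tolerance = 1e-8)
})

test_that("the likelihood-ratio statistic is nonnegative and HR = exp(coef)", {
  rec <- simulate_survival_records(120, c(bf = 1.0), baseline_hazard = 0.08,
                                   censor_time = 8, seed = 11)
  fit <- fit_cox(rec, "bf")
  expect_gte(fit$lr_stat, 0)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$coef))
  expect_true(all(fit$coefficients$hr_lo <= fit$coefficients$hr &
                  fit$coefficients$hr <= fit$coefficients$hr_hi))
})

test_that("collinear brain factors are flagged, not silently fitted", {
  rec <- simulate_survival_records(80, c(bf = 0.6), baseline_hazard = 0.1,
                                   censor_time = 8, seed = 13)
  rec$bf_copy <- rec$bf
  expect_error(fit_cox(rec, "bf", covariates = c("age", "bf_copy"),
                       zscore_factor = FALSE),
               "collinear")
})

test_that("degenerate survival inputs produce statistics errors", {
  rec <- simulate_survival_records(40, c(bf = 0.6), baseline_hazard = 0.1,
                                   censor_time = 8, seed = 17)
  rec$event <- 0L
  expect_error(fit_cox(rec, "bf"), "no conversion events")
  rec2 <- simulate_survival_records(40, c(bf = 0.6), 0.1, 8, seed = 17)
  rec2$bf[3] <- NA
  expect_error(fit_cox(rec2, "bf"), "missing")
  # perfect separation: factor = event indicator
  rec3 <- simulate_survival_records(40, c(bf = 1), 0.15, 8, seed = 19)
  rec3$sep <- ifelse(rec3$event == 1, 100, -100) + rnorm(40, sd = 1e-4)
  expect_error(fit_cox(rec3, "sep", covariates = character(0),
                       zscore_factor = FALSE),
               "converge|separation")
})

test_that("log-hazard-ratio estimates recover the truth as n grows", {
  bias <- vapply(c(100, 500), function(n) {
    rec <- simulate_survival_records(n, c(bf = 0.5), baseline_hazard = 0.2,
                                     censor_time = 50, seed = 23)
    fit <- fit_cox(rec, "bf", covariates = character(0), zscore_factor = FALSE)
    abs(fit$coefficients$coef[fit$coefficients$term == "bf"] - log(0.5))
  }, numeric(1))
  expect_lt(bias[2], 0.15)
  rec <- simulate_survival_records(500, c(bf = 0.5), 0.2, 50, seed = 23)
  fit <- fit_cox(rec, "bf", covariates = character(0), zscore_factor = FALSE)
  hr <- fit$coefficients$hr[fit$coefficients$term == "bf"]
  expect_gt(hr, 0.4); expect_lt(hr, 0.6)
})
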