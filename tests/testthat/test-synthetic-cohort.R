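small_spec <- function(seed = 7L, ...) {
  cohort_spec(n_subjects = 12L, grid_shape = c(10L, 10L, 10L),
              planted_region = list(center = c(5.5, 5.5, 5.5), radii = c(3, 3, 3)),
              seed = seed, ...)
}

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(small_spec())
  b <- generate_cohort(small_spec())
  expect_identical(a$subject_table, b$subject_table)
  expect_identical(lapply(a$maps, `[[`, "values"),
                   lapply(b$maps, `[[`, "values"))
  c2 <- generate_cohort(small_spec(seed = 8L))
  expect_false(identical(a$subject_table$fornix_fa, c2$subject_table$fornix_fa))
})

test_that("no signal and no noise yields constant background maps", {
  coh <- generate_cohort(small_spec(effect_beta = 0, noise_sigma = 0))
  for (i in seq_along(coh$maps)) {
    dt <- coh$subject_table$delta_t_years[i]
    expect_equal(coh$maps[[i]]$values,
                 array(coh$spec$mu_bg * dt / 2, coh$spec$grid_shape))
  }
})

test_that("OLS on the normalized planted-region mean recovers effect_beta", {
  beta <- 0.05
  coh <- generate_cohort(cohort_spec(n_subjects = 60L, effect_beta = beta,
                                     noise_sigma = 0.01, seed = 13L))
  maps <- lapply(coh$maps, normalize_to_two_years)
  y <- vapply(maps, function(m) roi_mean(m, coh$truth$region_mask), numeric(1))
  z <- coh$truth$predictor_z
  # closed-form simple OLS, the generating equation's own estimator
  zc <- z - mean(z)
  slope <- sum(zc * y) / sum(zc^2)
  resid <- y - mean(y) - slope * zc
  se <- sqrt(sum(resid^2) / (length(y) - 2) / sum(zc^2))
  expect_lt(abs(slope - beta), 3 * se)
})

test_that("null cohorts carry no predictor association in the planted region", {
  cors <- vapply(1:200, function(i) {
    sp <- cohort_spec(n_subjects = 20L, grid_shape = c(8L, 8L, 8L),
                      planted_region = list(center = c(4.5, 4.5, 4.5),
                                            radii = c(2, 2, 2)),
                      seed = i)
    coh <- generate_null_cohort(sp)
    y <- vapply(lapply(coh$maps, normalize_to_two_years),
                function(m) roi_mean(m, coh$truth$region_mask), numeric(1))
    cor(y, coh$truth$predictor_z)
  }, numeric(1))
  # sample correlation at n = 20 has SD ~ 1/sqrt(n); the mean of 200
  # independent replicates must sit within 3 SE of zero
  expect_lt(abs(mean(cors)), 3 * (1 / sqrt(20)) / sqrt(200))
  expect_true(all(generate_null_cohort(small_spec())$truth$hr_per_z == 1))
})

test_that("event rate is monotone in the baseline hazard", {
  rates <- vapply(c(0.02, 0.1, 0.5), function(h) {
    coh <- generate_cohort(small_spec(baseline_hazard = h))
    mean(coh$subject_table$event)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("invalid specs fail with the offending field named", {
  expect_error(cohort_spec(n_subjects = 3), "n_subjects")
  expect_error(cohort_spec(planted_region = list(center = c(2, 2, 2),
                                                 radii = c(9, 9, 9))),
               "planted_region")
  expect_error(cohort_spec(planted_region = list(center = c(10, 10, 10),
                                                 radii = c(0, 1, 1))),
               "planted_region")
  expect_error(cohort_spec(delta_t_range = c(0, 2)), "delta_t_range")
  expect_error(cohort_spec(hr_per_z = c(fornix_fa = -0.5)), "hr_per_z")
  expect_error(cohort_spec(predictor_sd = 0), "predictor_sd")
})

test_that("native maps scale with the interscan interval", {
  coh <- generate_cohort(small_spec(effect_beta = 0, noise_sigma = 0))
  # after normalization all subjects agree exactly (pure background)
  norm <- lapply(coh$maps, normalize_to_two_years)
  for (m in norm)
    expect_equal(m$values, array(coh$spec$mu_bg, coh$spec$grid_shape))
})

test_that("survival-only simulation respects hazard ratios directionally", {
  rec <- simulate_survival_records(2000, c(f = 0.4), baseline_hazard = 0.1,
                                   censor_time = 8, seed = 5)
  # protective factor: converters should have lower Z on average
  expect_lt(mean(rec$f[rec$event == 1]), mean(rec$f[rec$event == 0]))
  rec2 <- simulate_survival_records(2000, c(f = 0.4), baseline_hazard = 0.1,
                                    censor_time = 8, seed = 5)
  expect_identical(rec, rec2)
})
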