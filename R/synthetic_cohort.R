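#' Specification for a synthetic longitudinal cohort
#'
#' Collects every parameter of the synthetic cohort generator: grid geometry,
#' the planted ellipsoidal effect region, the subject-level predictor
#' (a fornix-FA-like baseline measurement), noise and smoothing, interscan
#' intervals, the conversion hazard model, and demographic distributions.
#' Defaults emulate a community-recruited elderly normal cohort: mean age in
#' the early seventies, ~11.5 years of education, majority female, two
#' ethnicity strata, interscan intervals of 1-3.6 years, and a conversion
#' process calibrated to roughly 12 events per 68 subjects over 6 years.
#'
#' @param n_subjects number of subjects (>= 4).
#' @param grid_shape 3 positive integers, image grid in voxels.
#' @param voxel_size_mm 3 positive reals, voxel spacing in mm.
#' @param seed integer seed; all randomness flows from it.
#' @param effect_beta slope of the planted association, in 2-year log-Jacobian
#'   units per unit predictor Z-score inside the planted region. Positive
#'   values reproduce the expected direction (higher baseline FA, less
#'   tissue loss); the default 0.01 is about one smoothed-noise SD per Z.
#' @param planted_region list with `center` and `radii` (voxels): an
#'   ellipsoid that must fit inside the grid.
#' @param noise_sigma SD of voxelwise log-Jacobian noise before smoothing.
#' @param smooth_fwhm_mm Gaussian FWHM (mm) applied to the noise field.
#' @param mu_bg background mean 2-year log-Jacobian (mild global tissue loss
#'   by default).
#' @param delta_t_range interval (years) from which interscan intervals are
#'   drawn uniformly; lower bound must be > 0.
#' @param predictor_mean,predictor_sd distribution of the simulated baseline
#'   predictor (fornix-FA-like, so ~0.50 +/- 0.06).
#' @param hr_per_z named numeric: true hazard ratio per Z-unit for each brain
#'   factor entering the conversion model. Factors other than `fornix_fa`
#'   get independent standard-normal Z columns in the subject table.
#' @param baseline_hazard baseline conversion hazard per year.
#' @param censor_time administrative censoring time (years).
#' @param demographics list with `age_mean`, `age_sd`, `education_mean`,
#'   `education_sd`, `p_female`, and `ethnicity` (named probability vector
#'   with >= 2 levels).
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [generate_null_cohort()]
#' @export
cohort_spec <- function(n_subjects = 60L,
                        grid_shape = c(20L, 20L, 20L),
                        voxel_size_mm = c(2, 2, 2),
                        seed = 1L,
                        effect_beta = 0.01,
                        planted_region = list(center = (grid_shape + 1) / 2,
                                              radii = c(4, 4, 4)),
                        noise_sigma = 0.05,
                        smooth_fwhm_mm = 4,
                        mu_bg = -0.01,
                        delta_t_range = c(1, 3.6),
                        predictor_mean = 0.50,
                        predictor_sd = 0.06,
                        hr_per_z = c(fornix_fa = 0.38),
                        baseline_hazard = 0.035,
                        censor_time = 6,
                        demographics = list(age_mean = 72.9, age_sd = 7.0,
                                            education_mean = 11.5,
                                            education_sd = 4.8,
                                            p_female = 0.74,
                                            ethnicity = c(hispanic = 0.56,
                                                          white = 0.44))) {
  spec <- list(n_subjects = as.integer(n_subjects),
               grid_shape = as.integer(grid_shape),
               voxel_size_mm = as.numeric(voxel_size_mm),
               seed = as.integer(seed),
               effect_beta = as.numeric(effect_beta),
               planted_region = planted_region,
               noise_sigma = as.numeric(noise_sigma),
               smooth_fwhm_mm = as.numeric(smooth_fwhm_mm),
               mu_bg = as.numeric(mu_bg),
               delta_t_range = as.numeric(delta_t_range),
               predictor_mean = as.numeric(predictor_mean),
               predictor_sd = as.numeric(predictor_sd),
               hr_per_z = hr_per_z,
               baseline_hazard = as.numeric(baseline_hazard),
               censor_time = as.numeric(censor_time),
               demographics = demographics)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, why)
    stop(sprintf("invalid cohort spec: `%s` %s", field, why), call. = FALSE)
  if (is.na(spec$n_subjects) || spec$n_subjects < 4L)
    fail("n_subjects", "must be >= 4")
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 2L))
    fail("grid_shape", "must be 3 integers >= 2")
  if (length(spec$voxel_size_mm) != 3L || any(spec$voxel_size_mm <= 0))
    fail("voxel_size_mm", "must be 3 positive reals")
  pr <- spec$planted_region
  if (!is.list(pr) || is.null(pr$center) || is.null(pr$radii))
    fail("planted_region", "must have `center` and `radii`")
  if (any(pr$radii <= 0)) fail("planted_region", "radii must be > 0")
  if (any(pr$center - pr$radii < 1) || any(pr$center + pr$radii > spec$grid_shape))
    fail("planted_region", "must fit inside grid_shape")
  if (spec$noise_sigma < 0) fail("noise_sigma", "must be >= 0")
  if (spec$smooth_fwhm_mm < 0) fail("smooth_fwhm_mm", "must be >= 0")
  if (length(spec$delta_t_range) != 2L || spec$delta_t_range[1] <= 0 ||
      diff(spec$delta_t_range) < 0)
    fail("delta_t_range", "must be an interval with lower bound > 0")
  if (spec$predictor_sd <= 0) fail("predictor_sd", "must be > 0")
  if (length(spec$hr_per_z) < 1L || is.null(names(spec$hr_per_z)) ||
      any(!nzchar(names(spec$hr_per_z))))
    fail("hr_per_z", "must be a named vector")
  if (any(spec$hr_per_z <= 0)) fail("hr_per_z", "values must be > 0")
  if (spec$baseline_hazard <= 0) fail("baseline_hazard", "must be > 0")
  if (spec$censor_time <= 0) fail("censor_time", "must be > 0")
  dg <- spec$demographics
  if (length(dg$ethnicity) < 2L || is.null(names(dg$ethnicity)))
    fail("demographics", "ethnicity needs >= 2 named levels")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: n = %d, grid %s (%s mm), seed %d\n",
              x$n_subjects, paste(x$grid_shape, collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"), x$seed))
  cat(sprintf("  planted effect %.4g per Z in ellipsoid r = (%s) voxels\n",
              x$effect_beta, paste(format(x$planted_region$radii), collapse = ", ")))
  cat(sprintf("  noise sigma %.3g, smoothing FWHM %.3g mm, background %.3g\n",
              x$noise_sigma, x$smooth_fwhm_mm, x$mu_bg))
  cat(sprintf("  hazard ratios per Z: %s; baseline %.3g/yr, censor %.3g yr\n",
              paste(sprintf("%s=%.3g", names(x$hr_per_z), x$hr_per_z),
                    collapse = ", "),
              x$baseline_hazard, x$censor_time))
  invisible(x)
}

#' Ellipsoidal binary mask
#'
#' @param grid_shape 3 positive integers (voxels).
#' @param center ellipsoid center in voxel coordinates (1-based).
#' @param radii semi-axes in voxels.
#' @return Logical 3-D array, `TRUE` inside the ellipsoid.
#' @export
ellipsoid_mask <- function(grid_shape, center, radii) {
  grid_shape <- as.integer(grid_shape)
  ix <- (seq_len(grid_shape[1]) - center[1]) / radii[1]
  iy <- (seq_len(grid_shape[2]) - center[2]) / radii[2]
  iz <- (seq_len(grid_shape[3]) - center[3]) / radii[3]
  d2 <- outer(outer(ix^2, iy^2, `+`), iz^2, `+`)
  d2 <= 1
}

# Truncated, renormalized 1-D Gaussian kernel for a given FWHM (in voxels).
gaussian_kernel_1d <- function(fwhm_vox) {
  sd <- fwhm_vox / (2 * sqrt(2 * log(2)))
  if (sd <= 0) return(1)
  r <- max(1L, ceiling(3 * sd))
  k <- dnorm(seq(-r, r), sd = sd)
  k / sum(k)
}

#' Separable Gaussian smoothing of a 3-D array
#'
#' Convolves with a truncated Gaussian of the stated FWHM along each axis.
#' Near the grid boundary the kernel is renormalized over the in-grid
#' support, so means are preserved at the edges.
#'
#' @param x 3-D numeric array.
#' @param fwhm_mm full width at half maximum, mm (0 = no smoothing).
#' @param voxel_size_mm voxel spacing, mm.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth_3d <- function(x, fwhm_mm, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (fwhm_mm <= 0) return(x)
  d <- dim(x)
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(fwhm_mm / voxel_size_mm[axis])
    if (length(k) == 1L) next
    n <- d[axis]
    r <- (length(k) - 1L) / 2L
    # dense n x n band matrix with edge renormalization
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    xp <- K %*% matrix(xp, nrow = n)
    dim(xp) <- dp
    x <- aperm(xp, order(perm))
  }
  x
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates, for each subject, a native-interval log-Jacobian map of the form
#' `(dT/2) * (mu_bg + effect_beta * z * region + smoothed noise)`, where `z`
#' is the subject's predictor Z-score and `region` the planted ellipsoid
#' indicator — so after 2-year normalization the planted-region mean is
#' exactly linear in `z` with slope `effect_beta`. Change accumulates
#' log-linearly with the interscan interval, making the `2/dT` normalization
#' exact. Conversion times follow a proportional-hazards exponential model
#' with log-hazard `log(baseline_hazard) + sum(log(hr_per_z) * z_factor)`,
#' censored administratively at `censor_time`. Fully deterministic given
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `synthetic_cohort`: `subject_table`
#'   (data.frame: id, age, gender, education, ethnicity, delta_t_years,
#'   fornix_fa, extra factor Z columns, event, time_years), `maps` (list of
#'   native-interval [log_jacobian_map()]), and `truth` (planted mask, true
#'   effect, true hazard ratios, predictor Z-scores, seed).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 8, seed = 42))
#' coh$subject_table[1:3, c("id", "age", "fornix_fa", "event", "time_years")]
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_subjects
  dg <- spec$demographics

  fa <- rnorm(n, spec$predictor_mean, spec$predictor_sd)
  z <- (fa - spec$predictor_mean) / spec$predictor_sd
  delta_t <- runif(n, spec$delta_t_range[1], spec$delta_t_range[2])

  tab <- data.frame(
    id = sprintf("sub-%03d", seq_len(n)),
    age = rnorm(n, dg$age_mean, dg$age_sd),
    gender = factor(ifelse(rbinom(n, 1, dg$p_female) == 1, "F", "M"),
                    levels = c("F", "M")),
    education = pmax(0, rnorm(n, dg$education_mean, dg$education_sd)),
    ethnicity = factor(sample(names(dg$ethnicity), n, replace = TRUE,
                              prob = dg$ethnicity),
                       levels = names(dg$ethnicity)),
    delta_t_years = delta_t,
    fornix_fa = fa,
    stringsAsFactors = FALSE)

  # brain-factor Z-scores entering the hazard; fornix_fa reuses the
  # predictor's Z, any other named factor gets an independent N(0,1) column
  zmat <- matrix(0, n, length(spec$hr_per_z),
                 dimnames = list(NULL, names(spec$hr_per_z)))
  for (f in names(spec$hr_per_z)) {
    if (f == "fornix_fa") zmat[, f] <- z
    else {
      zmat[, f] <- rnorm(n)
      tab[[paste0(f, "_z")]] <- zmat[, f]
    }
  }
  hazard <- spec$baseline_hazard * exp(drop(zmat %*% log(spec$hr_per_z)))
  t_event <- rexp(n, rate = hazard)
  tab$event <- as.integer(t_event <= spec$censor_time)
  tab$time_years <- pmin(t_event, spec$censor_time)

  region <- ellipsoid_mask(spec$grid_shape, spec$planted_region$center,
                           spec$planted_region$radii)
  maps <- vector("list", n)
  for (i in seq_len(n)) {
    noise <- if (spec$noise_sigma > 0) {
      gaussian_smooth_3d(array(rnorm(prod(spec$grid_shape), 0, spec$noise_sigma),
                               spec$grid_shape),
                         spec$smooth_fwhm_mm, spec$voxel_size_mm)
    } else array(0, spec$grid_shape)
    two_year <- spec$mu_bg + spec$effect_beta * z[i] * region + noise
    maps[[i]] <- log_jacobian_map(two_year * (delta_t[i] / 2.0),
                                  interval_years = delta_t[i],
                                  voxel_size_mm = spec$voxel_size_mm)
  }

  structure(list(subject_table = tab, maps = maps,
                 truth = list(region_mask = region,
                              effect_beta = spec$effect_beta,
                              hr_per_z = spec$hr_per_z,
                              mu_bg = spec$mu_bg,
                              predictor_z = z,
                              seed = spec$seed),
                 spec = spec),
            class = "synthetic_cohort")
}

#' Generate a null synthetic cohort
#'
#' Same generative process as [generate_cohort()] but with the planted effect
#' forced to zero and every hazard ratio forced to 1, so the predictor still
#' varies across subjects but is independent of both the change maps and
#' conversion. The calibration fixture for the permutation test.
#'
#' @inheritParams generate_cohort
#' @return A `synthetic_cohort` whose truth records `effect_beta = 0`.
#' @export
generate_null_cohort <- function(spec) {
  validate_cohort_spec(spec)
  spec$effect_beta <- 0
  spec$hr_per_z[] <- 1
  generate_cohort(spec)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, grid %s, seed %d\n",
              nrow(x$subject_table),
              paste(dim(x$maps[[1]]$values), collapse = "x"),
              x$truth$seed))
  cat(sprintf("  planted effect %.4g per Z in %d voxels; %d conversion events\n",
              x$truth$effect_beta, sum(x$truth$region_mask),
              sum(x$subject_table$event)))
  invisible(x)
}

#' Simulate survival-only subject records
#'
#' The conversion sub-model of [generate_cohort()] without images: subjects
#' get demographics and a set of Z-scored brain factors, and conversion times
#' are drawn from an exponential proportional-hazards model with the stated
#' hazard ratios per Z-unit, censored at `censor_time`. Useful for validating
#' survival fits at sample sizes where simulating maps would be wasteful.
#'
#' @param n number of subjects.
#' @param hr_per_z named numeric, true hazard ratio per Z-unit per factor.
#' @param baseline_hazard hazard per year.
#' @param censor_time administrative censoring (years).
#' @param seed integer seed.
#' @return data.frame with demographics, one Z column per factor, `event`,
#'   and `time_years`.
#' @export
simulate_survival_records <- function(n, hr_per_z = c(fornix_fa = 0.5),
                                      baseline_hazard = 0.1,
                                      censor_time = 10, seed = 1L) {
  stopifnot(n >= 2, all(hr_per_z > 0), baseline_hazard > 0, censor_time > 0)
  set.seed(as.integer(seed))
  tab <- data.frame(
    id = sprintf("sub-%04d", seq_len(n)),
    age = rnorm(n, 72.9, 7.0),
    gender = factor(ifelse(rbinom(n, 1, 0.74) == 1, "F", "M"),
                    levels = c("F", "M")),
    education = pmax(0, rnorm(n, 11.5, 4.8)),
    ethnicity = factor(sample(c("hispanic", "white"), n, TRUE, c(0.56, 0.44)),
                       levels = c("hispanic", "white")),
    stringsAsFactors = FALSE)
  zmat <- matrix(rnorm(n * length(hr_per_z)), n,
                 dimnames = list(NULL, names(hr_per_z)))
  for (f in names(hr_per_z)) tab[[f]] <- zmat[, f]
  hazard <- baseline_hazard * exp(drop(zmat %*% log(hr_per_z)))
  t_event <- rexp(n, rate = hazard)
  tab$event <- as.integer(t_event <= censor_time)
  tab$time_years <- pmin(t_event, censor_time)
  tab
}
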