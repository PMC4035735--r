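---
title: "Methods: log-Jacobian atrophy mapping, cluster-extent permutation inference, and conversion models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: log-Jacobian atrophy mapping and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrophymap)
```

## The measurement model

Longitudinal tensor-based morphometry summarizes within-subject brain change
as a warp `x -> x + u(x)` aligning the baseline scan to the follow-up scan.
The local volume-change factor is the Jacobian determinant of that mapping,

    J(x) = det(I + grad u(x)),

with `J` in (0, 1) meaning shrinkage and `J > 1` expansion. We store the
*displacement* `u` (not absolute positions), the standard TBM convention, so
the identity warp is `u = 0` and the Jacobian of the mapping is `I + grad u`.
`log J` is symmetric about zero, which is what every downstream linear model
assumes. Spatial derivatives are taken in physical units (mm) — central
differences in the grid interior, one-sided at the boundary — so strongly
anisotropic voxels (e.g. 1.875 × 1.875 × 5 mm diffusion grids) are handled
correctly. For an affine warp the finite differences are exact, which gives
the package its sharpest self-checks (uniform scaling by `s` must produce
`3 log s` everywhere, to 1e-6).

Non-positive determinants can occur in practice (folding, noise at CSF
boundaries). The log transform clamps them at `clamp_eps` (default `1e-6`)
and flags the voxels in a mask rather than aborting a cohort run; the flag
count is recorded in the NIfTI sidecar.

Because tissue change is roughly log-linear in time over a few years, maps
from subjects with different interscan intervals ΔT are made comparable by
scaling with `2.0 / ΔT` onto a common 2-year scale. ΔT always comes from the
subject table, never from file metadata. Normalization is exactly linear and
refuses to run twice (the normalized state is an explicit sentinel, not a
convention).

## Voxelwise inference

At each voxel inside the analysis mask we fit a simple linear regression of
the 2-year log-Jacobian on one subject-level baseline predictor (intercept
included) and form the slope t-statistic with `n − 2` degrees of freedom;
computationally we use the algebraic identity `t = r√(n−2)/√(1−r²)` with `r`
the sample correlation, which the tests verify against the regression form
to 1e-10. Two degenerate cases are handled explicitly: voxels with no
between-subject variance get `t = 0` (they can never be suprathreshold), and
numerically perfect fits are capped at `±1e6` and flagged so that infinities
never reach the cluster stage.

Clusters are connected components of `{t > t_threshold}`. Defaults follow
the standard analysis settings: threshold 3.5, 26-connectivity (6 and 18
available), one-sided — only positive associations form clusters, matching
the expected direction (higher baseline FA, less subsequent tissue loss).
A two-sided analysis can be emulated by running the negated maps.

### Familywise control

Significance is assessed by permutation of the predictor across subjects
with the maps fixed. With a single regressor plus intercept and no nuisance
covariates this is an exact exchangeability scheme. For each of `n_perm`
permutations we rebuild the t-map, label clusters, and record the **maximum**
cluster size; the critical size is the `⌈0.95·n_perm⌉`-th order statistic of
those maxima, and an observed cluster is significant only if **strictly
larger** — conservative under ties, which matters because at `t > 3.5` most
null permutations have max size 0–2. Corrected per-cluster p-values use the
add-one estimator `(1 + #{null max ≥ size})/(1 + n_perm)`, whose floor is
`1/(n_perm + 1)`.

The "95th percentile over all iterations" rule admits a second reading —
pooling *all* cluster sizes from all permutations rather than the
per-iteration maximum. The maximal-statistic form is the one that delivers
familywise control and is what the significance criterion here uses by
default; the pooled variant is available via `null_stat = "pooled"` in
`permutation_null()` for sensitivity analyses.

The permutation seed is a required argument: there is no hidden global
randomness anywhere in the package, and a seeded run is byte-reproducible.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture. For subject
`i` with predictor Z-score `z_i` and interval `ΔT_i` it emits the
native-interval map

    (ΔT_i / 2) · ( μ_bg + β·z_i·1{region} + ε_smooth ),

so after 2-year normalization the planted ellipsoid's mean is *exactly*
linear in `z_i` with slope `β` — the generating equation doubles as the
closed-form oracle for recovery tests. The noise field is white Gaussian
(SD `noise_sigma`) smoothed by a separable Gaussian kernel of the stated
FWHM before the ΔT scaling, mimicking the spatial correlation of real TBM
maps; the planted signal is deliberately *not* smoothed so the truth mask is
crisp. Conversion times are exponential with log-hazard
`log(h0) + Σ log(HR_f)·z_f`, censored administratively.

Default conditions (chosen once, as a desk-scale emulation of an elderly
normal cohort, and not revisited):

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 60 | small elderly imaging cohort |
| `grid_shape`, `voxel_size_mm` | 20³ voxels, 2 mm | desk-scale grid with realistic physical extent for ROI-level structure |
| predictor | FA-like, N(0.50, 0.06) | fornix-body FA range in elderly normals |
| `delta_t_range` | 1–3.6 y | second scan at least a year after baseline |
| `noise_sigma`, `smooth_fwhm_mm` | 0.05, 4 mm | smoothed-noise SD ≈ 0.010 in 2-year log-Jacobian units, a plausible per-voxel change SD |
| `effect_beta` | 0.01 | ≈ 1 smoothed-noise SD per predictor Z (per-subject SNR ≈ 1) |
| `mu_bg` | −0.01 | mild global 2-year tissue loss |
| `hr_per_z` | fornix_fa = 0.38 | protective hazard ratio per Z typical of white-matter predictors of conversion |
| `baseline_hazard`, `censor_time` | 0.035/y, 6 y | ≈ 18% converters, matching a ~12/68 conversion pattern |
| demographics | age N(72.9, 7), educ N(11.5, 4.8), 74% female, 2 ethnicity strata (0.56/0.44) | community-recruited elderly normal cohort |

The spatial autocorrelation of real log-Jacobian maps is not identified by
any quantity the analysis reports, so `smooth_fwhm_mm` is a free simulation
parameter, not an estimate of any particular dataset. Ethnicity defaults to
two levels — the smallest case that exercises categorical dummy coding — and
is configurable.

What the generator deliberately does **not** emulate: registration error and
template-space warping artifacts, anatomically structured (non-stationary)
noise, CSF/tissue boundary effects, informative censoring, and any coupling
between demographics and the imaging signal. Passing tests therefore
demonstrate the *statistical machinery* is correct and calibrated under the
stated model, not that real acquisitions meet the model's assumptions.

## Survival and cohort-level models

`fit_cox()` fits one brain factor at a time together with age, gender,
education and ethnicity, the factor Z-scored against the analysis cohort so
its hazard ratio is per Z-unit (age per year). Design choices where the
convention is not forced: Efron tie handling (standard default, and the
brute-force partial-likelihood oracle in the tests uses the same
convention); Wald confidence intervals on the log-HR scale; ethnicity (and
any categorical covariate) treatment-coded with the most frequent level as
reference, identically in the regression module. Collinear designs and
non-convergent (separated) fits are errors, never silent output. The
factor's evidence is a 1-df likelihood-ratio test against the model without
it.

`fit_multi_regression()` is OLS with intercept, two-sided t-test p-values,
and no multiple-testing adjustment (single pre-specified model per factor);
`correlation_matrix()` reports raw Pearson correlations (not partial /
age-adjusted — the unadjusted matrix is the conventional companion to the
adjusted regression).

## Numerical and validation choices

Every nontrivial computation has an independent oracle in the test suite:
a voxel-by-voxel triple-loop Jacobian builder (agreement to 1e-8 on ≤16³
grids), a breadth-first-search component labeler in pure R against the C++
implementation for all three connectivities, the correlation closed form for
the t-map (1e-10), explicit normal equations for the regression (1e-10), a
naive covariance loop for correlations (1e-12), and a grid-maximized Efron
partial likelihood for tiny-n Cox fits (1e-6).

Calibration and recovery are checked at fixed problem sizes chosen to give
stable Monte-Carlo answers at desk scale: familywise error over 200 null
cohorts (40 subjects, 20³ voxels, 500 permutations each; the observed
detection rate must stay below 0.05 plus the binomial margin ≈ 0.082);
planted-region recovery at per-subject SNR ≈ 1 (`effect_beta = 0.01`, n = 60,
Dice > 0.5 required in ≥ 8/10 seeds); and Cox coverage of a true HR 0.5 per Z
across 100 cohorts of n = 500. `scripts/acceptance.R` re-runs the
calibration experiment from scratch with all seeds derived from `--seed`.

## Known limitations

* The voxelwise model is a single-predictor regression; covariate-adjusted
  voxelwise inference (e.g. Freedman–Lane) is out of scope — age adjustment
  happens at the cohort level in the regression and survival modules.
* Cluster-mass statistics and threshold-free cluster enhancement are not
  implemented; inference is cluster-extent only.
* Mask resampling is nearest-neighbor on binary masks; no partial-volume
  weighting in overlap or tissue-composition reports.
* The deformation-field path assumes the displacement convention
  `x -> x + u(x)` in mm on the image grid; estimating `u` from image pairs
  is upstream of this package.
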