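# atrophymap

Tools for asking whether a baseline measurement of brain microstructure —
typically the mean fractional anisotropy (FA) of a white-matter tract such as
the fornix body — predicts *where* and *how fast* brain tissue is lost over
the following years, and whether that tissue loss in turn predicts cognitive
conversion from normal aging to MCI/AD. The intended users are neuroimaging
groups running longitudinal tensor-based morphometry (TBM) studies.

## What it computes

**Volume change.** Given a longitudinal within-subject warp `x -> x + u(x)`,
the local volume-change factor is the Jacobian determinant
`J(x) = det(I + ∇u(x))`; its natural log is symmetric about 0 (negative =
tissue contraction, positive = expansion). Because tissue change is roughly
log-linear in time, each subject's map is rescaled by `2 / ΔT` (ΔT = interscan
interval in years) onto a common 2-year scale.

**Voxelwise inference.** At every voxel the 2-year log-Jacobian is regressed
on the subject-level predictor (OLS with intercept); the slope t-statistic
(`n − 2` df) forms a t-map. Clusters of contiguous voxels with `t > 3.5` are
labeled (6/18/26-connectivity), and familywise significance is assessed by
permutation: the predictor is randomly permuted across subjects, the maximal
suprathreshold cluster size is recorded per permutation, and observed
clusters larger than the 95th percentile of that null are declared
significant (corrected `p = (1 + #{null max ≥ size}) / (1 + n_perm)`). The
union of significant clusters is the significant-association region (the
"fSROI" analog when the predictor is fornix FA).

**Cohort models.** The region's mean change feeds Cox proportional-hazards
models of conversion (demographics + one Z-scored brain factor per model,
Efron ties, likelihood-ratio test), a multiple regression of region mean
change on the predictor plus demographics, and a factor correlation matrix.

**Synthetic cohorts.** `generate_cohort()` simulates the whole data model —
smooth noise maps with a planted ellipsoidal effect whose mean is exactly
linear in the predictor Z-score after 2-year normalization, plus an
exponential proportional-hazards conversion process — with full ground truth,
so every stage is testable end to end.

## Worked example

```r
library(atrophymap)

spec <- cohort_spec(n_subjects = 60, effect_beta = 0.01, seed = 42)
coh  <- generate_cohort(spec)
maps <- lapply(coh$maps, normalize_to_two_years)

fit <- cluster_inference(maps, coh$subject_table$fornix_fa,
                         t_threshold = 3.5, connectivity = 26,
                         n_perm = 1000, alpha = 0.05, seed = 7)
fit
#> Significant region: 1 cluster(s) above critical size 5 (alpha = 0.05)
#>   total volume 2.240 cm^3 (280 voxels)
#>  cluster size_voxels volume_cm3 p_corrected significant
#>        2         280      2.240    0.000999        TRUE
#>        1           1      0.008    0.898102       FALSE
#>        3           1      0.008    0.898102       FALSE

dice_coefficient(fit$roi$mask, coh$truth$region_mask)
#> [1] 1
```

The planted 280-voxel ellipsoid is recovered exactly (Dice 1.0): its cluster
dwarfs the permutation critical size (5 voxels) and gets the smallest
corrected p-value the 1000-permutation null can resolve, `1/1001 ≈ 0.001`.
Two stray single-voxel clusters are correctly rejected. Downstream, the
region's mean change is dominated by the predictor, not demographics, and
predicts conversion:

```r
tab <- coh$subject_table
tab$fsroi_logj <- vapply(maps, function(m) roi_mean(m, fit$roi$mask), numeric(1))

fit_multi_regression(tab, "fsroi_logj",
                     c("fornix_fa", "age", "gender", "education", "ethnicity"))
#> Multiple regression of 'fsroi_logj': n = 60, R^2 = 0.959
#>   (Intercept)            -0.08871  (p = 5.54e-26)
#>   fornix_fa                0.1658  (p = 2.28e-38)
#>   age                  -4.871e-05  (p = 0.331)
#>   ...

fit_cox(tab, "fsroi_logj")
#> Cox proportional-hazards fit: n = 60, events = 13
#> Brain factor 'fsroi_logj' (per unit Z increase): LR chi^2 = 13.281 (df 1), p = 0.000268
#>   hazard ratio 0.318 (95% CI 0.163-0.620)
```

A higher region mean (less tissue loss) carries roughly a 0.32-fold
conversion hazard per Z-unit — the planted protective association propagated
through the imaging stage into the survival model.

`run_pipeline(pipeline_config(...))` chains all stages, writes NIfTI/CSV/JSON
intermediates with provenance sidecars, and returns the report tables.

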