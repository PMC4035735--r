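#' Pipeline configuration
#'
#' Settings for the end-to-end analysis driver [run_pipeline()]. Defaults
#' match the analysis's standard settings: cluster-forming threshold
#' t > 3.5, 1000 permutations, familywise alpha 0.05, 26-connectivity,
#' 2-year target interval.
#'
#' @param output_dir where stages write their outputs and sidecars.
#' @param spec a [cohort_spec()] for the simulation stage.
#' @param null_cohort simulate under the null (no planted effect) instead.
#' @param predictor subject-table column used as the voxelwise predictor.
#' @param t_threshold cluster-forming threshold (default 3.5).
#' @param n_perm permutations for the null (default 1000, minimum 100).
#' @param alpha familywise level (default 0.05).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param seed integer seed for the permutation null.
#' @param clamp_eps determinant floor for the log transform.
#' @param target_interval_years normalization target (default 2).
#' @param write_intermediates write cohort maps and stage outputs to
#'   `output_dir` (default `TRUE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = tempfile("atrophymap-"),
                            spec = cohort_spec(),
                            null_cohort = FALSE,
                            predictor = "fornix_fa",
                            t_threshold = 3.5,
                            n_perm = 1000L,
                            alpha = 0.05,
                            connectivity = 26L,
                            seed = 1L,
                            clamp_eps = 1e-6,
                            target_interval_years = 2.0,
                            write_intermediates = TRUE) {
  cfg <- list(output_dir = output_dir, spec = spec,
              null_cohort = isTRUE(null_cohort), predictor = predictor,
              t_threshold = t_threshold, n_perm = as.integer(n_perm),
              alpha = alpha, connectivity = as.integer(connectivity),
              seed = as.integer(seed), clamp_eps = clamp_eps,
              target_interval_years = target_interval_years,
              write_intermediates = isTRUE(write_intermediates))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$n_perm < 100L)
    stop("configuration error: n_perm must be >= 100", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha > 0.5)
    stop("configuration error: alpha must be in (0, 0.5]", call. = FALSE)
  if (!cfg$connectivity %in% c(6L, 18L, 26L))
    stop("configuration error: connectivity must be 6, 18 or 26", call. = FALSE)
  if (cfg$clamp_eps <= 0)
    stop("configuration error: clamp_eps must be > 0", call. = FALSE)
  if (cfg$target_interval_years != 2.0)
    stop("configuration error: only the 2-year target interval is supported",
         call. = FALSE)
  validate_cohort_spec(cfg$spec)
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  cat(sprintf("  output_dir: %s\n", x$output_dir))
  cat(sprintf("  cohort: n = %d, grid %s, seed %d%s\n", x$spec$n_subjects,
              paste(x$spec$grid_shape, collapse = "x"), x$spec$seed,
              if (x$null_cohort) " (null)" else ""))
  cat(sprintf("  inference: predictor %s, t > %.3g, %d permutations, alpha %.3g, %d-connectivity, seed %d\n",
              x$predictor, x$t_threshold, x$n_perm, x$alpha,
              x$connectivity, x$seed))
  invisible(x)
}

# Re-raise any stage failure with the stage name attached.
.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE))
}

.stage_log <- function(report, stage, t0) {
  elapsed <- as.numeric(Sys.time()) - t0
  message(sprintf("[%s] done in %.2f s", stage, elapsed))
  report$stages[[stage]] <- list(seconds = elapsed)
  report
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in order — simulate, normalize to 2 years, voxelwise
#' slope t-map, cluster labeling, permutation null, significant region,
#' overlap/tissue composition, association regression, correlation matrix,
#' and survival models — writing intermediates and JSON provenance sidecars
#' to `config$output_dir`, and returns a report bundle mirroring the
#' standard result tables: significant-cluster volumes, overlap of the
#' significant region with the planted truth, the multi-regression of
#' region mean change on the predictor plus demographics, the factor
#' correlation matrix, and Cox conversion fits.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  out <- config$output_dir
  if (config$write_intermediates)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(), config = config)

  t0 <- as.numeric(Sys.time())
  cohort <- .with_stage("simulate",
    if (config$null_cohort) generate_null_cohort(config$spec)
    else generate_cohort(config$spec))
  if (config$write_intermediates)
    write_cohort(cohort, file.path(out, "cohort"))
  report <- .stage_log(report, "simulate", t0)

  t0 <- as.numeric(Sys.time())
  maps2y <- .with_stage("normalize", lapply(cohort$maps, normalize_to_two_years))
  report <- .stage_log(report, "normalize", t0)

  tab <- cohort$subject_table
  predictor <- tab[[config$predictor]]
  if (is.null(predictor))
    stop(sprintf("stage cluster: predictor column '%s' not in subject table",
                 config$predictor))

  t0 <- as.numeric(Sys.time())
  inference <- .with_stage("cluster",
    cluster_inference(maps2y, predictor,
                      t_threshold = config$t_threshold,
                      connectivity = config$connectivity,
                      n_perm = config$n_perm, alpha = config$alpha,
                      seed = config$seed))
  report$cluster_table <- inference$roi$table
  report$critical_size <- inference$roi$critical_size
  report$total_sig_volume_cm3 <- inference$roi$total_volume_cm3
  if (config$write_intermediates) {
    vox <- cohort$spec$voxel_size_mm
    RNifti::writeNifti(.as_nifti(inference$tmap$values, vox),
                       file.path(out, "tmap.nii.gz"))
    RNifti::writeNifti(.as_nifti(inference$clusters$label_map, vox),
                       file.path(out, "cluster_labels.nii.gz"))
    write_mask(inference$roi$mask, file.path(out, "significant_mask.nii.gz"), vox)
    .write_sidecar(file.path(out, "significant_mask.nii.gz"), list(
      stage = "cluster", t_threshold = config$t_threshold,
      connectivity = config$connectivity, n_perm = config$n_perm,
      alpha = config$alpha, seed = config$seed,
      critical_size = inference$roi$critical_size,
      version = as.character(utils::packageVersion("atrophymap"))))
  }
  report <- .stage_log(report, "cluster", t0)

  t0 <- as.numeric(Sys.time())
  report$overlap_table <- overlap_composition(
    inference$roi$mask, list(planted_region = cohort$truth$region_mask))
  report$dice_vs_truth <- dice_coefficient(inference$roi$mask,
                                           cohort$truth$region_mask)
  report <- .stage_log(report, "overlap", t0)

  has_roi <- any(inference$roi$mask)
  t0 <- as.numeric(Sys.time())
  if (has_roi) {
    tab$fsroi_logj <- vapply(maps2y, function(m)
      roi_mean(m, inference$roi$mask), numeric(1))
    report$association <- .with_stage("associate", fit_multi_regression(
      tab, "fsroi_logj",
      c(config$predictor, "age", "gender", "education", "ethnicity")))
    report$correlations <- correlation_matrix(
      tab[, c("fsroi_logj", config$predictor, "age")])
  } else {
    report$association <- NULL
    report$correlations <- NULL
  }
  report <- .stage_log(report, "associate", t0)

  t0 <- as.numeric(Sys.time())
  report$survival <- list()
  report$survival[[config$predictor]] <-
    .with_stage("survive", fit_cox(tab, config$predictor))
  if (has_roi)
    report$survival$fsroi_logj <- .with_stage("survive", fit_cox(tab, "fsroi_logj"))
  report <- .stage_log(report, "survive", t0)

  if (config$write_intermediates) {
    write.csv(report$cluster_table, file.path(out, "cluster_table.csv"),
              row.names = FALSE)
    write.csv(report$overlap_table, file.path(out, "overlap_table.csv"),
              row.names = FALSE)
    surv_tab <- do.call(rbind, lapply(names(report$survival), function(f) {
      fit <- report$survival[[f]]
      bf <- fit$coefficients[fit$coefficients$term == f, ]
      data.frame(brain_factor = f, lr_p = fit$lr_p, hr_per_z = bf$hr,
                 hr_lo = bf$hr_lo, hr_hi = bf$hr_hi)
    }))
    write.csv(surv_tab, file.path(out, "survival_table.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      critical_size = report$critical_size,
      total_sig_volume_cm3 = report$total_sig_volume_cm3,
      dice_vs_truth = report$dice_vs_truth,
      r_squared = if (has_roi) report$association$r_squared else NULL,
      seed = config$seed, n_perm = config$n_perm,
      version = as.character(utils::packageVersion("atrophymap"))),
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n===============\n")
  nsig <- sum(x$cluster_table$significant)
  cat(sprintf("Significant clusters: %d (critical size %d voxels); total %.3f cm^3\n",
              nsig, x$critical_size, x$total_sig_volume_cm3))
  if (nsig > 0) {
    cat(sprintf("Dice vs planted truth: %.3f\n", x$dice_vs_truth))
    cat(sprintf("Association model R^2 = %.3f\n", x$association$r_squared))
  }
  for (f in names(x$survival)) {
    fit <- x$survival[[f]]
    bf <- fit$coefficients[fit$coefficients$term == f, ]
    cat(sprintf("Cox [%s]: HR/Z = %.3f (%.3f-%.3f), LR p = %.4g\n",
                f, bf$hr, bf$hr_lo, bf$hr_hi, fit$lr_p))
  }
  invisible(x)
}
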