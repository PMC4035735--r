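# Internal: coerce a per-subject map stack into a voxels x subjects matrix.
# Accepts a list of normalized log_jacobian_map objects or a 4-D array with
# the subject axis last. Returns list(mat, dims, voxel_size_mm).
.map_stack <- function(maps, require_normalized = TRUE) {
  if (is.list(maps) && length(maps) && inherits(maps[[1]], "log_jacobian_map")) {
    dims <- dim(maps[[1]]$values)
    vox <- maps[[1]]$voxel_size_mm
    for (m in maps) {
      if (!identical(dim(m$values), dims))
        stop("maps are not on a common grid")
      if (require_normalized && !identical(m$interval_years, "normalized-2yr"))
        stop("all maps must be normalized to 2 years (see normalize_to_two_years)")
    }
    mat <- vapply(maps, function(m) as.vector(m$values), numeric(prod(dims)))
  } else if (is.array(maps) && length(dim(maps)) == 4L) {
    dims <- dim(maps)[1:3]
    vox <- c(1, 1, 1)
    mat <- matrix(maps, nrow = prod(dims))
  } else stop("`maps` must be a list of log_jacobian_map or a 4-D array")
  list(mat = mat, dims = dims, voxel_size_mm = vox)
}

# Internal: slope t-statistics for every row of `mat` (voxels x subjects)
# regressed on each column of `zs` (standardized predictors, subjects x P).
# Returns a voxels x P matrix. t = r * sqrt(n-2) / sqrt(1 - r^2), capped at
# +/- t_cap where the fit is numerically perfect; zero-variance voxels get 0.
.slope_t_matrix <- function(mat, zs, t_cap = 1e6) {
  n <- ncol(mat)
  xc <- mat - rowMeans(mat)
  ssx <- rowSums(xc^2)
  r <- (xc %*% zs) / (sqrt(ssx) * sqrt(n - 1))
  r[ssx == 0, ] <- 0
  r <- pmin(pmax(r, -1), 1)
  one_minus_r2 <- pmax(1 - r^2, 0)
  t <- r * sqrt(n - 2) / sqrt(one_minus_r2)
  perfect <- one_minus_r2 < 1e-12
  t[perfect] <- sign(r[perfect]) * t_cap
  t[ssx == 0, ] <- 0
  t
}

.standardize <- function(z) {
  s <- sd(z)
  if (!is.finite(s) || s == 0) stop("predictor has zero variance")
  (z - mean(z)) / s
}

#' Voxelwise slope t-map
#'
#' At each voxel inside the analysis mask, fits an ordinary least-squares
#' regression (with intercept) of the subjects' 2-year-normalized
#' log-Jacobian values on a scalar baseline predictor, and returns the
#' Student t-statistic of the slope with `n - 2` degrees of freedom.
#' Positive t means higher predictor values co-occur with less negative
#' log-Jacobians (less tissue loss). Voxels with a numerically perfect fit
#' are capped at `+/- 1e6` and flagged; voxels with no between-subject
#' variance get t = 0.
#'
#' @param maps list of normalized [log_jacobian_map()] (one per subject) or
#'   a 4-D array with subjects on the last axis.
#' @param predictor numeric per-subject baseline measurement (e.g. ROI mean
#'   FA); must have nonzero variance.
#' @param mask optional logical 3-D array restricting the analysis; defaults
#'   to all voxels.
#' @return An object of class `t_map`: `values` (3-D array, 0 outside the
#'   mask), `mask`, `n_subjects`, `df`, `voxel_size_mm`, and `capped`
#'   (logical array flagging perfect-fit voxels).
#' @export
voxelwise_slope_t <- function(maps, predictor, mask = NULL) {
  st <- .map_stack(maps)
  n <- ncol(st$mat)
  if (n < 4L) stop("need at least 4 subjects for a slope t-map")
  if (length(predictor) != n)
    stop("`predictor` length must equal the number of maps")
  if (is.null(mask)) mask <- array(TRUE, st$dims)
  if (!identical(dim(mask), st$dims)) stop("mask grid does not match maps")
  zs <- .standardize(predictor)
  idx <- which(mask)
  tvals <- array(0, st$dims)
  capped <- array(FALSE, st$dims)
  tm <- .slope_t_matrix(st$mat[idx, , drop = FALSE], matrix(zs, ncol = 1))
  tvals[idx] <- tm[, 1]
  capped[idx] <- abs(tm[, 1]) >= 1e6
  structure(list(values = tvals, mask = mask, n_subjects = n, df = n - 2L,
                 voxel_size_mm = st$voxel_size_mm, capped = capped),
            class = "t_map")
}

#' @export
print.t_map <- function(x, ...) {
  cat(sprintf("Slope t-map: %s grid, n = %d subjects (df = %d)\n",
              paste(dim(x$values), collapse = "x"), x$n_subjects, x$df))
  v <- x$values[x$mask]
  cat(sprintf("  t in mask: [%.3f, %.3f]; %d voxel(s) capped\n",
              min(v), max(v), sum(x$capped)))
  invisible(x)
}

#' Label suprathreshold clusters
#'
#' Connected components of the suprathreshold set `t > t_threshold` under
#' 6-, 18- or 26-connectivity (one-sided, matching positive-association
#' cluster reporting). Sizes are reported in voxels and in cm^3 via the
#' voxel volume.
#'
#' @param tmap a [voxelwise_slope_t()] result, or a plain 3-D numeric array.
#' @param t_threshold finite scalar cluster-forming threshold (default 3.5).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param voxel_size_mm used when `tmap` is a plain array.
#' @return An object of class `cluster_set`: `label_map` (integer 3-D array,
#'   0 background, labels 1..K), `sizes` (voxels per label), `volumes_cm3`,
#'   `t_threshold`, `connectivity`, `voxel_volume_cm3`.
#' @export
label_clusters <- function(tmap, t_threshold = 3.5, connectivity = 26,
                           voxel_size_mm = NULL) {
  if (inherits(tmap, "t_map")) {
    values <- tmap$values
    if (is.null(voxel_size_mm)) voxel_size_mm <- tmap$voxel_size_mm
  } else {
    values <- tmap
    if (is.null(voxel_size_mm)) voxel_size_mm <- c(1, 1, 1)
  }
  stopifnot(is.array(values), length(dim(values)) == 3L,
            is.finite(t_threshold))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  supra <- values > t_threshold
  labels <- .label_components_cpp(as.logical(supra), dim(values), connectivity)
  dim(labels) <- dim(values)
  k <- max(labels)
  sizes <- if (k > 0) tabulate(labels[labels > 0L], nbins = k) else integer(0)
  voxel_volume_cm3 <- prod(voxel_size_mm) / 1000
  structure(list(label_map = labels, sizes = sizes,
                 volumes_cm3 = sizes * voxel_volume_cm3,
                 t_threshold = t_threshold, connectivity = connectivity,
                 voxel_volume_cm3 = voxel_volume_cm3),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: %d cluster(s) with t > %.3g, %d-connectivity\n",
              length(x$sizes), x$t_threshold, x$connectivity))
  if (length(x$sizes)) {
    o <- order(x$sizes, decreasing = TRUE)
    show <- utils::head(o, 10)
    for (i in show)
      cat(sprintf("  cluster %d: %d voxels (%.3f cm^3)\n",
                  i, x$sizes[i], x$volumes_cm3[i]))
    if (length(o) > 10) cat(sprintf("  ... and %d more\n", length(o) - 10))
  }
  invisible(x)
}

#' Permutation null distribution of the maximal cluster size
#'
#' Builds the familywise null by randomly permuting the predictor across
#' subjects (maps fixed), recomputing the slope t-map, labeling
#' suprathreshold clusters, and recording the maximum cluster size per
#' permutation. With a single regressor plus intercept this permutation
#' scheme is exact under exchangeability. The critical size is the
#' `ceiling((1 - alpha) * n_perm)`-th order statistic of the max sizes;
#' significance downstream requires a strictly larger observed cluster,
#' which is conservative under ties. A pooled mode — percentile over all
#' cluster sizes from all permutations pooled — is available via
#' `null_stat = "pooled"`.
#'
#' @inheritParams voxelwise_slope_t
#' @param t_threshold cluster-forming threshold (default 3.5).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param n_perm number of permutations, >= 100 (default 1000).
#' @param seed integer seed (mandatory: no hidden global randomness).
#' @param alpha familywise level used to place the critical order statistic
#'   (default 0.05).
#' @param null_stat `"max"` (maximal-statistic familywise control, default)
#'   or `"pooled"`.
#' @return An object of class `permutation_null`: `max_cluster_sizes`,
#'   `critical_size`, `n_perm`, `seed`, `alpha`, `t_threshold`,
#'   `connectivity`, `null_stat`.
#' @export
permutation_null <- function(maps, predictor, mask = NULL, t_threshold = 3.5,
                             connectivity = 26, n_perm = 1000, seed,
                             alpha = 0.05, null_stat = c("max", "pooled")) {
  null_stat <- match.arg(null_stat)
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (n_perm * alpha < 1)
    stop("n_perm too small to resolve the requested percentile")
  if (missing(seed)) stop("`seed` is required for the permutation null")
  connectivity <- as.integer(connectivity)
  st <- .map_stack(maps)
  n <- ncol(st$mat)
  if (length(predictor) != n)
    stop("`predictor` length must equal the number of maps")
  if (is.null(mask)) mask <- array(TRUE, st$dims)
  if (!identical(dim(mask), st$dims)) stop("mask grid does not match maps")
  zs <- .standardize(predictor)
  idx <- which(mask)
  xmat <- st$mat[idx, , drop = FALSE]

  set.seed(as.integer(seed))
  perms <- vapply(seq_len(n_perm), function(i) zs[sample.int(n)], numeric(n))
  tmat <- .slope_t_matrix(xmat, perms)

  max_sizes <- integer(n_perm)
  all_sizes <- if (null_stat == "pooled") vector("list", n_perm) else NULL
  supra_full <- array(FALSE, st$dims)
  for (p in seq_len(n_perm)) {
    sup <- tmat[, p] > t_threshold
    if (!any(sup)) next
    supra_full[] <- FALSE
    supra_full[idx[sup]] <- TRUE
    labels <- .label_components_cpp(as.logical(supra_full), st$dims,
                                    connectivity)
    sizes <- tabulate(labels[labels > 0L], nbins = max(labels))
    max_sizes[p] <- max(sizes)
    if (null_stat == "pooled") all_sizes[[p]] <- sizes
  }
  pool <- if (null_stat == "pooled") unlist(all_sizes) else max_sizes
  if (length(pool) == 0L) pool <- 0L
  k <- ceiling((1 - alpha) * length(pool))
  critical_size <- sort(pool)[max(k, 1L)]
  structure(list(max_cluster_sizes = max_sizes, critical_size = critical_size,
                 n_perm = n_perm, seed = as.integer(seed), alpha = alpha,
                 t_threshold = t_threshold, connectivity = connectivity,
                 null_stat = null_stat),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("Permutation null (%s statistic): %d permutations, seed %d\n",
              x$null_stat, x$n_perm, x$seed))
  cat(sprintf("  t > %.3g, %d-connectivity; critical size (alpha = %.3g): %d voxels\n",
              x$t_threshold, x$connectivity, x$alpha, x$critical_size))
  cat(sprintf("  max sizes: median %d, 95%% %d, max %d\n",
              stats::median(x$max_cluster_sizes),
              as.integer(quantile(x$max_cluster_sizes, 0.95, type = 1)),
              max(x$max_cluster_sizes)))
  invisible(x)
}

#' Significant clusters under familywise permutation control
#'
#' Retains observed clusters whose size strictly exceeds the permutation
#' critical size, and reports the familywise-corrected p-value
#' `(1 + #(null max >= size)) / (1 + n_perm)` for every observed cluster.
#' The union mask of retained clusters is the significant-association
#' region (the "fSROI" analog when the predictor is fornix FA).
#'
#' @param observed a [label_clusters()] result.
#' @param null a [permutation_null()] built with the same threshold and
#'   connectivity.
#' @param alpha familywise level (in (0, 0.5]; default 0.05).
#' @return An object of class `significant_roi`: `mask` (logical 3-D array),
#'   `table` (data.frame: cluster, size_voxels, volume_cm3, p_corrected,
#'   significant), `critical_size`, `total_volume_cm3`, `alpha`.
#' @export
significant_clusters <- function(observed, null, alpha = 0.05) {
  stopifnot(inherits(observed, "cluster_set"), inherits(null, "permutation_null"))
  if (!isTRUE(all.equal(observed$t_threshold, null$t_threshold)) ||
      observed$connectivity != null$connectivity)
    stop("observed clusters and permutation null use different threshold/connectivity")
  if (alpha <= 0 || alpha > 0.5) stop("alpha must be in (0, 0.5]")
  sizes <- observed$sizes
  p_corr <- vapply(sizes, function(s)
    (1 + sum(null$max_cluster_sizes >= s)) / (1 + null$n_perm), numeric(1))
  sig <- sizes > null$critical_size
  mask <- array(FALSE, dim(observed$label_map))
  if (any(sig))
    mask <- array(observed$label_map %in% which(sig), dim(observed$label_map))
  tab <- data.frame(cluster = seq_along(sizes), size_voxels = sizes,
                    volume_cm3 = observed$volumes_cm3, p_corrected = p_corr,
                    significant = sig)
  structure(list(mask = mask, table = tab,
                 critical_size = null$critical_size,
                 total_volume_cm3 = sum(observed$volumes_cm3[sig]),
                 alpha = alpha),
            class = "significant_roi")
}

#' @export
print.significant_roi <- function(x, ...) {
  nsig <- sum(x$table$significant)
  cat(sprintf("Significant region: %d cluster(s) above critical size %d (alpha = %.3g)\n",
              nsig, x$critical_size, x$alpha))
  cat(sprintf("  total volume %.3f cm^3 (%d voxels)\n",
              x$total_volume_cm3, sum(x$mask)))
  if (nrow(x$table)) {
    tb <- x$table[order(-x$table$size_voxels), ][seq_len(min(10, nrow(x$table))), ]
    print(tb, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' One-call cluster-extent permutation inference
#'
#' Convenience wrapper running [voxelwise_slope_t()], [label_clusters()],
#' [permutation_null()] and [significant_clusters()] with shared settings.
#'
#' @inheritParams permutation_null
#' @param alpha familywise level (default 0.05).
#' @return An object of class `cluster_inference` bundling `tmap`,
#'   `clusters`, `null` and `roi`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_spec(n_subjects = 20,
#'                                    grid_shape = c(12L, 12L, 12L),
#'                                    effect_beta = 0.05, seed = 3))
#' maps <- lapply(coh$maps, normalize_to_two_years)
#' fit <- cluster_inference(maps, coh$subject_table$fornix_fa,
#'                          n_perm = 200, seed = 11)
#' summary(fit)
#' }
#' @export
cluster_inference <- function(maps, predictor, mask = NULL, t_threshold = 3.5,
                              connectivity = 26, n_perm = 1000, alpha = 0.05,
                              seed, null_stat = c("max", "pooled")) {
  null_stat <- match.arg(null_stat)
  tmap <- voxelwise_slope_t(maps, predictor, mask)
  clusters <- label_clusters(tmap, t_threshold, connectivity)
  null <- permutation_null(maps, predictor, mask, t_threshold, connectivity,
                           n_perm, seed, alpha, null_stat)
  roi <- significant_clusters(clusters, null, alpha)
  structure(list(tmap = tmap, clusters = clusters, null = null, roi = roi),
            class = "cluster_inference")
}

#' @export
print.cluster_inference <- function(x, ...) {
  print(x$roi)
  invisible(x)
}

#' @export
summary.cluster_inference <- function(object, ...) {
  print(object$tmap)
  print(object$clusters)
  print(object$null)
  print(object$roi)
  invisible(object)
}

#' Dice overlap coefficient of two binary masks
#'
#' `2|A & B| / (|A| + |B|)`; 1 for identical nonempty masks, 0 for disjoint.
#'
#' @param a,b logical arrays on a common grid.
#' @return Scalar between 0 and 1; `NaN` if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
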