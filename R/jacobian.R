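#' Displacement field on a regular voxel grid
#'
#' Bundles a 3-D vector field `u` (in mm) with its voxel spacing. The field
#' encodes the longitudinal within-subject warp as the mapping
#' `x -> x + u(x)` from baseline to follow-up space, so the identity warp is
#' `u = 0` everywhere. The spatial Jacobian of the mapping is `I + grad(u)`.
#'
#' @param u 4-D numeric array, `dim = c(nx, ny, nz, 3)`; the last axis holds
#'   the x, y, z displacement components in mm.
#' @param voxel_size_mm positive numeric of length 3, voxel spacing in mm.
#' @return An object of class `displacement_field`.
#' @seealso [jacobian_determinant()]
#' @export
displacement_field <- function(u, voxel_size_mm) {
  if (!is.array(u) || length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("`u` must be a 4-D array with dim[4] == 3 (vector components)")
  if (any(dim(u)[1:3] < 2L))
    stop("grid dimensions must be >= 2 along each axis")
  if (!all(is.finite(u)))
    stop("displacement field contains non-finite values")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive reals")
  structure(list(u = u, voxel_size_mm = voxel_size_mm),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$u)[1:3]
  cat(sprintf("Displacement field: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$voxel_size_mm), collapse = " x ")))
  invisible(x)
}

# Finite-difference derivative of a 3-D array along one axis, in physical
# units: central differences in the interior, one-sided at the boundaries.
.fd_axis <- function(a, axis, spacing) {
  d <- dim(a)
  n <- d[axis]
  idx_hi <- c(2:n, n)       # forward neighbour (clamped)
  idx_lo <- c(1, 1:(n - 1)) # backward neighbour (clamped)
  # denominator: 2h interior, h at the two boundary slices
  denom <- rep(2 * spacing, n)
  denom[c(1, n)] <- spacing
  slice <- function(idx) {
    if (axis == 1L) a[idx, , , drop = FALSE]
    else if (axis == 2L) a[, idx, , drop = FALSE]
    else a[, , idx, drop = FALSE]
  }
  diff <- slice(idx_hi) - slice(idx_lo)
  den <- array(0, dim = d)
  if (axis == 1L) den[] <- denom
  else if (axis == 2L) den[] <- rep(denom, each = d[1])
  else den[] <- rep(denom, each = d[1] * d[2])
  diff / den
}

#' Jacobian determinant of a longitudinal warp
#'
#' Computes, at every voxel, the determinant of the 3x3 spatial derivative
#' matrix of the mapping `x -> x + u(x)`, i.e. `det(I + grad(u))` with
#' derivatives taken in physical units (mm). This is the local volume-change
#' factor: values in (0, 1) indicate shrinkage, values above 1 expansion,
#' and exactly 1 no change. Central differences are used in the grid
#' interior and one-sided differences at the boundaries, so anisotropic
#' voxels are handled correctly.
#'
#' @param field a [displacement_field()].
#' @return 3-D numeric array of determinants, one per voxel.
#' @examples
#' u <- array(0, c(4, 4, 4, 3))
#' field <- displacement_field(u, c(1, 1, 1))
#' range(jacobian_determinant(field))  # identity warp: all 1
#' @export
jacobian_determinant <- function(field) {
  if (!inherits(field, "displacement_field"))
    field <- displacement_field(field$u, field$voxel_size_mm)
  u <- field$u
  h <- field$voxel_size_mm
  # J[i][j] = d u_i / d x_j ; mapping Jacobian is I + J
  J <- vector("list", 3L)
  for (i in 1:3) {
    ui <- u[, , , i]
    J[[i]] <- lapply(1:3, function(j) .fd_axis(ui, j, h[j]))
  }
  a11 <- 1 + J[[1]][[1]]; a12 <- J[[1]][[2]]; a13 <- J[[1]][[3]]
  a21 <- J[[2]][[1]]; a22 <- 1 + J[[2]][[2]]; a23 <- J[[2]][[3]]
  a31 <- J[[3]][[1]]; a32 <- J[[3]][[2]]; a33 <- 1 + J[[3]][[3]]
  a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Log-Jacobian map
#'
#' Container for a per-subject map of log proportional volume change.
#' A value of 0 means no change, negative values contraction (tissue loss),
#' positive values expansion. `interval_years` is the subject's interscan
#' interval; after [normalize_to_two_years()] it carries the sentinel
#' `"normalized-2yr"` and values are on a common 2-year scale.
#'
#' @param values 3-D numeric array of log volume-change factors.
#' @param interval_years positive scalar (years), or `"normalized-2yr"`.
#' @param voxel_size_mm positive numeric of length 3 (mm); default 1 mm iso.
#' @param clamp_mask optional logical array flagging voxels whose determinant
#'   was clamped before the log transform.
#' @return An object of class `log_jacobian_map`.
#' @export
log_jacobian_map <- function(values, interval_years,
                             voxel_size_mm = c(1, 1, 1), clamp_mask = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  normalized <- identical(interval_years, "normalized-2yr")
  if (!normalized) {
    interval_years <- as.numeric(interval_years)
    if (length(interval_years) != 1L || !is.finite(interval_years) ||
        interval_years <= 0)
      stop("`interval_years` must be a positive scalar (years)")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive reals")
  if (!is.null(clamp_mask) && !identical(dim(clamp_mask), dim(values)))
    stop("`clamp_mask` must match the grid of `values`")
  structure(list(values = values, interval_years = interval_years,
                 voxel_size_mm = voxel_size_mm, clamp_mask = clamp_mask),
            class = "log_jacobian_map")
}

#' @export
print.log_jacobian_map <- function(x, ...) {
  d <- dim(x$values)
  iv <- if (identical(x$interval_years, "normalized-2yr"))
    "normalized to 2 years" else sprintf("interval %.3g years", x$interval_years)
  cat(sprintf("Log-Jacobian map: %d x %d x %d voxels, %s\n", d[1], d[2], d[3], iv))
  cat(sprintf("  values: [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  if (!is.null(x$clamp_mask) && any(x$clamp_mask))
    cat(sprintf("  %d voxel(s) clamped before log transform\n", sum(x$clamp_mask)))
  invisible(x)
}

#' Log transform of a Jacobian determinant map
#'
#' Takes the natural log of the volume-change factor so that the result is
#' symmetric about 0 (negative = contraction, positive = expansion).
#' Non-positive determinants — which can arise from folding or noise at CSF
#' boundaries — are clamped to `clamp_eps` rather than aborting; clamped
#' voxels are flagged in the returned map's `clamp_mask`.
#'
#' @param det_map 3-D numeric array of Jacobian determinants.
#' @param interval_years interscan interval ΔT in years (positive).
#' @param clamp_eps positive floor applied to determinants before `log`;
#'   default `1e-6`.
#' @param voxel_size_mm voxel spacing in mm, stored on the map.
#' @return A [log_jacobian_map()].
#' @export
log_jacobian <- function(det_map, interval_years, clamp_eps = 1e-6,
                         voxel_size_mm = c(1, 1, 1)) {
  if (!is.numeric(clamp_eps) || length(clamp_eps) != 1L || clamp_eps <= 0)
    stop("`clamp_eps` must be a positive scalar")
  if (!is.array(det_map) || length(dim(det_map)) != 3L)
    stop("`det_map` must be a 3-D array")
  if (!all(is.finite(det_map)))
    stop("`det_map` contains non-finite values")
  clamped <- det_map < clamp_eps
  vals <- log(pmax(det_map, clamp_eps))
  dim(vals) <- dim(det_map)
  dim(clamped) <- dim(det_map)
  log_jacobian_map(vals, interval_years, voxel_size_mm, clamp_mask = clamped)
}

#' Normalize a log-Jacobian map to a two-year interval
#'
#' Scales the map by `2.0 / interval_years` so that maps from subjects with
#' different interscan intervals represent change over a common 2-year
#' period. Valid because brain-tissue change is roughly log-linear over time
#' at these scales. Normalizing an already-normalized map is an error.
#'
#' @param map a [log_jacobian_map()] with a numeric `interval_years`.
#' @return A [log_jacobian_map()] with `interval_years = "normalized-2yr"`.
#' @export
normalize_to_two_years <- function(map) {
  stopifnot(inherits(map, "log_jacobian_map"))
  if (identical(map$interval_years, "normalized-2yr"))
    stop("map is already normalized to a 2-year interval")
  f <- 2.0 / map$interval_years
  log_jacobian_map(map$values * f, "normalized-2yr",
                   map$voxel_size_mm, clamp_mask = map$clamp_mask)
}

#' Analytic affine displacement field
#'
#' Emits the displacement field `u(x) = (A - I) x` of the affine warp
#' `x -> A x` about the grid origin (first voxel corner), in mm. Useful as
#' an exactly solvable input: the Jacobian determinant of the warp is
#' `det(A)` everywhere, e.g. uniform scaling by `s` gives `s^3`.
#'
#' @param A 3x3 numeric matrix.
#' @param grid_shape integer vector of length 3 (voxels).
#' @param voxel_size_mm voxel spacing in mm.
#' @return A [displacement_field()].
#' @export
affine_displacement_field <- function(A, grid_shape, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(is.matrix(A), all(dim(A) == c(3L, 3L)))
  grid_shape <- as.integer(grid_shape)
  co <- as.matrix(expand.grid(x = (seq_len(grid_shape[1]) - 1) * voxel_size_mm[1],
                              y = (seq_len(grid_shape[2]) - 1) * voxel_size_mm[2],
                              z = (seq_len(grid_shape[3]) - 1) * voxel_size_mm[3]))
  u_flat <- co %*% t(A - diag(3)) # (A - I) x, row-wise
  u <- array(0, c(grid_shape, 3L))
  for (i in 1:3) u[, , , i] <- array(u_flat[, i], grid_shape)
  displacement_field(u, voxel_size_mm)
}
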