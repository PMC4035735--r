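#' Mean of an image over an ROI
#'
#' Arithmetic mean of a scalar image (e.g. an FA map or a normalized
#' log-Jacobian map) over the voxels of a binary ROI mask.
#'
#' @param image 3-D numeric array, or a [log_jacobian_map()].
#' @param roi logical 3-D array on the same grid; must be nonempty.
#' @return Scalar mean.
#' @export
roi_mean <- function(image, roi) {
  if (inherits(image, "log_jacobian_map")) image <- image$values
  stopifnot(is.array(image), length(dim(image)) == 3L)
  if (!identical(dim(roi), dim(image)))
    stop("ROI grid does not match the image grid")
  if (!any(roi)) stop("ROI mask is empty")
  mean(image[roi])
}

#' Overlap composition of a reference mask against atlas ROIs
#'
#' For each atlas ROI, the percentage of the ROI's voxels lying inside the
#' reference mask (the denominator is the ROI size, matching "% of ROI"
#' reporting). The converse percentage — share of the reference covered by
#' the ROI — is also returned. Empty ROIs are flagged, not dropped.
#'
#' @param reference logical 3-D array (e.g. the significant-region mask).
#' @param rois named list of logical 3-D arrays on the same grid.
#' @return data.frame with columns `roi`, `n_roi_voxels`, `n_overlap`,
#'   `pct_of_roi`, `pct_of_reference`, `empty`.
#' @export
overlap_composition <- function(reference, rois) {
  stopifnot(is.array(reference), is.list(rois), length(rois) >= 1L)
  if (is.null(names(rois)) || any(!nzchar(names(rois))))
    stop("`rois` must be a named list")
  n_ref <- sum(reference)
  rows <- lapply(names(rois), function(nm) {
    roi <- rois[[nm]]
    if (!identical(dim(roi), dim(reference)))
      stop(sprintf("ROI '%s' is not on the reference grid", nm))
    n_roi <- sum(roi)
    n_ov <- sum(roi & reference)
    data.frame(roi = nm, n_roi_voxels = n_roi, n_overlap = n_ov,
               pct_of_roi = if (n_roi > 0) 100 * n_ov / n_roi else NA_real_,
               pct_of_reference = if (n_ref > 0) 100 * n_ov / n_ref else NA_real_,
               empty = n_roi == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$empty))
    warning(sprintf("empty ROI(s): %s", paste(out$roi[out$empty], collapse = ", ")))
  out
}

#' Tissue composition of a mask
#'
#' Fraction of the reference mask's voxels in each tissue class of a labeled
#' segmentation (e.g. CSF/GM/WM). Voxels whose segmentation label is not in
#' `labels` count as unclassified, with a warning.
#'
#' @param reference logical 3-D array; must be nonempty.
#' @param segmentation integer 3-D array of tissue labels on the same grid.
#' @param labels named integer vector mapping class name -> label value,
#'   default `c(csf = 1, gm = 2, wm = 3)`.
#' @return Named numeric of fractions over the classes plus `unclassified`;
#'   sums to 1.
#' @export
tissue_composition <- function(reference, segmentation,
                               labels = c(csf = 1L, gm = 2L, wm = 3L)) {
  stopifnot(is.array(reference), identical(dim(segmentation), dim(reference)))
  if (!any(reference)) stop("reference mask is empty")
  seg <- segmentation[reference]
  n <- length(seg)
  fr <- vapply(labels, function(l) sum(seg == l) / n, numeric(1))
  unclassified <- 1 - sum(fr)
  if (unclassified > 1e-12)
    warning(sprintf("%.1f%% of reference voxels have labels outside `labels`",
                    100 * unclassified))
  c(fr, unclassified = max(unclassified, 0))
}
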