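# NIfTI and tabular I/O with JSON provenance sidecars.

.sidecar_path <- function(path) sub("(\\.nii)?(\\.gz)?$", ".json", path)

.write_sidecar <- function(path, info) {
  jsonlite::write_json(info, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.as_nifti <- function(values, voxel_size_mm) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- voxel_size_mm
  img
}

#' Write a log-Jacobian map as NIfTI with a JSON sidecar
#'
#' The sidecar records the interval semantics (`interval_years` or the
#' normalized-2yr sentinel) and the number of clamped voxels, so the map can
#' be re-read without loss of provenance.
#'
#' @param map a [log_jacobian_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_logj_map <- function(map, path) {
  stopifnot(inherits(map, "log_jacobian_map"))
  RNifti::writeNifti(.as_nifti(map$values, map$voxel_size_mm), path)
  .write_sidecar(path, list(
    kind = "log_jacobian_map",
    interval_years = map$interval_years,
    voxel_size_mm = map$voxel_size_mm,
    n_clamped = if (is.null(map$clamp_mask)) 0L else sum(map$clamp_mask)))
  invisible(path)
}

#' Read a log-Jacobian map written by [write_logj_map()]
#'
#' @param path NIfTI path; the JSON sidecar written alongside is required
#'   for the interval semantics.
#' @return A [log_jacobian_map()].
#' @export
read_logj_map <- function(path) {
  img <- RNifti::readNifti(path)
  sc_path <- .sidecar_path(path)
  if (!file.exists(sc_path))
    stop(sprintf("missing sidecar %s (interval semantics unknown)", sc_path))
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  vals <- array(as.numeric(img), dim = dim(img))
  iv <- sc$interval_years
  if (!identical(iv, "normalized-2yr")) iv <- as.numeric(iv)
  log_jacobian_map(vals, iv, as.numeric(sc$voxel_size_mm))
}

#' Write a binary mask as NIfTI
#'
#' @param mask logical 3-D array.
#' @param path output path.
#' @param voxel_size_mm voxel spacing, mm.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, voxel_size_mm = c(1, 1, 1)) {
  vals <- array(as.integer(mask), dim = dim(mask))
  RNifti::writeNifti(.as_nifti(vals, voxel_size_mm), path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI path.
#' @return Logical 3-D array.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim = dim(img))
}

#' Write a displacement field as 4-D NIfTI
#'
#' The last axis holds the x, y, z displacement components (mm).
#'
#' @param field a [displacement_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  img <- RNifti::asNifti(field$u)
  RNifti::pixdim(img) <- c(field$voxel_size_mm, 1)
  RNifti::writeNifti(img, path)
  .write_sidecar(path, list(kind = "displacement_field",
                            voxel_size_mm = field$voxel_size_mm,
                            component_order = c("x", "y", "z")))
  invisible(path)
}

#' Read a displacement field from 4-D NIfTI
#'
#' @param path NIfTI path (4-D, last axis = x/y/z components in mm).
#' @param voxel_size_mm override voxel spacing; taken from the sidecar (or
#'   header pixdim) when `NULL`.
#' @return A [displacement_field()].
#' @export
read_displacement_field <- function(path, voxel_size_mm = NULL) {
  img <- RNifti::readNifti(path)
  u <- array(as.numeric(img), dim = dim(img))
  if (is.null(voxel_size_mm)) {
    sc_path <- .sidecar_path(path)
    voxel_size_mm <- if (file.exists(sc_path)) {
      as.numeric(jsonlite::read_json(sc_path,
                                     simplifyVector = TRUE)$voxel_size_mm)
    } else RNifti::pixdim(img)[1:3]
  }
  displacement_field(u, voxel_size_mm)
}

#' Write a synthetic cohort to disk
#'
#' Writes one NIfTI log-Jacobian map per subject under `maps/`, the subject
#' table as CSV, the planted truth mask as NIfTI, and a JSON sidecar
#' recording the generating spec and seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "maps"), recursive = TRUE, showWarnings = FALSE)
  tab <- cohort$subject_table
  for (i in seq_len(nrow(tab)))
    write_logj_map(cohort$maps[[i]],
                   file.path(dir, "maps", paste0(tab$id[i], "_logj.nii.gz")))
  write.csv(tab, file.path(dir, "subject_table.csv"), row.names = FALSE)
  write_mask(cohort$truth$region_mask, file.path(dir, "truth_mask.nii.gz"),
             cohort$spec$voxel_size_mm)
  spec <- cohort$spec
  class(spec) <- NULL
  # named vectors must serialize as JSON objects, not bare arrays
  spec$hr_per_z <- as.list(spec$hr_per_z)
  spec$demographics$ethnicity <- as.list(spec$demographics$ethnicity)
  jsonlite::write_json(list(kind = "synthetic_cohort", spec = spec,
                            seed = cohort$truth$seed),
                       file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return A `synthetic_cohort` (truth holds the mask and recorded seed;
#'   per-subject predictor Z-scores are recomputed from the stored spec).
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  tab <- read.csv(file.path(dir, "subject_table.csv"),
                  stringsAsFactors = FALSE)
  tab$gender <- factor(tab$gender, levels = c("F", "M"))
  eth_levels <- names(meta$spec$demographics$ethnicity)
  tab$ethnicity <- factor(tab$ethnicity, levels = eth_levels)
  maps <- lapply(tab$id, function(id)
    read_logj_map(file.path(dir, "maps", paste0(id, "_logj.nii.gz"))))
  z <- (tab$fornix_fa - meta$spec$predictor_mean) / meta$spec$predictor_sd
  structure(list(subject_table = tab, maps = maps,
                 truth = list(region_mask = read_mask(
                                file.path(dir, "truth_mask.nii.gz")),
                              effect_beta = meta$spec$effect_beta,
                              hr_per_z = unlist(meta$spec$hr_per_z),
                              mu_bg = meta$spec$mu_bg,
                              predictor_z = z,
                              seed = meta$seed),
                 spec = meta$spec),
            class = "synthetic_cohort")
}
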