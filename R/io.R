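## File round-tripping: schedule tables (CSV), k-space bundles (RDS), and
## parameter maps / weighted images (NIfTI with FOV-derived voxel size).

#' Write / read a sampling schedule table
#'
#' Columnar export of a sampling pattern: chronological_index, window_id,
#' readout_pos, weighting_id, golden_index, angle_deg (and the predicted
#' signal).
#'
#' @param pattern a `sampling_pattern`.
#' @param path CSV file path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule` a
#'   data frame.
#' @export
write_schedule <- function(pattern, path) {
  utils::write.csv(as.data.frame(pattern), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  utils::read.csv(path)
}

#' Write / read a radial k-space bundle
#'
#' Single-file container (RDS) holding the complex samples, per-spoke
#' angles, radial coordinates, the schedule table and the protocol.
#'
#' @param kspace a `radial_kspace` object.
#' @param path file path (`.rds`).
#' @return `write_kspace` returns `path` invisibly; `read_kspace` the
#'   restored object.
#' @export
write_kspace <- function(kspace, path) {
  stopifnot(inherits(kspace, "radial_kspace"))
  saveRDS(kspace, path)
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "radial_kspace"))
  x
}

#' Write an image or map as NIfTI with FOV-derived voxel size
#'
#' @param x a matrix, a 3-D array, an `image_series`, or a `t1rho_map`
#'   (writes the `t1rho` matrix).
#' @param path output path (`.nii` / `.nii.gz`).
#' @param fov field of view in mm (taken from the object if present).
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(x, path, fov = NULL) {
  if (inherits(x, "image_series")) {
    fov <- fov %||% x$fov
    arr <- x$images
  } else if (inherits(x, "t1rho_map")) {
    fov <- fov %||% x$fov
    arr <- x$t1rho
  } else arr <- x
  if (is.null(fov)) stop("fov is required to set the voxel size")
  vox <- fov / dim(arr)[1]
  arr[!is.finite(arr)] <- 0
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[1:2] <- vox
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
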