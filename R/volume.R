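#' Volumetric image and label-mask containers
#'
#' A `volume_grid` is a 3D grayscale intensity array with per-axis voxel
#' spacing in millimetres; the third array axis is the coronal slice axis. A
#' `label_mask` is an integer array on the same grid holding the three
#' segmentation classes: 0 = background, 1 = left kidney, 2 = right kidney.
#'
#' @param data 3D numeric array (rows, columns, coronal slices).
#' @param spacing numeric length-3, voxel edge lengths in mm per axis.
#' @param slice_axis integer, the axis along which coronal slices are stacked
#'   (fixed to 3 in this implementation; retained as metadata).
#' @return An object of class `volume_grid` (or `label_mask`), a list with
#'   elements `data`, `spacing`, `slice_axis`.
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), slice_axis = 3L) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive finite numbers (mm).")
  }
  structure(list(data = data, spacing = spacing, slice_axis = 3L),
            class = "volume_grid")
}

#' @rdname volume_grid
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), slice_axis = 3L) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  storage.mode(data) <- "integer"
  vals <- unique(as.vector(data))
  if (!all(vals %in% 0:2)) {
    abort("label_mask values must be 0 (background), 1 (left) or 2 (right).")
  }
  out <- volume_grid(data, spacing, slice_axis)
  class(out) <- c("label_mask", "volume_grid")
  out
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Read and write volumes as NIfTI
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] that carry
#' the voxel spacing in the NIfTI header. Masks are written as 16-bit
#' integers.
#'
#' @param x a `volume_grid` or `label_mask`.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_volume`/`read_mask` return a `volume_grid`/`label_mask`;
#'   the writers return `path` invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "volume_grid"))
  dt <- if (inherits(x, "label_mask")) "int16" else "double"
  arr <- x$data
  attr(arr, "pixdim") <- x$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = dt), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  volume_grid(array(as.numeric(img), dim(img)),
              spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  label_mask(array(as.integer(round(as.numeric(img))), dim(img)),
             spacing = RNifti::pixdim(img)[seq_len(3)])
}
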