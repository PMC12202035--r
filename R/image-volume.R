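#' 3D image volumes and binary masks
#'
#' `image_volume()` wraps a 3D numeric array with its physical voxel
#' spacing (mm) and origin; `binary_mask()` does the same for a logical
#' array on the same lattice. These are the in-memory currency of the
#' volumetry functions; [read_volume()] / [write_volume()] move them to
#' and from NIfTI-1 files.
#'
#' Conventions: voxel indices are 1-based in R but physical positions are
#' measured in mm from the centre of the first voxel, so voxel `(i,j,k)`
#' sits at `origin_mm + (c(i,j,k) - 1) * spacing_mm`. Volumes are reported
#' in cm^3 (1 mL = 1 cm^3).
#'
#' @param voxels 3D numeric (or logical for masks) array.
#' @param spacing_mm Positive length-3 numeric, voxel edge lengths in mm.
#' @param origin_mm Length-3 numeric, physical position of voxel (1,1,1).
#' @return An object of class `image_volume` or `binary_mask`.
#' @export
image_volume <- function(voxels, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!all(is.finite(voxels))) abort("image_volume: all intensities must be finite")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    abort("image_volume: spacing_mm must be three strictly positive values")
  }
  structure(
    list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "image_volume"
  )
}

#' @rdname image_volume
#' @export
binary_mask <- function(voxels, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) abort("binary_mask: NA voxels not allowed")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    abort("binary_mask: spacing_mm must be three strictly positive values")
  }
  structure(
    list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "binary_mask"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume %dx%dx%d, spacing %s mm, range [%.3g, %.3g]>\n",
              d[1], d[2], d[3], paste(format(x$spacing_mm), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask %dx%dx%d, spacing %s mm, %d voxels on (%.3f cm^3)>\n",
              d[1], d[2], d[3], paste(format(x$spacing_mm), collapse = "x"),
              sum(x$voxels), mask_volume_cm3(x)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

#' @export
dim.binary_mask <- function(x) dim(x$voxels)

voxel_volume_mm3 <- function(x) prod(x$spacing_mm)

same_lattice <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm, tolerance = 1e-9))
}

stop_if_lattice_mismatch <- function(a, b, what = "inputs") {
  if (!same_lattice(a, b)) {
    abort(sprintf("%s must share one lattice (same shape and spacing)", what))
  }
  invisible(TRUE)
}

# physical mm position -> fractional 1-based voxel index
mm_to_index <- function(vol, pos_mm) {
  (as.numeric(pos_mm) - vol$origin_mm) / vol$spacing_mm + 1
}

#' Volume of a binary mask in cm^3
#'
#' Counts true voxels and multiplies by the physical voxel volume. Full
#' precision is returned; rounding to one decimal happens only at the
#' presentation layer.
#'
#' @param mask A [binary_mask()].
#' @return Nonnegative scalar volume in cm^3.
#' @examples
#' m <- binary_mask(array(TRUE, c(10, 10, 10)))
#' mask_volume_cm3(m)  # 1000 voxels at 1 mm^3 -> 1 cm^3
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$voxels) * voxel_volume_mm3(mask) / 1000
}

#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers around the RNifti reader/writer that preserve voxel
#' spacing. Masks are stored as 0/1 integer volumes and re-binarised on
#' read with `as_mask = TRUE`.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param as_mask Read as a [binary_mask()] (voxels > 0)?
#' @return [read_volume()] returns an `image_volume` or `binary_mask`;
#'   [write_volume()] returns `path` invisibly.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (as_mask) binary_mask(vox > 0, spacing_mm = sp)
  else image_volume(vox, spacing_mm = sp)
}

#' @rdname read_volume
#' @param x An `image_volume` or `binary_mask`.
#' @export
write_volume <- function(x, path) {
  vox <- x$voxels
  if (inherits(x, "binary_mask")) vox <- array(as.integer(vox), dim = dim(vox))
  img <- RNifti::asNifti(vox)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
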