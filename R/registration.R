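#' Rigid transforms and image resampling
#'
#' A rigid transform maps physical (mm) points of the fixed image's space
#' into the moving image's space: `T(x) = R (x - c) + c + t`, with `R` a
#' proper rotation, `t` a translation and `c` the rotation centre
#' (defaulting to the grid centre). Resampling an image under `T` pulls
#' moving-image intensities back onto the fixed lattice, which is the
#' form needed for subtraction volumetry.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation_mm Length-3 numeric translation in mm.
#' @param centre_mm Rotation centre in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation_mm = c(0, 0, 0),
                            centre_mm = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)))
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    abort("rigid_transform: rotation must be orthonormal with determinant +1")
  }
  structure(
    list(rotation = rotation, translation_mm = as.numeric(translation_mm),
         centre_mm = as.numeric(centre_mm)),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angles(x$rotation) * 180 / pi
  cat(sprintf("<rigid_transform t = (%.3f, %.3f, %.3f) mm, angles = (%.3f, %.3f, %.3f) deg>\n",
              x$translation_mm[1], x$translation_mm[2], x$translation_mm[3],
              ang[1], ang[2], ang[3]))
  invisible(x)
}

rotation_from_angles <- function(a) {
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

rotation_angles <- function(R) {
  # inverse of rotation_from_angles for small-angle regimes
  c(atan2(R[3, 2], R[3, 3]), -asin(max(-1, min(1, R[3, 1]))), atan2(R[2, 1], R[1, 1]))
}

grid_centre_mm <- function(vol) {
  vol$origin_mm + (dim(vol$voxels) - 1) / 2 * vol$spacing_mm
}

# trilinear sample of a 3D array at fractional 1-based indices (matrix n x 3);
# coordinates are clamped to the grid (edge replication)
interp_trilinear <- function(arr, idx) {
  d <- dim(arr)
  x <- pmin(pmax(idx[, 1], 1), d[1])
  y <- pmin(pmax(idx[, 2], 1), d[2])
  z <- pmin(pmax(idx[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  lin <- function(i, j, k) arr[cbind(i, j, k)]
  c000 <- lin(x0, y0, z0);     c100 <- lin(x0 + 1, y0, z0)
  c010 <- lin(x0, y0 + 1, z0); c110 <- lin(x0 + 1, y0 + 1, z0)
  c001 <- lin(x0, y0, z0 + 1); c101 <- lin(x0 + 1, y0, z0 + 1)
  c011 <- lin(x0, y0 + 1, z0 + 1); c111 <- lin(x0 + 1, y0 + 1, z0 + 1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
}

fixed_lattice_mm <- function(vol) {
  d <- dim(vol$voxels)
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  cbind(vol$origin_mm[1] + (g$i - 1) * vol$spacing_mm[1],
        vol$origin_mm[2] + (g$j - 1) * vol$spacing_mm[2],
        vol$origin_mm[3] + (g$k - 1) * vol$spacing_mm[3])
}

apply_transform_mm <- function(transform, pts) {
  ctr <- matrix(transform$centre_mm, nrow(pts), 3, byrow = TRUE)
  sweep(t(transform$rotation %*% t(pts - ctr)), 2,
        -(transform$centre_mm + transform$translation_mm))
}

#' @rdname rigid_transform
#' @param moving Image to resample.
#' @param transform A `rigid_transform` mapping fixed space to moving space.
#' @param reference Image providing the output lattice.
#' @param method `"trilinear"` (images) or `"nearest"` (masks).
#' @export
resample_image <- function(moving, transform, reference, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  pts <- apply_transform_mm(transform, fixed_lattice_mm(reference))
  idx <- sweep(sweep(pts, 2, moving$origin_mm), 2, moving$spacing_mm, "/") + 1
  vals <- if (method == "nearest") {
    d <- dim(moving$voxels)
    ii <- pmin(pmax(round(idx[, 1]), 1), d[1])
    jj <- pmin(pmax(round(idx[, 2]), 1), d[2])
    kk <- pmin(pmax(round(idx[, 3]), 1), d[3])
    moving$voxels[cbind(ii, jj, kk)]
  } else {
    interp_trilinear(moving$voxels, idx)
  }
  out <- array(as.numeric(vals), dim = dim(reference$voxels))
  if (inherits(moving, "binary_mask")) {
    binary_mask(out > 0.5, spacing_mm = reference$spacing_mm,
                origin_mm = reference$origin_mm)
  } else {
    image_volume(out, spacing_mm = reference$spacing_mm,
                 origin_mm = reference$origin_mm)
  }
}

#' Rigid co-registration of pre/post-infusion volumes
#'
#' Estimates the rigid transform aligning `moving` onto `fixed` by
#' minimising the mean squared intensity difference. Initialisation uses
#' the integer-voxel shift maximising the FFT cross-correlation, followed
#' by Nelder-Mead refinement over three rotation angles (about the grid
#' centre) and three translations. Identical inputs return the identity
#' transform immediately.
#'
#' @param fixed,moving [image_volume()]s with overlapping fields of view.
#' @param refine Run the continuous 6-parameter refinement after the
#'   integer-shift initialisation (default `TRUE`).
#' @param maxit Maximum Nelder-Mead iterations.
#' @return A [rigid_transform()] mapping fixed space into moving space;
#'   `resample_image(moving, transform, fixed)` then overlays `fixed`.
#' @export
register_rigid <- function(fixed, moving, refine = TRUE, maxit = 300) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"))
  ctr <- grid_centre_mm(fixed)
  if (identical(dim(fixed$voxels), dim(moving$voxels)) &&
      isTRUE(all.equal(fixed$voxels, moving$voxels, tolerance = 1e-12))) {
    return(rigid_transform(diag(3), c(0, 0, 0), ctr))
  }
  init_t <- fft_integer_shift(fixed, moving)
  if (!refine) return(rigid_transform(diag(3), init_t, ctr))

  obj <- function(par) {
    tr <- rigid_transform(rotation_from_angles(par[1:3]), par[4:6], ctr)
    res <- resample_image(moving, tr, fixed)
    mean((fixed$voxels - res$voxels)^2)
  }
  fit <- optim(c(0, 0, 0, init_t), obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))
  if (obj(c(0, 0, 0, init_t)) < fit$value) {
    # refinement wandered; keep the initialisation
    return(rigid_transform(diag(3), init_t, ctr))
  }
  rigid_transform(rotation_from_angles(fit$par[1:3]), fit$par[4:6], ctr)
}

# integer-voxel translation (mm) maximising circular cross-correlation;
# moving(x) ~ fixed(x - d) content-shift convention, so the pull-back
# translation returned is +d
fft_integer_shift <- function(fixed, moving) {
  a <- fixed$voxels - mean(fixed$voxels)
  b <- moving$voxels - mean(moving$voxels)
  xc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  d <- dim(a)
  peak <- arrayInd(which.max(xc), d) - 1L
  shift <- ifelse(peak > d / 2, peak - d, peak)
  as.numeric(shift) * fixed$spacing_mm
}
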