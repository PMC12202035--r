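#' Specification of a synthetic CED imaging phantom
#'
#' Describes the geometry and corruption model of a synthetic pre/post
#' infusion T1 pair plus FLAIR volume. The post-infusion image is built
#' as `drift_scale * pre + drift_offset + delta_intensity * 1[vd] + noise`,
#' i.e. a localized T1-shortening signal increase where the tracer went,
#' on top of a global affine scanner drift and Gaussian noise — the
#' minimal corruption that makes reference-structure normalization
#' necessary. The ground-truth distribution volume is an ellipsoid with
#' an optional planar cap carved away (`blocked_fraction`), mimicking
#' tissue regions that blocked infusate delivery.
#'
#' @param grid_shape Integer triple, voxels per axis.
#' @param spacing_mm Positive real triple, voxel size in mm.
#' @param tumor_center_mm,tumor_radii_mm Tumor ellipsoid (FLAIR
#'   hyperintense) centre and semi-axes, mm.
#' @param infusate_center_mm,infusate_radii_mm Ground-truth tracer
#'   distribution ellipsoid, mm.
#' @param blocked_fraction Fraction in `[0, 1)` of the infusate ellipsoid
#'   volume removed as a surface-touching cap.
#' @param delta_intensity T1-shortening signal increase inside the
#'   distribution volume (arbitrary intensity units).
#' @param drift_scale,drift_offset Global affine intensity drift between
#'   the pre and post scans.
#' @param noise_sigma Standard deviation of the independent Gaussian
#'   noise added to the post image (and FLAIR).
#' @param reference_center_mm,reference_radii_mm Uninfused reference
#'   structure used for intensity normalization; must be voxel-disjoint
#'   from the infusate ellipsoid.
#' @return A `phantom_spec` list, validated.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing_mm = c(1, 1, 1),
                         tumor_center_mm = c(31.5, 31.5, 31.5),
                         tumor_radii_mm = c(22, 18, 17.5),
                         infusate_center_mm = c(34, 34, 32),
                         infusate_radii_mm = c(14, 11, 9.6),
                         blocked_fraction = 0.2,
                         delta_intensity = 50,
                         drift_scale = 1.1,
                         drift_offset = 15,
                         noise_sigma = 5,
                         reference_center_mm = c(10, 48, 16),
                         reference_radii_mm = c(6, 6, 6)) {
  spec <- list(
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    tumor_center_mm = as.numeric(tumor_center_mm),
    tumor_radii_mm = as.numeric(tumor_radii_mm),
    infusate_center_mm = as.numeric(infusate_center_mm),
    infusate_radii_mm = as.numeric(infusate_radii_mm),
    blocked_fraction = blocked_fraction,
    delta_intensity = delta_intensity,
    drift_scale = drift_scale, drift_offset = drift_offset,
    noise_sigma = noise_sigma,
    reference_center_mm = as.numeric(reference_center_mm),
    reference_radii_mm = as.numeric(reference_radii_mm)
  )
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3L, all(spec$grid_shape >= 8L),
            all(spec$spacing_mm > 0))
  for (r in c("tumor_radii_mm", "infusate_radii_mm", "reference_radii_mm")) {
    if (any(spec[[r]] <= 0)) abort(sprintf("phantom_spec: %s must be strictly positive", r))
  }
  if (spec$blocked_fraction < 0 || spec$blocked_fraction >= 1) {
    abort("phantom_spec: blocked_fraction must be in [0, 1)")
  }
  if (spec$delta_intensity < 0) abort("phantom_spec: delta_intensity must be nonnegative")
  if (spec$drift_scale <= 0) abort("phantom_spec: drift_scale must be positive")
  if (spec$noise_sigma < 0) abort("phantom_spec: noise_sigma must be nonnegative")
  extent_mm <- (spec$grid_shape - 1) * spec$spacing_mm
  for (nm in c("tumor", "infusate", "reference")) {
    ctr <- spec[[paste0(nm, "_center_mm")]]
    rad <- spec[[paste0(nm, "_radii_mm")]]
    if (any(ctr - rad < 0) || any(ctr + rad > extent_mm)) {
      abort(sprintf("phantom_spec: %s ellipsoid exceeds the grid (centre %s, radii %s)",
                    nm, paste(ctr, collapse = ","), paste(rad, collapse = ",")))
    }
  }
  invisible(spec)
}

# logical array: voxel centres inside the ellipsoid
rasterise_ellipsoid <- function(grid_shape, spacing_mm, center_mm, radii_mm) {
  ax <- lapply(1:3, function(a) ((seq_len(grid_shape[a]) - 1) * spacing_mm[a] - center_mm[a]) / radii_mm[a])
  ux2 <- ax[[1]]^2
  uy2 <- ax[[2]]^2
  uz2 <- ax[[3]]^2
  q <- outer(outer(ux2, uy2, "+"), uz2, "+")
  q <= 1
}

# normalized cap plane position t such that the fraction of a ball with
# first coordinate u1 > t equals f; cap fraction(t) = (2 - 3t + t^3) / 4
cap_plane_position <- function(f) {
  if (f <= 0) return(1)
  stats::uniroot(function(t) (2 - 3 * t + t^3) / 4 - f,
                 lower = -1, upper = 1, tol = 1e-12)$root
}

# analytic volume (cm^3) of the carved ellipsoid
carved_ellipsoid_cm3 <- function(radii_mm, blocked_fraction) {
  4 / 3 * pi * prod(radii_mm) * (1 - blocked_fraction) / 1000
}

#' Generate a synthetic pre/post-infusion phantom case
#'
#' Builds the deterministic pre-infusion T1 image (smooth background
#' texture plus a brighter reference structure), the FLAIR image (tumor
#' hyperintensity), the ground-truth masks, and the post-infusion T1
#' image under the corruption model described in [phantom_spec()].
#' Identical `(spec, seed)` pairs give bit-identical arrays.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer RNG seed for the noise draws.
#' @return A `phantom_case` list: `pre_t1`, `post_t1`, `flair`
#'   ([image_volume()]s), `tumor_truth`, `vd_truth`, `reference_mask`
#'   ([binary_mask()]s), `spec`, `seed`.
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sigma = 0), seed = 1)
#' mask_volume_cm3(ph$vd_truth)
#' @export
generate_phantom <- function(spec, seed = 1L) {
  validate_phantom_spec(spec)
  gs <- spec$grid_shape; sp <- spec$spacing_mm

  tumor <- rasterise_ellipsoid(gs, sp, spec$tumor_center_mm, spec$tumor_radii_mm)
  ref <- rasterise_ellipsoid(gs, sp, spec$reference_center_mm, spec$reference_radii_mm)
  vd <- rasterise_ellipsoid(gs, sp, spec$infusate_center_mm, spec$infusate_radii_mm)
  if (spec$blocked_fraction > 0) {
    tcut <- cap_plane_position(spec$blocked_fraction)
    u1 <- ((seq_len(gs[1]) - 1) * sp[1] - spec$infusate_center_mm[1]) / spec$infusate_radii_mm[1]
    blocked <- array(u1 > tcut, dim = gs)  # recycles along axis 1
    vd <- vd & !blocked
  }
  if (any(vd & ref)) {
    abort("generate_phantom: reference structure overlaps the infusate ellipsoid")
  }

  # deterministic smooth texture gives registration gradients to lock
  # onto; the reference structure additionally carries an internal
  # intensity ramp and fine texture, because the variance-matching
  # normalization needs the reference's own contrast to dominate the
  # scanner noise (as anatomical structures do)
  pos <- lapply(1:3, function(a) (seq_len(gs[a]) - 1) * sp[a])
  tx <- sin(2 * pi * pos[[1]] / 23)
  ty <- sin(2 * pi * pos[[2]] / 29)
  tz <- sin(2 * pi * pos[[3]] / 37)
  texture <- 8 * outer(outer(tx, ty), tz) +
    4 * outer(outer(cos(2 * pi * pos[[1]] / 11), cos(2 * pi * pos[[2]] / 13)),
              rep(1, gs[3]))
  ref_ramp <- array(15 * (pos[[1]] - spec$reference_center_mm[1]) /
                      spec$reference_radii_mm[1], dim = gs)
  ref_fine <- 8 * outer(outer(sin(2 * pi * pos[[1]] / 5.3),
                              sin(2 * pi * pos[[2]] / 4.7)),
                        sin(2 * pi * pos[[3]] / 6.1))

  pre <- 100 + texture + ref * (50 + ref_ramp + ref_fine)
  flair_clean <- 100 + texture + 100 * tumor

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  noise_post <- if (spec$noise_sigma > 0) array(rnorm(prod(gs), 0, spec$noise_sigma), gs) else 0
  noise_flair <- if (spec$noise_sigma > 0) array(rnorm(prod(gs), 0, spec$noise_sigma), gs) else 0

  post <- spec$drift_scale * pre + spec$drift_offset +
    spec$delta_intensity * vd + noise_post

  structure(list(
    pre_t1 = image_volume(pre, sp),
    post_t1 = image_volume(post, sp),
    flair = image_volume(flair_clean + noise_flair, sp),
    tumor_truth = binary_mask(tumor, sp),
    vd_truth = binary_mask(vd, sp),
    reference_mask = binary_mask(ref, sp),
    spec = spec, seed = as.integer(seed)
  ), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case seed %d: vd %.2f cm^3 (analytic %.2f), tumor %.2f cm^3>\n",
              x$seed, mask_volume_cm3(x$vd_truth),
              carved_ellipsoid_cm3(x$spec$infusate_radii_mm, x$spec$blocked_fraction),
              mask_volume_cm3(x$tumor_truth)))
  invisible(x)
}

#' Write a phantom case to NIfTI files
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if needed).
#' @return Tibble of file paths, invisibly.
#' @export
write_phantom <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(pre_t1 = "pre_t1.nii.gz", post_t1 = "post_t1.nii.gz",
             flair = "flair.nii.gz", tumor_truth = "tumor_truth.nii.gz",
             vd_truth = "vd_truth.nii.gz", reference_mask = "reference_mask.nii.gz")
  paths <- file.path(dir, files)
  purrr::walk2(names(files), paths, function(nm, p) write_volume(case[[nm]], p))
  invisible(tibble(component = names(files), path = paths))
}
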