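#' Segment the uninfused reference structure
#'
#' Region growing on the pre-infusion image: the 6-connected component
#' of voxels whose intensity lies inside `intensity_window` that
#' contains the seed point. The reference structure calibrates the
#' pre/post intensity normalization, so it must lie outside any infused
#' region (the caller is responsible for choosing such a seed; see
#' [normalize_post()]).
#'
#' @param pre Pre-infusion [image_volume()].
#' @param reference_seed_mm Physical seed point (mm) inside the structure.
#' @param intensity_window Length-2 numeric `(lo, hi)`.
#' @return A [binary_mask()] of the reference structure.
#' @export
segment_reference <- function(pre, reference_seed_mm, intensity_window) {
  stopifnot(inherits(pre, "image_volume"), length(intensity_window) == 2L)
  idx <- round(mm_to_index(pre, reference_seed_mm))
  d <- dim(pre$voxels)
  if (any(idx < 1) || any(idx > d)) abort("segment_reference: seed point outside the volume")
  seed_lin <- idx[1] + (idx[2] - 1) * d[1] + (idx[3] - 1) * d[1] * d[2]
  v <- pre$voxels[seed_lin]
  if (v < intensity_window[1] || v > intensity_window[2]) {
    abort(sprintf("segment_reference: seed intensity %.3g outside window [%g, %g]",
                  v, intensity_window[1], intensity_window[2]))
  }
  candidate <- pre$voxels >= intensity_window[1] & pre$voxels <= intensity_window[2]
  comp <- flood_fill(candidate, as.integer(seed_lin))
  if (!any(comp)) abort("segment_reference: empty segmentation")
  binary_mask(comp, spacing_mm = pre$spacing_mm, origin_mm = pre$origin_mm)
}

#' Normalize the post-infusion image against the pre-infusion image
#'
#' The post scan differs from the pre scan by an unknown global affine
#' intensity map (scanner drift) on top of the localized tracer signal.
#' Inside a reference structure untouched by the infusion, the two scans
#' image identical tissue, so matching the reference-mask mean and
#' standard deviation identifies the drift: the returned image is
#' `scale * post + offset` with `scale = sd_ref(pre) / sd_ref(post)` and
#' `offset = mean_ref(pre) - scale * mean_ref(post)`. `residual_sigma`,
#' the standard deviation of `post_norm - pre` within the reference,
#' estimates the noise floor used to threshold the difference image.
#'
#' @param pre Pre-infusion [image_volume()].
#' @param post Post-infusion [image_volume()], already resampled onto
#'   `pre`'s lattice (see [register_rigid()] / [resample_image()]).
#' @param reference Nonempty [binary_mask()] of the uninfused structure.
#' @return List of class `normalization`: `post_norm` (an
#'   [image_volume()]), and a one-row `result` tibble with `scale`,
#'   `offset`, `residual_sigma`.
#' @export
normalize_post <- function(pre, post, reference) {
  stop_if_lattice_mismatch(pre, post, "pre and post")
  stop_if_lattice_mismatch(pre, reference, "image and reference mask")
  sel <- reference$voxels
  if (!any(sel)) abort("normalize_post: reference mask is empty")
  sd_pre <- sd(pre$voxels[sel])
  sd_post <- sd(post$voxels[sel])
  if (sd_post < 1e-12) {
    abort("normalize_post: zero intensity variance inside the reference (degenerate reference)")
  }
  scale <- sd_pre / sd_post
  offset <- mean(pre$voxels[sel]) - scale * mean(post$voxels[sel])
  post_norm <- image_volume(scale * post$voxels + offset,
                            spacing_mm = pre$spacing_mm, origin_mm = pre$origin_mm)
  structure(list(
    post_norm = post_norm,
    result = tibble(scale = scale, offset = offset,
                    residual_sigma = sd(post_norm$voxels[sel] - pre$voxels[sel]))
  ), class = "normalization")
}

#' @export
print.normalization <- function(x, ...) {
  cat(sprintf("<normalization scale %.4f, offset %.3f, residual sigma %.4f>\n",
              x$result$scale, x$result$offset, x$result$residual_sigma))
  invisible(x)
}

#' Segment the tracer distribution volume (Vd) from the difference image
#'
#' Voxels inside the region of interest where the normalized
#' post-minus-pre difference exceeds `k_sigma` times the reference-mask
#' residual noise are kept; connected components smaller than
#' `min_component_cm3` are removed as noise speckle; interior holes are
#' filled; the result is clipped to the ROI. With `residual_sigma = 0`
#' (noise-free input) the threshold degenerates to strict positivity,
#' recorded in the `degenerate_threshold` attribute.
#'
#' @param pre Pre-infusion [image_volume()].
#' @param post_norm Normalized post-infusion image ([normalize_post()]).
#' @param roi Nonempty [binary_mask()] region of interest (a generous
#'   bounding region around the infusion site; the whole grid is a valid
#'   default for phantoms).
#' @param k_sigma Threshold multiplier (default 3).
#' @param min_component_cm3 Minimum connected-component volume kept
#'   (default 0.05 cm^3).
#' @param residual_sigma Noise-floor estimate, usually
#'   `normalization$result$residual_sigma`.
#' @return A [binary_mask()] (subset of `roi`) with attributes
#'   `threshold` and `degenerate_threshold`.
#' @export
segment_vd <- function(pre, post_norm, roi, k_sigma = 3,
                       min_component_cm3 = 0.05, residual_sigma) {
  stop_if_lattice_mismatch(pre, post_norm, "pre and post_norm")
  stop_if_lattice_mismatch(pre, roi, "images and roi")
  stopifnot(k_sigma > 0, min_component_cm3 >= 0, residual_sigma >= 0)
  if (!any(roi$voxels)) abort("segment_vd: roi is empty")
  # floor the threshold at a fraction of the image dynamic range: with a
  # (near-)noise-free pair the estimated sigma collapses to rounding
  # dust, and "strictly positive difference" must not pick up float
  # noise of that magnitude
  floor_eps <- 1e-6 * diff(range(pre$voxels))
  thr <- k_sigma * residual_sigma
  degenerate <- thr < floor_eps
  if (degenerate) thr <- floor_eps
  diff <- post_norm$voxels - pre$voxels
  m <- roi$voxels & diff > thr
  m <- remove_small_components(m, pre$spacing_mm, min_component_cm3)
  m <- fill_holes(m) & roi$voxels
  out <- binary_mask(m, spacing_mm = pre$spacing_mm, origin_mm = pre$origin_mm)
  attr(out, "threshold") <- thr
  attr(out, "degenerate_threshold") <- degenerate
  out
}

#' Segment the FLAIR-hyperintense tumor by seeded region growing
#'
#' The connected component of voxels at or above `threshold` containing
#' the seed, followed by hole filling so that dark cystic or necrotic
#' compartments enclosed by the hyperintense rim are counted as tumor.
#'
#' @param flair Baseline FLAIR [image_volume()].
#' @param seed_mm Physical seed point (mm) inside the tumor.
#' @param threshold Hyperintensity threshold.
#' @return A [binary_mask()] of the tumor.
#' @export
segment_tumor <- function(flair, seed_mm, threshold) {
  stopifnot(inherits(flair, "image_volume"))
  idx <- round(mm_to_index(flair, seed_mm))
  d <- dim(flair$voxels)
  if (any(idx < 1) || any(idx > d)) abort("segment_tumor: seed point outside the volume")
  seed_lin <- idx[1] + (idx[2] - 1) * d[1] + (idx[3] - 1) * d[1] * d[2]
  if (flair$voxels[seed_lin] < threshold) {
    abort(sprintf("segment_tumor: seed intensity %.3g below threshold %g (empty segmentation)",
                  flair$voxels[seed_lin], threshold))
  }
  comp <- flood_fill(flair$voxels >= threshold, as.integer(seed_lin))
  binary_mask(fill_holes(comp), spacing_mm = flair$spacing_mm,
              origin_mm = flair$origin_mm)
}

#' Full subtraction-volumetry chain on one pre/post pair
#'
#' Convenience wrapper: optional rigid registration of the post image
#' onto the pre lattice (identity for same-session pairs), reference
#' normalization, difference segmentation, and volume measurement.
#'
#' @param pre,post [image_volume()]s.
#' @param roi,reference [binary_mask()]s on the pre lattice.
#' @param k_sigma,min_component_cm3 Passed to [segment_vd()].
#' @param register Run [register_rigid()] on the pair (default `FALSE`:
#'   same-session acquisitions are already aligned).
#' @return List of class `vd_report`: `vd_mask`, and a one-row `report`
#'   tibble (`vd_cm3`, `scale`, `offset`, `residual_sigma`, `k_sigma`,
#'   `min_component_cm3`, `registered`).
#' @export
measure_vd <- function(pre, post, roi, reference, k_sigma = 3,
                       min_component_cm3 = 0.05, register = FALSE) {
  if (register) {
    tr <- register_rigid(pre, post)
    post <- resample_image(post, tr, pre)
  }
  norm <- normalize_post(pre, post, reference)
  vd <- segment_vd(pre, norm$post_norm, roi, k_sigma = k_sigma,
                   min_component_cm3 = min_component_cm3,
                   residual_sigma = norm$result$residual_sigma)
  structure(list(
    vd_mask = vd,
    report = dplyr::mutate(norm$result,
                           vd_cm3 = mask_volume_cm3(vd), k_sigma = k_sigma,
                           min_component_cm3 = min_component_cm3,
                           registered = register, .before = 1)
  ), class = "vd_report")
}

#' @export
print.vd_report <- function(x, ...) {
  cat(sprintf("<vd_report: Vd %.3f cm^3 (k = %g, sigma = %.4g)>\n",
              x$report$vd_cm3, x$report$k_sigma, x$report$residual_sigma))
  invisible(x)
}

#' Dice overlap between two masks
#'
#' @param a,b [binary_mask()]s on the same lattice.
#' @return Dice coefficient in `[0, 1]` (1 for two empty masks).
#' @export
dice_coefficient <- function(a, b) {
  stop_if_lattice_mismatch(a, b, "masks")
  denom <- sum(a$voxels) + sum(b$voxels)
  if (denom == 0) return(1)
  2 * sum(a$voxels & b$voxels) / denom
}
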