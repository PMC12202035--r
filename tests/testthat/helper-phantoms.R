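# Small, fast phantom geometry for unit tests: 36^3 grid at 1 mm with a
# carved infusate ellipsoid, a reference sphere well away from it, and a
# tumor filling most of the grid centre.
small_spec <- function(...) {
  defaults <- list(
    grid_shape = c(36L, 36L, 36L), spacing_mm = c(1, 1, 1),
    tumor_center_mm = c(18, 18, 18), tumor_radii_mm = c(13, 11, 10),
    infusate_center_mm = c(21, 21, 18), infusate_radii_mm = c(9, 8, 7),
    blocked_fraction = 0.2, delta_intensity = 50,
    drift_scale = 1.1, drift_offset = 15, noise_sigma = 5,
    reference_center_mm = c(7, 28, 8), reference_radii_mm = c(4, 4, 4)
  )
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

whole_grid_roi <- function(vol) {
  binary_mask(array(TRUE, dim = dim(vol$voxels)), spacing_mm = vol$spacing_mm,
              origin_mm = vol$origin_mm)
}
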