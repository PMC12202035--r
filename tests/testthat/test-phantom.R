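test_that("phantom construction satisfies its volume and disjointness contracts", {
  # uncarved 10 mm sphere: voxel count vs analytic 4/3*pi*10^3
  spec <- phantom_spec(grid_shape = c(36L, 36L, 36L),
                       tumor_center_mm = c(18, 18, 18), tumor_radii_mm = c(12, 12, 12),
                       infusate_center_mm = c(18, 18, 18),
                       infusate_radii_mm = c(10, 10, 10),
                       blocked_fraction = 0, noise_sigma = 0,
                       drift_scale = 1, drift_offset = 0,
                       reference_center_mm = c(5, 30, 5),
                       reference_radii_mm = c(4, 4, 4))
  ph <- generate_phantom(spec, seed = 1)
  analytic <- 4 / 3 * pi * 10^3 / 1000  # 4.19 cm^3
  # discretization error is bounded by the half-voxel surface shell but in
  # practice far smaller; 1% covers it comfortably at 1 mm voxels
  expect_equal(mask_volume_cm3(ph$vd_truth), analytic, tolerance = 0.01)

  # carved ellipsoid matches its analytic volume; the cut plane adds a
  # half-voxel discretization band on top of the curved surface, so the
  # bound is looser than for the plain sphere
  ph2 <- generate_phantom(small_spec(noise_sigma = 0), seed = 1)
  analytic2 <- 4 / 3 * pi * 9 * 8 * 7 * (1 - 0.2) / 1000
  expect_equal(mask_volume_cm3(ph2$vd_truth), analytic2, tolerance = 0.05)

  # reference structure and infusate ground truth never share a voxel
  for (seed in 1:3) {
    p <- generate_phantom(small_spec(), seed = seed)
    expect_false(any(p$vd_truth$voxels & p$reference_mask$voxels))
  }
})

test_that("phantom generation is deterministic in (spec, seed) and seeded noise differs", {
  spec <- small_spec()
  a <- generate_phantom(spec, seed = 42)
  b <- generate_phantom(spec, seed = 42)
  expect_identical(a$post_t1$voxels, b$post_t1$voxels)
  expect_identical(a$flair$voxels, b$flair$voxels)
  c <- generate_phantom(spec, seed = 43)
  expect_false(identical(a$post_t1$voxels, c$post_t1$voxels))
})

test_that("post image equals drift * pre + offset + delta inside truth (noise-free)", {
  spec <- small_spec(noise_sigma = 0)
  ph <- generate_phantom(spec, seed = 7)
  expected <- spec$drift_scale * ph$pre_t1$voxels + spec$drift_offset +
    spec$delta_intensity * ph$vd_truth$voxels
  expect_equal(ph$post_t1$voxels, expected, tolerance = 1e-12)

  # zero infusate signal: difference carries no tracer term
  ph0 <- generate_phantom(small_spec(noise_sigma = 0, delta_intensity = 0,
                                     drift_scale = 1, drift_offset = 0), seed = 7)
  expect_equal(max(abs(ph0$post_t1$voxels - ph0$pre_t1$voxels)), 0)
  expect_gt(sum(ph0$vd_truth$voxels), 0)  # truth mask still the carved ellipsoid
})

test_that("ellipsoids exceeding the grid are rejected with the offender named", {
  expect_error(phantom_spec(grid_shape = c(24L, 24L, 24L),
                            tumor_center_mm = c(12, 12, 12),
                            tumor_radii_mm = c(20, 10, 10),
                            infusate_center_mm = c(12, 12, 12),
                            infusate_radii_mm = c(5, 5, 5),
                            reference_center_mm = c(4, 20, 4),
                            reference_radii_mm = c(2, 2, 2)),
               "tumor ellipsoid exceeds")
  expect_error(phantom_spec(blocked_fraction = 1), "blocked_fraction")
})

test_that("cohort generator honours its distributions and flags", {
  # no loss to follow-up when lost_prob = 0
  ch <- generate_cohort(cohort_spec(n_patients = 50, lost_prob = 0, seed = 3))
  expect_false(any(ch$survival$status == "lost"))

  # empirical median of exponential survival times matches the parameter
  big <- generate_cohort(cohort_spec(n_patients = 10000, lost_prob = 0,
                                     followup_cutoff_months = Inf,
                                     survival_median_months = 14, seed = 11))
  expect_equal(median(big$survival$time_months), 14, tolerance = 0.5 / 14)

  # per-dose toxicity flags respect the probability vector
  ch0 <- generate_cohort(cohort_spec(n_patients = 20,
                                     dlt_prob_per_dose = c(0, 0),
                                     grade2_prob_per_dose = c(0, 0), seed = 5))
  expect_false(any(ch0$toxicity$dlt))
  expect_false(any(ch0$toxicity$grade2))

  # reproducible under the same seed
  again <- generate_cohort(cohort_spec(n_patients = 50, lost_prob = 0, seed = 3))
  expect_identical(ch$survival, again$survival)

  expect_error(cohort_spec(dlt_prob_per_dose = c(0.1, 0.2),
                           grade2_prob_per_dose = c(0.1)),
               "one entry per dose level")
})

test_that("synthetic infusion durations are positive with the configured moments", {
  inf <- generate_infusions(500, dose_level = 2, seed = 9)
  expect_true(all(inf$duration_min > 0))
  expect_equal(mean(inf$duration_min), 361.6, tolerance = 0.03)
  expect_true(all(inf$vi_mL == 3))
})

test_that("phantom NIfTI round trip preserves voxels and spacing", {
  ph <- generate_phantom(small_spec(), seed = 2)
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  back <- read_volume(file.path(dir, "post_t1.nii.gz"))
  expect_equal(back$voxels, ph$post_t1$voxels, tolerance = 1e-6)
  expect_equal(back$spacing_mm, ph$post_t1$spacing_mm)
  mask <- read_volume(file.path(dir, "vd_truth.nii.gz"), as_mask = TRUE)
  expect_masks_equal(mask, ph$vd_truth)
})
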