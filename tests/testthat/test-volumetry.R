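test_that("rigid registration recovers identity and known translations", {
  ph <- generate_phantom(small_spec(noise_sigma = 0), seed = 1)
  fixed <- ph$pre_t1

  # identical inputs: identity within 1e-6
  tr <- register_rigid(fixed, fixed)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-6)
  expect_equal(tr$translation_mm, c(0, 0, 0), tolerance = 1e-6)

  # content shifted by exactly 2 voxels along axis 1
  shifted <- fixed$voxels
  shifted[3:36, , ] <- fixed$voxels[1:34, , ]
  shifted[1:2, , ] <- fixed$voxels[1, , ]
  moving <- image_volume(shifted, fixed$spacing_mm)
  tr2 <- register_rigid(fixed, moving, refine = FALSE)
  expect_equal(tr2$translation_mm, c(2, 0, 0), tolerance = 0.1)

  # resampling under the recovered transform overlays the fixed image
  res <- resample_image(moving, tr2, fixed)
  interior <- fixed$voxels[4:33, 4:33, 4:33]
  expect_equal(res$voxels[4:33, 4:33, 4:33], interior, tolerance = 1e-8)
})

test_that("registration recovers a subvoxel translation under noise", {
  ph <- generate_phantom(small_spec(noise_sigma = 0), seed = 2)
  fixed <- ph$pre_t1
  true_t <- c(1.5, -1.0, 0.5)
  # build the moving image by sampling fixed at x + t (pull-back identity)
  tr_true <- rigid_transform(diag(3), -true_t)
  moving <- resample_image(fixed, tr_true, fixed)
  # ~2% noise relative to the signal scale
  set.seed(4)
  moving$voxels <- moving$voxels + rnorm(length(moving$voxels), 0, 2)
  tr <- register_rigid(fixed, moving)
  expect_equal(tr$translation_mm, true_t, tolerance = 0.5)
})

test_that("reference segmentation recovers the phantom structure from a seed", {
  ph <- generate_phantom(small_spec(noise_sigma = 0), seed = 1)
  ref <- segment_reference(ph$pre_t1, small_spec()$reference_center_mm,
                           intensity_window = c(114, 200))
  # matches ground truth up to surface voxels (texture modulates the rim)
  expect_gt(dice_coefficient(ref, ph$reference_mask), 0.95)

  expect_error(segment_reference(ph$pre_t1, small_spec()$reference_center_mm,
                                 intensity_window = c(300, 400)),
               "outside window")
})

test_that("normalization inverts a known affine drift exactly", {
  ph <- generate_phantom(small_spec(noise_sigma = 0, delta_intensity = 0,
                                    drift_scale = 1, drift_offset = 0), seed = 1)
  pre <- ph$pre_t1
  post <- image_volume(1.2 * pre$voxels + 30, pre$spacing_mm)
  nr <- normalize_post(pre, post, ph$reference_mask)
  expect_equal(nr$result$scale, 1 / 1.2, tolerance = 1e-9)
  expect_equal(nr$result$offset, -25, tolerance = 1e-9)
  expect_equal(nr$post_norm$voxels, pre$voxels, tolerance = 1e-9)
  expect_equal(nr$result$residual_sigma, 0, tolerance = 1e-9)

  # identity input: scale 1, offset 0
  nr2 <- normalize_post(pre, pre, ph$reference_mask)
  expect_equal(nr2$result$scale, 1, tolerance = 1e-12)
  expect_equal(nr2$result$offset, 0, tolerance = 1e-9)

  # mean and sd inside the reference match pre's after normalization
  ph3 <- generate_phantom(small_spec(), seed = 3)
  nr3 <- normalize_post(ph3$pre_t1, ph3$post_t1, ph3$reference_mask)
  sel <- ph3$reference_mask$voxels
  expect_equal(mean(nr3$post_norm$voxels[sel]), mean(ph3$pre_t1$voxels[sel]),
               tolerance = 1e-9)
  expect_equal(sd(nr3$post_norm$voxels[sel]), sd(ph3$pre_t1$voxels[sel]),
               tolerance = 1e-9)

  # constant reference region is degenerate
  flat <- image_volume(array(100, dim(pre$voxels)), pre$spacing_mm)
  expect_error(normalize_post(flat, flat, ph$reference_mask), "degenerate")
})

test_that("difference segmentation recovers ground truth exactly on noise-free phantoms", {
  spec <- small_spec(noise_sigma = 0)
  ph <- generate_phantom(spec, seed = 1)
  roi <- whole_grid_roi(ph$pre_t1)
  nr <- normalize_post(ph$pre_t1, ph$post_t1, ph$reference_mask)
  vd <- segment_vd(ph$pre_t1, nr$post_norm, roi,
                   residual_sigma = nr$result$residual_sigma)
  expect_true(attr(vd, "degenerate_threshold"))
  expect_masks_equal(vd, ph$vd_truth)

  # identical images give an empty mask
  vd0 <- segment_vd(ph$pre_t1, ph$pre_t1, roi, residual_sigma = 0)
  expect_equal(sum(vd0$voxels), 0L)

  # zero tracer signal: segmentation finds (approximately) nothing
  ph0 <- generate_phantom(small_spec(delta_intensity = 0), seed = 5)
  m0 <- measure_vd(ph0$pre_t1, ph0$post_t1, whole_grid_roi(ph0$pre_t1),
                   ph0$reference_mask)
  expect_lt(m0$report$vd_cm3, 0.1)
})

test_that("segmentation output is invariant to affine intensity drift of the post scan", {
  spec <- small_spec(noise_sigma = 0, drift_scale = 1, drift_offset = 0)
  ph <- generate_phantom(spec, seed = 1)
  roi <- whole_grid_roi(ph$pre_t1)
  base <- measure_vd(ph$pre_t1, ph$post_t1, roi, ph$reference_mask)
  for (ab in list(c(0.8, -30), c(1.0, 17.5), c(1.2, 30))) {
    corrupted <- image_volume(ab[1] * ph$post_t1$voxels + ab[2],
                              ph$post_t1$spacing_mm)
    m <- measure_vd(ph$pre_t1, corrupted, roi, ph$reference_mask)
    expect_masks_equal(m$vd_mask, base$vd_mask)
  }
})

test_that("increasing the threshold multiplier never enlarges the Vd mask", {
  ph <- generate_phantom(small_spec(), seed = 6)
  roi <- whole_grid_roi(ph$pre_t1)
  nr <- normalize_post(ph$pre_t1, ph$post_t1, ph$reference_mask)
  sizes <- sapply(c(1, 2, 3, 4, 6), function(k) {
    sum(segment_vd(ph$pre_t1, nr$post_norm, roi, k_sigma = k,
                   residual_sigma = nr$result$residual_sigma)$voxels)
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("noisy phantoms at SNR 10 are recovered with high Dice and small volume error", {
  errs <- numeric(5)
  for (i in 1:5) {
    ph <- generate_phantom(small_spec(), seed = 100 + i)  # delta 50, sigma 5
    m <- measure_vd(ph$pre_t1, ph$post_t1, whole_grid_roi(ph$pre_t1),
                    ph$reference_mask)
    expect_gt(dice_coefficient(m$vd_mask, ph$vd_truth), 0.90)
    truth <- mask_volume_cm3(ph$vd_truth)
    errs[i] <- abs(m$report$vd_cm3 - truth) / truth
  }
  expect_lt(mean(errs), 0.05)
})

test_that("tumor segmentation grows from a seed and includes cystic holes", {
  ph <- generate_phantom(small_spec(noise_sigma = 0), seed = 1)
  tum <- segment_tumor(ph$flair, small_spec()$tumor_center_mm, threshold = 150)
  expect_gt(dice_coefficient(tum, ph$tumor_truth), 0.97)

  # carve an interior dark cyst; hole filling must recover it as tumor
  flair2 <- ph$flair
  cyst <- rep(FALSE, length(flair2$voxels))
  dim(cyst) <- dim(flair2$voxels)
  cyst[22:25, 17:21, 17:21] <- TRUE  # interior, away from the seed voxel
  flair2$voxels[cyst] <- 60
  tum2 <- segment_tumor(flair2, small_spec()$tumor_center_mm, threshold = 150)
  expect_true(all(tum2$voxels[cyst]))

  expect_error(segment_tumor(ph$flair, small_spec()$tumor_center_mm,
                             threshold = 250), "below threshold")
})

test_that("mask volume converts voxel counts to cm^3", {
  m <- binary_mask(array(FALSE, c(10, 10, 10)))
  expect_equal(mask_volume_cm3(m), 0)
  m$voxels[1:1000] <- TRUE
  expect_equal(mask_volume_cm3(m), 1.0)
  m2 <- binary_mask(array(TRUE, c(10, 10, 10)), spacing_mm = c(2, 1, 0.5))
  expect_equal(mask_volume_cm3(m2), 1.0)
})
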