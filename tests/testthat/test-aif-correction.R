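test_that("activity balance solves the printed arithmetic", {
  expect_equal(solve_activity_balance(10, 20, 2, 15, 5), (200 - 30) / 5)
  expect_equal(solve_activity_balance(10, 20, 0, 0, 5), 10 * 20 / 5)
  expect_equal(solve_activity_balance(c(10, 5), 20, c(2, 1), 15, 5),
               c(34, 17))
  expect_error(solve_activity_balance(10, 20, 2, 15, 0), "positive")
  expect_error(solve_activity_balance(10, 10, 2, 15, 5), "smaller")
  expect_warning(out <- solve_activity_balance(1, 10, 5, 9, 2), "clipped")
  expect_equal(out, 0)
})

test_that("spill-out regions have correct volumes and disjoint masks", {
  img <- array(0, c(20, 20, 16))
  img[9:12, 9:13, 6:10] <- 100  # 4 x 5 x 5 = 100 voxels
  reg <- build_spillout_regions(img, voxel_size_mm = 4, aorta_volume_ml = 3)
  expect_equal(reg$spillout_volume_ml, 100 * 0.064)
  expect_false(any(reg$spillout_mask & reg$background_mask))
  expect_equal(reg$total_volume_ml,
               reg$spillout_volume_ml + reg$background_volume_ml)
  # background shell equals the brute-force Euclidean-distance count
  idx <- which(reg$spillout_mask, arr.ind = TRUE)
  all_idx <- which(array(TRUE, dim(img)), arr.ind = TRUE)
  d2 <- apply(all_idx, 1, function(p)
    min((p[1] - idx[, 1])^2 + (p[2] - idx[, 2])^2 + (p[3] - idx[, 3])^2))
  shell_oracle <- d2 > 0 & d2 <= 9
  expect_equal(sum(reg$background_mask), sum(shell_oracle))
  expect_equal(which(reg$background_mask), which(array(shell_oracle, dim(img))))
})

test_that("dilation at the image border and empty masks are rejected", {
  img <- array(0, c(10, 10, 10))
  img[1:2, 5, 5] <- 10
  expect_error(build_spillout_regions(img, 4, aorta_volume_ml = 0.1),
               "bounds")
  expect_error(build_spillout_regions(array(0, c(10, 10, 10)), 4,
                                      aorta_volume_ml = 1), "no activity")
})

test_that("blurred cylinder phantom conserves activity and recovers the AIF", {
  sch <- frame_schema(seq(0, by = 5, length.out = 24), rep(5, 24))
  aif <- simulate_aif(sch, peak_time_min = 0.5)
  ph <- simulate_spillout_phantom(aif, grid_dim = c(32, 32, 24),
                                  voxel_size_mm = 4, psf_fwhm_mm = 8)
  vox_ml <- 0.064
  # activity conservation per frame
  painted <- aif$values * sum(ph$aorta_mask) * vox_ml
  blurred <- vapply(seq_len(24), function(f) sum(ph$image[, , , f]) * vox_ml,
                    numeric(1))
  expect_equal(blurred, painted, tolerance = 1e-9)
  # psf = 0 leaves in-cylinder values exact
  ph0 <- simulate_spillout_phantom(aif, grid_dim = c(32, 32, 24),
                                   voxel_size_mm = 4, psf_fwhm_mm = 0)
  f_peak <- which.max(aif$values)
  expect_equal(mean(ph0$image[, , , f_peak][ph0$aorta_mask]),
               aif$values[f_peak])
  # uncorrected in-mask mean underestimates the true peak after blurring
  expect_lt(mean(ph$image[, , , f_peak][ph$aorta_mask]), aif$values[f_peak])

  # full correction: threshold ~0 captures the entire blur support, and the
  # activity balance then returns the true curve exactly
  summed <- ph$image[, , , 2]
  for (f in 3:7) summed <- summed + ph$image[, , , f]
  reg <- build_spillout_regions(summed, voxel_size_mm = 4,
                                threshold_frac = 1e-12,
                                aorta_mask = ph$aorta_mask)
  expect_equal(which(reg$spillout_mask), which(ph$support_mask))
  corr <- correct_aif(ph$image, reg, sch)
  truth <- aif$values
  ok <- truth > 1e-9
  expect_lt(max(abs(corr$corrected$values[ok] - truth[ok]) / truth[ok]), 1e-6)
  expect_equal(corr$corrected$values[!ok], truth[!ok], tolerance = 1e-9)
  # corrected peak is above the uncorrected in-mask peak (outward spill-out)
  expect_gt(max(corr$corrected$values), max(corr$original$values))
})

test_that("a zero-activity dynamic image corrects to a zero curve", {
  sch <- frame_schema(c(0, 5, 10), rep(5, 3))
  aif <- simulate_aif(sch)
  ph <- simulate_spillout_phantom(aif, grid_dim = c(24, 24, 20),
                                  length_vox = 6,
                                  voxel_size_mm = 4, psf_fwhm_mm = 6)
  summed <- ph$image[, , , 2] + ph$image[, , , 3]
  reg <- build_spillout_regions(summed, 4, threshold_frac = 1e-12,
                                aorta_mask = ph$aorta_mask)
  zero_img <- array(0, dim(ph$image))
  corr <- correct_aif(zero_img, reg, sch)
  expect_equal(corr$corrected$values, rep(0, 3))
})
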