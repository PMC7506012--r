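# Spatial transforms, resampling, registration and subtraction.

test_that("identity transform resamples to the identical volume", {
  ph <- generate_paired_ct(small_spec())
  id <- spatial_transform()
  out <- apply_transform(ph$pre, id)
  expect_equal(out$data, ph$pre$data, tolerance = 1e-12)
})

test_that("integer-voxel translation is an exact shift", {
  ph <- generate_paired_ct(small_spec())
  tr <- spatial_transform(translation = c(2, 0, -3))
  out <- apply_transform(ph$pre, tr)
  # mapping adds +2 mm in x: output voxel i takes input voxel i+2
  expect_equal(out$data[1:40, 10, 20], ph$pre$data[3:42, 10, 17])
  expect_true(all(is.na(out$data[47:48, , ])))  # out-of-field sentinel
  expect_true(all(is.na(out$data[, , 1:3])))
})

test_that("translation followed by its inverse restores the volume", {
  ph <- generate_paired_ct(small_spec())
  tr <- spatial_transform(translation = c(1.4, -0.6, 0.8))
  back <- spatial_transform(translation = -tr$translation)
  out <- apply_transform(apply_transform(ph$pre, tr), back)
  core <- !is.na(out$data)
  expect_lt(max(abs(out$data[core] - ph$pre$data[core])), 60)
  # interior (smooth neighbourhood) agrees tightly
  mid <- out$data[20:30, 20:30, 20:30] - ph$pre$data[20:30, 20:30, 20:30]
  expect_lt(stats::median(abs(mid)), 1)
})

test_that("subtraction is voxelwise, antisymmetric and grid-checked", {
  ph <- generate_paired_ct(small_spec())
  zero <- subtract(ph$pre, ph$pre)
  expect_true(all(zero$data == 0))
  s1 <- subtract(ph$delayed, ph$pre)
  s2 <- subtract(ph$pre, ph$delayed)
  expect_equal(s1$data, -s2$data)
  g <- ph$truth$geometry
  expect_equal(unique(s1$data[g$endo_mask]), 100)
  other <- ct_volume(array(0, c(10, 10, 10)))
  expect_error(subtract(ph$delayed, other), "grid")
})

test_that("self-registration returns the identity transform", {
  ph <- generate_paired_ct(reg_spec())
  tr <- register(ph$pre, ph$pre, mode = "rigid", normalize = "none")
  # displacement anywhere in the volume below 0.05 voxel (0.05 mm)
  xyz <- rbind(c(10, 10, 10), c(32, 32, 32), c(50, 20, 40))
  disp <- sqrt(rowSums((transform_map(tr, xyz) - xyz)^2))
  expect_lt(max(disp), 0.05)
})

test_that("rigid registration recovers applied transforms within 0.1 mm", {
  ph <- generate_paired_ct(reg_spec())
  img <- ph$delayed  # lesions make all six degrees of freedom identifiable
  myo_xyz <- grid_coords(img)[which(ph$truth$geometry$myo_mask), , drop = FALSE]
  myo_xyz <- myo_xyz[seq(1, nrow(myo_xyz), 50), ]
  cases <- list(
    spatial_transform(c(3, -2, 1), c(0, 0, 0), center = c(31.5, 31.5, 31.5)),
    spatial_transform(c(2, -1, 1), c(3, 0, -2), center = c(31.5, 31.5, 31.5)))
  for (applied in cases) {
    moved <- apply_transform(img, applied)
    moved$data[is.na(moved$data)] <- -20
    rec <- suppressWarnings(register(moved, img, mode = "rigid",
                                     normalize = "none"))
    resid <- transform_map(applied, transform_map(rec, myo_xyz)) - myo_xyz
    expect_lt(mean(sqrt(rowSums(resid^2))), 0.1)
  }
})

test_that("registration metric is invariant to a global HU offset", {
  ph <- generate_paired_ct(reg_spec())
  img <- ph$delayed
  applied <- spatial_transform(c(2.5, -1.5, 0.5), c(0, 0, 0),
                               center = c(31.5, 31.5, 31.5))
  moved <- apply_transform(img, applied)
  moved$data[is.na(moved$data)] <- -20
  shifted <- moved
  shifted$data <- shifted$data + 150
  r1 <- suppressWarnings(register(moved, img, mode = "rigid",
                                  normalize = "meanshift"))
  r2 <- suppressWarnings(register(shifted, img, mode = "rigid",
                                  normalize = "meanshift"))
  expect_lt(max(abs(r1$translation - r2$translation)), 0.05)
})

test_that("registration rejects non-overlapping volumes", {
  a <- ct_volume(array(0, c(10, 10, 10)), origin = c(0, 0, 0))
  b <- ct_volume(array(0, c(10, 10, 10)), origin = c(500, 500, 500))
  expect_error(register(a, b), "overlap")
})

test_that("deformable registration recovers the observable (boundary-normal)
           part of a smooth deformation and sharpens the subtraction", {
  spec <- phantom_spec(noise_sd = 0,
                       misalignment = list(translation = c(0, 0, 0),
                                           rotation = c(0, 0, 0),
                                           deform_amplitude = 2,
                                           deform_wavelength = 40))
  ph <- generate_paired_ct(spec)
  g <- ph$truth$geometry
  mis <- ph$truth$misalignment
  tr <- suppressWarnings(register(ph$delayed, ph$pre, mode = "deformable"))
  # endocardial-boundary voxels; analytic outward normal of the endo shell
  bm <- g$myo_mask & ctecv:::dilate6(g$endo_mask)
  sam <- grid_coords(ph$pre)[which(bm), , drop = FALSE]
  sam <- sam[seq(1, nrow(sam), 10), ]
  resid <- transform_map(mis, transform_map(tr, sam)) - sam
  ctr <- spec$lv_center
  L <- spec$long_axis_extent
  a_e <- spec$endo_radius
  c_e <- L - (spec$epi_radius - spec$endo_radius)
  zb <- ctr[3] + L / 2
  n <- cbind(2 * (sam[, 1] - ctr[1]) / a_e^2, 2 * (sam[, 2] - ctr[2]) / a_e^2,
             2 * (sam[, 3] - zb) / c_e^2)
  n <- n / sqrt(rowSums(n^2))
  expect_lt(mean(abs(rowSums(resid * n))), 0.5)
  # and the registered myocardial subtraction is strictly sharper
  aligned <- apply_transform(ph$delayed, tr, fixed = ph$pre)
  sd_reg <- stats::sd(subtract(aligned, ph$pre)$data[g$myo_mask], na.rm = TRUE)
  sd_unreg <- stats::sd(subtract(ph$delayed, ph$pre)$data[g$myo_mask])
  expect_lt(sd_reg, sd_unreg)
})
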