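# LV delineation, AHA-16 parcellation and the blood-pool ROI.

test_that("masks supplied as contours are used verbatim", {
  ph <- generate_paired_ct(small_spec())
  tg <- ph$truth$geometry
  g <- segment_lv(ph$pre, contours = list(endo = tg$endo_mask,
                                          epi = tg$epi_mask))
  expect_identical(g$endo_mask, tg$endo_mask)
  expect_identical(g$myo_mask, tg$myo_mask)
})

test_that("automatic segmentation reaches Dice >= 0.95 on a clean phantom", {
  ph <- generate_paired_ct(small_spec())
  tg <- ph$truth$geometry
  g <- segment_lv(ph$pre)
  expect_gte(dice(g$myo_mask, tg$myo_mask), 0.95)
  expect_gte(dice(g$endo_mask, tg$endo_mask), 0.95)
  # estimated long axis matches the analytic one
  expect_gt(abs(sum(g$long_axis * tg$long_axis)), 0.99)
})

test_that("featureless volumes raise a segmentation failure", {
  air <- ct_volume(array(-1000, c(24, 24, 24)))
  expect_error(segment_lv(air), "segmentation failure")
})

test_that("polyline contours rasterise to the enclosed discs", {
  ph <- generate_paired_ct(small_spec())
  # circular polygons approximating cavity/wall cross-sections on two slices
  circle <- function(cx, cy, r) {
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    list(x = cx + r * cos(th), y = cy + r * sin(th))
  }
  mkset <- function(r) lapply(c(24, 26), function(k) {
    c(list(slice = k), circle(23.5, 23.5, r))
  })
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(endo = mkset(6), epi = mkset(12)), tmp,
                       auto_unbox = TRUE, digits = NA)
  cont <- read_contours_json(tmp)
  g <- segment_lv(ph$pre, contours = cont)
  sl <- g$endo_mask[, , 24]
  ax <- (0:47)
  dd <- outer((ax - 23.5)^2, (ax - 23.5)^2, "+")
  expect_gt(dice(sl, dd <= 6^2), 0.95)
})

test_that("AHA parcellation partitions the wall with the stated structure", {
  ph <- generate_paired_ct(small_spec())
  g <- ph$truth$geometry
  counts <- tabulate(g$labels[g$labels > 0], 16)
  expect_true(all(counts > 0))
  # rotational symmetry: the 6 basal segments have equal counts within 2%
  basal <- counts[1:6]
  expect_lt((max(basal) - min(basal)) / mean(basal), 0.02)
  # every wall voxel between base and cap carries exactly one label
  u <- g$long_axis
  L <- sum((g$apex_mm - g$base_mm) * u)
  idx <- which(g$myo_mask)
  d <- dim(g$myo_mask)
  co <- cbind(((idx - 1) %% d[1]) * g$spacing[1],
              (((idx - 1) %/% d[1]) %% d[2]) * g$spacing[2],
              ((idx - 1) %/% (d[1] * d[2])) * g$spacing[3])
  s <- as.vector((co - matrix(g$base_mm, nrow(co), 3, byrow = TRUE)) %*% u) / L
  inside <- s >= 0 & s < 0.9
  expect_true(all((g$labels[idx] > 0) == inside))
})

test_that("rotating the reference angle permutes basal labels cyclically", {
  ph <- generate_paired_ct(small_spec())
  g0 <- ph$truth$geometry
  g60 <- parcellate_aha16(segment_lv(
    ph$pre, contours = list(endo = g0$endo_mask, epi = g0$epi_mask),
    ref_angle = 60))
  l0 <- g0$labels
  l60 <- g60$labels
  basal <- l0 >= 1 & l0 <= 6
  # advancing the reference by one sector relabels 2->1, 3->2, ..., 1->6;
  # sector boundaries are voxel-quantised so demand a dominant cyclic shift
  shifted <- ((l0[basal] - 2) %% 6) + 1
  agree <- mean(l60[basal] == shifted)
  expect_gt(agree, 0.95)
})

test_that("a voxel just past the reference angle gets label 1", {
  ph <- generate_paired_ct(small_spec())
  g <- ph$truth$geometry
  # basal-third wall voxel at small positive sector angle
  ctr <- c(23.5, 23.5)
  idx <- which(g$labels > 0 & g$labels <= 6)
  d <- dim(g$labels)
  xi <- ((idx - 1) %% d[1])
  yi <- (((idx - 1) %/% d[1]) %% d[2])
  # the in-plane frame anchors angle 0 at +x with the sector angle
  # increasing counterclockwise seen from the apex (-y in grid terms here)
  ang <- atan2(-(yi - ctr[2]), xi - ctr[1]) %% (2 * pi)
  near0 <- which(ang > 0.02 & ang < 0.3)
  expect_true(length(near0) > 0)
  expect_true(all(g$labels[idx[near0]] == 1))
})

test_that("parcellation is stable under voxel-size refinement", {
  coarse <- phantom_spec(noise_sd = 0, misalignment = NULL)
  fine <- phantom_spec(grid_shape = c(192, 192, 192),
                       spacing = c(0.5, 0.5, 0.5),
                       lv_center = coarse$lv_center,
                       noise_sd = 0, misalignment = NULL)
  g1 <- generate_paired_ct(coarse)$truth$geometry
  g2 <- generate_paired_ct(fine)$truth$geometry
  f1 <- tabulate(g1$labels[g1$labels > 0], 16) / sum(g1$labels > 0)
  f2 <- tabulate(g2$labels[g2$labels > 0], 16) / sum(g2$labels > 0)
  expect_lt(max(abs(f1 - f2) / f1), 0.02)
})

test_that("blood-pool ROI erosion honours the margin", {
  ph <- generate_paired_ct(small_spec())
  g <- ph$truth$geometry
  expect_identical(blood_pool_roi(g, 0), g$endo_mask)
  roi <- blood_pool_roi(g, 3)
  expect_true(all(roi[g$endo_mask] | !roi[g$endo_mask]))
  expect_true(all(g$endo_mask[roi]))
  # distance-transform oracle: every ROI voxel is >= 3 mm from non-cavity
  out_idx <- which(!g$endo_mask)
  d <- dim(roi)
  roi_idx <- which(roi)
  co_r <- cbind((roi_idx - 1) %% d[1], ((roi_idx - 1) %/% d[1]) %% d[2],
                (roi_idx - 1) %/% (d[1] * d[2]))
  co_o <- cbind((out_idx - 1) %% d[1], ((out_idx - 1) %/% d[1]) %% d[2],
                (out_idx - 1) %/% (d[1] * d[2]))
  # bounding filter keeps the pairwise check tractable
  keep <- co_o[, 1] >= min(co_r[, 1]) - 4 & co_o[, 1] <= max(co_r[, 1]) + 4 &
    co_o[, 2] >= min(co_r[, 2]) - 4 & co_o[, 2] <= max(co_r[, 2]) + 4 &
    co_o[, 3] >= min(co_r[, 3]) - 4 & co_o[, 3] <= max(co_r[, 3]) + 4
  co_o <- co_o[keep, , drop = FALSE]
  sam <- co_r[seq(1, nrow(co_r), length.out = min(200, nrow(co_r))), ,
              drop = FALSE]
  mind <- vapply(seq_len(nrow(sam)), function(i) {
    sqrt(min(colSums((t(co_o) - sam[i, ])^2)))
  }, numeric(1))
  expect_true(all(mind >= 3))
  expect_error(blood_pool_roi(g, 20), "margin")
})
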