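# The paired-CT phantom, perfusion curves, calcium volumes and cohort
# generator: ground-truth consistency and determinism.

test_that("noiseless zero-ECV phantom subtracts to blood enhancement only", {
  spec <- small_spec(true_ecv = rep(0, 16))
  ph <- generate_paired_ct(spec)
  diff <- ph$delayed$data - ph$pre$data
  g <- ph$truth$geometry
  expect_equal(unique(diff[g$endo_mask]), spec$delta_hu_blood)
  expect_true(all(diff[g$myo_mask] == 0))
})

test_that("segment enhancement encodes the inverted ECV relation", {
  ev <- rep(0.25, 16)
  ev[5] <- 0.30
  spec <- small_spec(hematocrit = 0.40, delta_hu_blood = 100, true_ecv = ev)
  ph <- generate_paired_ct(spec)
  # segment 5: DeltaHUm = 0.30 * 100 / 0.60 = 50 HU
  expect_equal(ph$truth$delta_hu_m[5], 50)
  diff <- ph$delayed$data - ph$pre$data
  seg5 <- ph$truth$geometry$labels == 5
  expect_equal(unique(round(diff[seg5], 10)), 50)
})

test_that("identical seeds give bit-identical phantoms", {
  spec <- small_spec(noise_sd = 8, seed = 42)
  a <- generate_paired_ct(spec)
  b <- generate_paired_ct(spec)
  expect_identical(a$pre$data, b$pre$data)
  expect_identical(a$delayed$data, b$delayed$data)
  c <- generate_paired_ct(small_spec(noise_sd = 8, seed = 43))
  expect_false(identical(a$pre$data, c$pre$data))
})

test_that("phantom validation rejects impossible geometry and parameters", {
  expect_error(small_spec(endo_radius = 14, epi_radius = 8), "endo_radius")
  expect_error(small_spec(hematocrit = 1.2), "hematocrit")
  expect_error(small_spec(true_ecv = rep(2, 16)), "true_ecv")
  expect_error(phantom_spec(grid_shape = c(32, 32, 32), endo_radius = 15,
                            epi_radius = 25, long_axis_extent = 60),
               "sizing error")
  expect_error(small_spec(endo_radius = 8, epi_radius = 14,
                          long_axis_extent = 5), "degenerate")
})

test_that("noiseless aligned phantom round-trips ECV to machine precision", {
  spec <- small_spec()
  ph <- generate_paired_ct(spec)
  tab <- ecv_segment_table(subtract(ph$delayed, ph$pre), ph$truth$geometry,
                           spec$hematocrit)
  expect_lt(max(abs(tab$ecv - spec$true_ecv)), 1e-6)
})

test_that("noise perturbs recovered ECV within the CLT bound", {
  spec <- small_spec(noise_sd = 10, seed = 7)
  ph <- generate_paired_ct(spec)
  g <- ph$truth$geometry
  tab <- ecv_segment_table(subtract(ph$delayed, ph$pre), g, spec$hematocrit,
                           threshold = Inf)
  # subtraction noise SD ~ 10*sqrt(2); segment mean SE = that / sqrt(n_vox);
  # allow 4 sigma, propagated through (1 - Hct) / DeltaHUb
  n_vox <- min(tabulate(g$labels[g$labels > 0], 16))
  bound <- 4 * 10 * sqrt(2) / sqrt(n_vox) * (1 - spec$hematocrit) /
    spec$delta_hu_blood
  expect_lt(max(abs(tab$ecv - spec$true_ecv)), bound)
})

test_that("perfusion curves encode MBF in their maximum upslope", {
  spec <- small_spec()
  p <- generate_perfusion_series(spec, true_mbf = rep(60, 16), dt = 1,
                                 arterial_peak = 200)
  # raw finite-difference slope: 60/100/60 * 200 = 2 HU/s
  expect_equal(max(diff(p$tissue[, 1])), 2, tolerance = 1e-12)
  # equal MBF in every segment -> identical noiseless curves
  expect_true(all(apply(p$tissue, 1, function(r) diff(range(r)) == 0)))
  # determinism under a fixed seed with noise
  a <- generate_perfusion_series(spec, noise_sd = 2)
  b <- generate_perfusion_series(spec, noise_sd = 2)
  expect_identical(a$tissue, b$tissue)
  expect_error(generate_perfusion_series(spec, dt = 0), "dt")
  expect_error(generate_perfusion_series(spec, true_mbf = rep(0, 16)),
               "positive")
})

test_that("calcium phantom respects the scoring threshold and truth list", {
  spec <- calcium_spec()
  empty <- generate_calcium_volume(spec, data.frame())
  expect_lt(max(empty$volume$data), 130)
  one <- generate_calcium_volume(
    spec, data.frame(x = 10, y = 10, slice = 3, area_mm2 = 4, peak_hu = 250))
  expect_length(one$truth$lesions, 1)
  expect_equal(one$truth$lesions[[1]]$area_mm2, 4)
  expect_equal(one$truth$lesions[[1]]$peak_hu, 250)
  two <- generate_calcium_volume(
    spec, data.frame(x = c(8, 28), y = c(8, 28), slice = c(2, 5),
                     area_mm2 = 4, peak_hu = 300))
  expect_length(two$truth$lesions, 2)
  expect_warning(
    generate_calcium_volume(
      spec, data.frame(x = c(10, 11), y = c(10, 10), slice = 3,
                       area_mm2 = 6, peak_hu = 250)),
    "overlap")
})

test_that("cohort generator matches its stated moments and correlation", {
  # independence: rho = 0 at large n
  p0 <- cohort_params(n_per_group = 4000, ecv_lavi_correlation = 0, seed = 3)
  co0 <- generate_cohort(p0)
  hd0 <- co0[co0$group == "HD", ]
  expect_lt(abs(cor(hd0$ecv, hd0$lavi)), 3 / sqrt(4000))
  # law of large numbers at the published HD parameters
  p <- cohort_params(n_per_group = 5000, seed = 4)
  co <- generate_cohort(p)
  hd <- co[co$group == "HD", ]
  expect_lt(abs(mean(hd$hematocrit) - 33.4), 0.2)
  expect_lt(abs(cor(hd$ecv, hd$lavi) - 0.54), 0.05)
  # determinism
  expect_identical(generate_cohort(p), generate_cohort(p))
  expect_error(cohort_params(n_per_group = 1), "n_per_group")
  expect_error(cohort_params(ecv_lavi_correlation = 1), "correlation")
})
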