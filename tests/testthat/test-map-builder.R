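calib_01 <- calibration_config(mm_per_pixel = 0.1, source_fps = 4,
                               binarize_threshold = 0.5,
                               sensor_positions_mm = c(5, 15))

test_that("binarize_frame thresholds silhouettes and flags degenerate frames", {
  fr <- matrix(1, 20, 60)
  m <- binarize_frame(fr, 0.5)
  expect_true(attr(m, "degenerate"))
  expect_false(any(m))
  # 40-pixel dark band on a light background
  fr <- matrix(1, 60, 80)
  fr[11:50, ] <- 0
  m <- binarize_frame(fr, 0.5)
  expect_false(attr(m, "degenerate"))
  truth <- matrix(FALSE, 60, 80); truth[11:50, ] <- TRUE
  expect_equal(dim(m), dim(truth))
  expect_identical(as.logical(m), as.logical(truth))
  expect_error(binarize_frame(matrix(numeric(0), 0, 0), 0.5), "non-empty")
  expect_error(binarize_frame(fr, 1.5), "\\[0, 1\\]")
})

test_that("extract_diameter_profile converts pixel extents to mm", {
  mask <- matrix(FALSE, 60, 80)
  mask[11:50, ] <- TRUE
  d <- extract_diameter_profile(mask, calib_01)
  expect_equal(as.vector(d), rep(4, 80))  # 40 px at 0.1 mm/px
  # empty mask: zeros with flags
  d0 <- extract_diameter_profile(matrix(FALSE, 10, 40), calib_01)
  expect_true(all(d0 == 0))
  expect_true(all(attr(d0, "empty_columns")))
  expect_error(extract_diameter_profile(matrix(FALSE, 40, 10), calib_01),
               "orientation")
})

test_that("build_diameter_map decimates by block averaging", {
  calib8 <- calibration_config(mm_per_pixel = 0.25, source_fps = 8,
                               target_fps = 4, binarize_threshold = 0.5)
  fr <- matrix(1, 40, 80); fr[11:26, ] <- 0   # 16 px = 4 mm band
  dmap <- build_diameter_map(rep(list(fr), 8), calib8)
  expect_equal(length(dmap$times_s), 4)
  expect_equal(diff(dmap$times_s[1:2]), 0.25)
  expect_true(all(abs(dmap$D - 4) < 1e-9))
  # 30 s at 4 Hz -> 120 samples
  dmap2 <- build_diameter_map(rep(list(fr), 120),
                              calibration_config(0.25, 4, 4, 0.5))
  expect_equal(length(dmap2$times_s), 120)
  expect_error(build_diameter_map(list(fr), calib8), "at least 2")
})

test_that("silhouette render -> rebuild recovers the generator truth", {
  cfg <- synth_config(length_mm = 80, duration_s = 40, boluses = list(
    bolus_spec(t0_s = 8, x0_mm = 25, speed_mm_s = 6.4, amplitude_mm = 5,
               travel_mm = 30, with_oral_contraction = FALSE,
               with_anal_relaxation = FALSE)),
    contractions = list(), noise_d_sd_mm = 0, noise_p_sd_mmhg = 0, seed = 3)
  prep <- generate_preparation(cfg)
  calib <- calibration_config(mm_per_pixel = 0.25, source_fps = 4,
                              binarize_threshold = 0.5,
                              sensor_positions_mm = prep$sensor_positions_mm)
  stack <- render_silhouette_stack(prep$dpmap$diameter, calib)
  rebuilt <- build_diameter_map(stack, calib)
  expect_equal(dim(rebuilt$D), dim(prep$dpmap$diameter$D))
  expect_lt(max(abs(rebuilt$D - prep$dpmap$diameter$D)), calib$mm_per_pixel)
})

test_that("pressure map interpolates linearly and is exact at sensors", {
  target <- structure(list(positions_mm = seq(0.5, 19.5, 1),
                           times_s = (0:19) * 0.25,
                           D = matrix(4, 20, 20)), class = "diameter_map")
  calib <- calibration_config(0.1, 4, 4, 0.5, sensor_positions_mm = c(5.5, 15.5))
  rec <- data.frame(time_s = (0:19) * 0.25, s1 = rep(0, 20), s2 = rep(10, 20))
  pmap <- build_pressure_map(rec, calib, target)
  mid <- which(target$positions_mm == 10.5)
  expect_equal(pmap$P[mid, 1], 5)                       # linear midpoint
  expect_equal(pmap$P[target$positions_mm == 5.5, 1], 0)
  expect_equal(pmap$P[target$positions_mm == 15.5, 1], 10)
  # held constant outside the sensor span
  expect_equal(pmap$P[1, 1], 0)
  expect_equal(pmap$P[20, 1], 10)
  # constant field is a fixed point
  rec3 <- data.frame(time_s = (0:19) * 0.25, s1 = rep(3, 20), s2 = rep(3, 20))
  expect_true(all(build_pressure_map(rec3, calib, target)$P == 3))
  expect_error(build_pressure_map(
    data.frame(time_s = c(0, 0.25, 0.2), s1 = 1:3, s2 = 1:3), calib, target),
    "monotone")
})

test_that("sensor-sampled synthetic pressure reconstructs the dense field", {
  pair <- default_pair()
  prep <- pair$control
  calib <- calibration_config(mm_per_pixel = 0.25, source_fps = 4,
                              binarize_threshold = 0.5,
                              sensor_positions_mm = prep$sensor_positions_mm)
  pmap <- build_pressure_map(prep$records, calib, prep$dpmap$diameter)
  si <- match(prep$sensor_positions_mm, pmap$positions_mm)
  expect_lt(max(abs(pmap$P[si, ] - t(as.matrix(prep$records[, -1])))), 1e-9)
  # smooth long-wavelength structure is recovered off-sensor too
  rmse <- sqrt(mean((pmap$P - prep$dpmap$pressure$P)^2))
  expect_lt(rmse, 0.1 * diff(range(prep$dpmap$pressure$P)))
})

test_that("bundling validates grids and the container round-trips", {
  prep <- quiet_prep()
  dp <- prep$dpmap
  expect_equal(dp$meta$duration_s,
               (length(dp$diameter$times_s) - 1) * 0.25)
  bad_p <- dp$pressure
  bad_p$times_s <- bad_p$times_s[-1]
  bad_p$P <- bad_p$P[, -1]
  expect_error(bundle_dpmap(dp$diameter, bad_p), "time")

  path <- tempfile(fileext = ".rds")
  save_container(dp, path)
  dp2 <- load_container(path)
  expect_identical(dp2$diameter$D, dp$diameter$D)
  expect_identical(dp2$pressure$P, dp$pressure$P)
  expect_identical(dp2$meta$condition, dp$meta$condition)
  # state maps keep their label vocabulary through the container
  smap <- classify_dpmap(dp)
  save_container(list(states = smap, vocab = MECH_STATES), path)
  back <- load_container(path)
  expect_identical(back$states$label, smap$label)
  expect_identical(back$vocab, MECH_STATES)
  # corrupted file: clean error
  writeLines("not a container", path)
  expect_error(load_container(path), "container")
})
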