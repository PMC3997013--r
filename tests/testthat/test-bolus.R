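# diameter map with an analytic Gaussian bump translating at speed v
bump_dmap <- function(nx = 120, nt = 160, A = 5, v = 8, x0 = 25, t0 = 3,
                      sigma = 10, base = 3) {
  tt <- (seq_len(nt) - 1) * 0.25
  X <- seq_len(nx) - 0.5
  D <- matrix(base, nx, nt)
  for (j in seq_len(nt)) {
    if (tt[j] < t0) next
    xc <- x0 + v * (tt[j] - t0)
    if (xc > nx - 20) break
    D[, j] <- base + A * exp(-(X - xc)^2 / (2 * sigma^2))
  }
  structure(list(positions_mm = X, times_s = tt, D = D),
            class = "diameter_map")
}

test_that("bolus detection applies the dilation and persistence rules", {
  flat <- structure(list(positions_mm = 1:50, times_s = (0:40) * 0.25,
                         D = matrix(4, 50, 41)), class = "diameter_map")
  expect_length(detect_boluses(flat), 0)
  # a 1-frame 5 mm bump is rejected by the 0.5 s persistence rule
  D <- matrix(3, 50, 41); D[20:26, 10] <- 8
  one <- structure(list(positions_mm = 1:50, times_s = (0:40) * 0.25,
                        D = D), class = "diameter_map")
  expect_length(detect_boluses(one), 0)
  # the same bump sustained for 3 frames (0.5 s span) is kept
  D[20:26, 10:12] <- 8
  three <- structure(list(positions_mm = 1:50, times_s = (0:40) * 0.25,
                          D = D), class = "diameter_map")
  expect_length(detect_boluses(three), 1)
})

test_that("tracked edges match the analytic 2 mm contour", {
  dmap <- bump_dmap()
  bol <- detect_boluses(dmap)
  expect_length(bol, 1)
  tr <- bol[[1]]$track
  # analytic truth: baseline is exactly 3 (bump absent most of the time),
  # so the 2 mm contour sits at xc +- sigma*sqrt(2*log(A/2))
  w <- 10 * sqrt(2 * log(5 / 2))
  for (r in seq_len(nrow(tr))) {
    xc <- 25 + 8 * (tr$time_s[r] - 3)
    expect_lt(abs(tr$oral_edge_mm[r] - (xc - w)), 2)
    expect_lt(abs(tr$anal_edge_mm[r] - (xc + w)), 2)
    # edge containment: dilation just outside the edges is at threshold
    expect_gt(tr$max_dilation_mm[r], 2)
  }
  expect_true(all(tr$anal_edge_mm > tr$oral_edge_mm))
})

test_that("speed estimation recovers seeded speeds and assigns bins", {
  # static transient bump: stationary (a permanent bump would be baseline)
  D <- matrix(3, 60, 60)
  D[25:35, 10:50] <- 3 + 5 * exp(-((25:35) - 30)^2 / 18)
  static <- structure(list(positions_mm = 1:60, times_s = (0:59) * 0.25,
                           D = D), class = "diameter_map")
  b <- estimate_speed(detect_boluses(static)[[1]])
  expect_lt(abs(b$speed_mm_s), 0.5)
  expect_equal(b$speed_bin, "stationary")
  # moving bumps at 1, 5, 8 mm/s land in slow / mid / fast
  for (case in list(c(1, NA), c(5, NA), c(8, NA))) {
    v <- case[1]
    dmap <- bump_dmap(v = v, nt = if (v < 3) 400 else 160)
    b <- estimate_speed(detect_boluses(dmap)[[1]])
    expect_equal(b$speed_mm_s, v, tolerance = 0.1 * v + 0.05)
    expect_equal(b$speed_bin,
                 if (v > 7) "fast" else if (v > 3) "mid" else "slow")
  }
  expect_error(estimate_speed(structure(list(track = data.frame(time_s = 1)),
                                        class = "bolus")), "3 frames")
})

test_that("state profiles normalise and respect map boundaries", {
  dmap <- bump_dmap()
  bol <- lapply(detect_boluses(dmap), estimate_speed)
  grp <- matrix("other", 120, 160)
  smap <- structure(list(positions_mm = dmap$positions_mm,
                         times_s = dmap$times_s,
                         label = matrix(11L, 120, 160), group = grp,
                         trend_D = matrix(2L, 120, 160),
                         trend_P = matrix(2L, 120, 160)),
                    class = "mech_state_map")
  prof <- state_profile(bol, smap, bin = "fast")
  expect_true(all(abs(prof$frac_contraction + prof$frac_relaxation +
                        prof$frac_other - 1) < 1e-12))
  expect_true(all(prof$frac_contraction == 0))
  expect_error(state_profile(bol, smap, bin = "stationary"), "no boluses")
  # random-point control: deterministic given the seed
  p1 <- random_point_control(smap, 50, seed = 4)
  p2 <- random_point_control(smap, 50, seed = 4)
  expect_identical(p1, p2)
  expect_true(all(p1$frac_contraction == 0))
})

test_that("dilation and length relations compute the stated proportions", {
  dmap <- bump_dmap()
  bol <- lapply(detect_boluses(dmap), estimate_speed)
  grp <- matrix("other", 120, 160)
  # paint relaxation in the anal flank of the tracked bolus
  tr <- bol[[1]]$track
  for (r in seq_len(nrow(tr))) {
    idx <- round(tr$anal_edge_mm[r]) + (2:10)
    grp[idx[idx <= 120], tr$time_idx[r]] <- "active_relaxation"
  }
  smap <- structure(list(positions_mm = dmap$positions_mm,
                         times_s = dmap$times_s,
                         label = matrix(11L, 120, 160), group = grp,
                         trend_D = matrix(2L, 120, 160),
                         trend_P = matrix(2L, 120, 160)),
                    class = "mech_state_map")
  curve <- dilation_relaxation_curve(bol, smap)
  expect_true(all(curve$proportion[curve$n > 0] == 1))
  # length test needs both classes
  expect_error(length_relaxation_test(bol, smap), "both length classes")
  # arithmetic: 3 of 4 short boluses with relaxation -> 0.75
  fake <- function(len, rel) structure(list(
    track = data.frame(time_idx = 1, time_s = 0.25, oral_edge_mm = 10,
                       anal_edge_mm = 10 + len, length_mm = len,
                       max_dilation_mm = 5),
    max_dilation_mm = 5, max_length_mm = len, speed_mm_s = 8,
    speed_bin = "fast"), class = "bolus")
  grp2 <- matrix("other", 120, 160)
  grp2[21:29, 1] <- "active_relaxation"  # anal flank of the short boluses
  smap2 <- smap; smap2$group <- grp2
  bl <- c(replicate(4, fake(8, TRUE), simplify = FALSE),
          replicate(2, fake(30, TRUE), simplify = FALSE))
  # one short bolus moved away so its flank misses the relaxation
  bl[[4]]$track$oral_edge_mm <- 60; bl[[4]]$track$anal_edge_mm <- 68
  res <- length_relaxation_test(bl, smap2)
  expect_equal(res$proportion_short, 0.75)
  expect_equal(unname(res$table["short", "relaxation"]), 3)
  expect_s3_class(res$test, "test_result")
})

test_that("sensor-pitch binning reproduces block averages exactly", {
  D <- matrix(rep(1:40, times = 20), 40, 20)
  dmap <- structure(list(positions_mm = seq(0.5, 39.5, 1),
                         times_s = (0:19) * 0.25, D = D),
                    class = "diameter_map")
  b <- bin_diameter(dmap, 10)
  expect_equal(nrow(b$D), 4)
  expect_equal(b$D[, 1], c(5.5, 15.5, 25.5, 35.5))
  # constant fixture: averaging is exact
  Dc <- matrix(7, 40, 20)
  dmc <- dmap; dmc$D <- Dc
  expect_true(all(bin_diameter(dmc, 10)$D == 7))
})
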