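test_that("quiescence model has its closed-form values and shape", {
  expect_equal(quiescence_probability(0), 1)
  expect_equal(quiescence_probability(1), exp(-0.5))
  expect_equal(quiescence_probability(-1), exp(-0.5))
  expect_equal(quiescence_probability(3), quiescence_probability(-3))
  expect_equal(quiescence_probability(3), exp(-4.5), tolerance = 1e-12)
  z <- seq(0, 6, length.out = 1000)
  g <- quiescence_probability(z)
  expect_true(all(diff(g) < 0))
  expect_true(all(g > 0 & g <= 1))
  expect_error(quiescence_probability(Inf), "finite")
})

test_that("derivatives normalise by the quiescence constants", {
  nx <- 4; nt <- 40
  # diameter falling at 0.4 mm/s -> zD = -1; pressure rising 6 mmHg/s -> zP = 2
  tt <- (seq_len(nt) - 1) * 0.25
  D <- matrix(rep(10 - 0.4 * tt, each = nx), nx)
  P <- matrix(rep(2 + 6 * tt, each = nx), nx)
  dv <- compute_derivatives(toy_dpmap(D, P), smooth_frames = 5)
  interior <- 6:(nt - 5)
  expect_equal(unname(dv$zD[2, interior]), rep(-1, length(interior)),
               tolerance = 1e-9)
  expect_equal(unname(dv$zP[3, interior]), rep(2, length(interior)),
               tolerance = 1e-9)
  # constant input -> all-zero derivatives
  dv0 <- compute_derivatives(toy_dpmap(matrix(5, nx, nt), matrix(3, nx, nt)))
  expect_true(all(dv0$zD == 0) && all(dv0$zP == 0))
  expect_error(compute_derivatives(toy_dpmap(D, P), smooth_frames = 4), "smooth_frames")
})

test_that("trend decoding matches exhaustive enumeration on 100 seeded series", {
  params <- trend_hmm_params()
  expect_equal(unname(rowSums(params$A)), rep(1, 3))
  set.seed(123)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    z <- runif(n, -4, 4)
    dec <- as.integer(decode_trend(z, params))
    expect_equal(dec, unname(viterbi_enumerate(z, params)),
                 info = paste("series", i))
  }
})

test_that("trend decoding smooths isolated spikes and finds sustained runs", {
  expect_true(all(decode_trend(rep(0, 30)) == "quiescent"))
  # single-frame spike absorbed by the sticky chain
  z <- rep(0, 9); z[5] <- 3
  expect_true(all(decode_trend(z) == "quiescent"))
  # twenty sustained +3 values flanked by zeros form one rising run
  z <- c(rep(0, 10), rep(3, 20), rep(0, 10))
  dec <- decode_trend(z)
  r <- rle(as.character(dec))
  expect_equal(r$values[r$values != "quiescent"], "rising")
  expect_equal(sum(r$values == "rising"), 1)
  expect_error(decode_trend(c(0, NA, 1)), "finite")
})

test_that("raising p_stay never increases the number of trend transitions", {
  set.seed(21)
  for (i in 1:20) {
    z <- cumsum(rnorm(60, sd = 1.2))
    z <- z - mean(z)
    n_trans <- sapply(c(0.6, 0.8, 0.95, 0.99), function(p) {
      dec <- decode_trend(z, trend_hmm_params(p_stay = p))
      sum(diff(as.integer(dec)) != 0)
    })
    expect_true(all(diff(n_trans) <= 0))
  }
})

test_that("the decision table assigns the twelve states as defined", {
  # grids: one position per (trend_D, trend_P, level) combination
  combos <- expand.grid(tD = 1:3, tP = 1:3, dist = c(FALSE, TRUE))
  n <- nrow(combos)
  lv <- structure(list(positions_mm = seq_len(n), times_s = 0,
                       rho = matrix(combos$dist * 1, n, 1),
                       distended = matrix(combos$dist, n, 1)),
                  class = "diameter_level_field")
  smap <- classify_states(matrix(combos$tD, n, 1), matrix(combos$tP, n, 1), lv)
  got <- MECH_STATES[smap$label[, 1]]
  pick <- function(tD, tP, dist) got[combos$tD == tD & combos$tP == tP &
                                       combos$dist == dist]
  # pressure rises with no diameter change on an occluded gut: a squeeze
  expect_equal(pick(2, 3, FALSE), "occluded_isometric_contraction")
  # both rising: content arriving against downstream resistance
  expect_equal(pick(3, 3, FALSE), "passive_dilation")
  expect_equal(pick(3, 3, TRUE), "passive_dilation")
  expect_equal(pick(2, 2, TRUE), "distended_quiescence")
  expect_equal(pick(2, 2, FALSE), "occluded_quiescence")
  expect_equal(pick(1, 3, TRUE), "auxotonic_contraction")
  expect_equal(pick(1, 2, FALSE), "isotonic_contraction")
  expect_equal(pick(1, 1, TRUE), "passive_shortening")
  expect_equal(pick(3, 1, FALSE), "auxotonic_relaxation")
  expect_equal(pick(3, 2, TRUE), "isotonic_relaxation")
  expect_equal(pick(2, 1, FALSE), "occluded_isometric_relaxation")
  expect_equal(pick(2, 3, TRUE), "distended_isometric_pressure_increase")
  expect_equal(pick(2, 1, TRUE), "distended_isometric_pressure_decrease")
})

test_that("every cell gets exactly one label and occupancy sums to one", {
  an <- default_analysis()
  smap <- an$smap
  expect_true(all(smap$label %in% 1:12))
  occ <- state_occupancy(smap)
  expect_equal(sum(occ), 1, tolerance = 1e-12)
  g <- attr(occ, "group_occupancy")
  expect_equal(sum(g), 1, tolerance = 1e-12)
  # fixed partition: 3 contraction, 2 relaxation, 7 other
  expect_equal(sum(STATE_GROUPS == "active_contraction"), 3)
  expect_equal(sum(STATE_GROUPS == "active_relaxation"), 2)
  expect_equal(sum(STATE_GROUPS == "other"), 7)
  expect_equal(length(MECH_STATES), 12)
  # sign coherence: auxotonic contraction cells have D falling, P rising
  aux <- smap$label == which(MECH_STATES == "auxotonic_contraction")
  expect_true(all(smap$trend_D[aux] == 1L))
  expect_true(all(smap$trend_P[aux] == 3L))
})

test_that("diameter level split uses the robust per-position range", {
  set.seed(4)
  D <- matrix(runif(200, 2, 8), 4, 50)
  dmap <- structure(list(positions_mm = 1:4, times_s = (0:49) * 0.25, D = D),
                    class = "diameter_map")
  lv <- diameter_levels(dmap)
  expect_true(all(lv$rho >= 0 & lv$rho <= 1))
  expect_equal(lv$distended, lv$rho >= 0.5)
  # constant row treated as occluded
  D2 <- D; D2[2, ] <- 5
  lv2 <- diameter_levels(structure(list(positions_mm = 1:4,
                                        times_s = (0:49) * 0.25, D = D2),
                                   class = "diameter_map"))
  expect_true(all(!lv2$distended[2, ]))
})

test_that("labels on noiseless block-constant trends match analytic truth", {
  # piecewise-linear diameter/pressure with block-constant derivatives
  nt <- 120; nx <- 3
  tt <- (seq_len(nt) - 1) * 0.25
  d_rate <- rep(c(0, -1.2, 0, 1.2, 0), each = 24)   # mm/s blocks
  p_rate <- rep(c(0, 9, 0, -9, 0), each = 24)       # mmHg/s blocks
  D <- matrix(rep(6 + cumsum(d_rate) * 0.25, each = nx), nx)
  P <- matrix(rep(10 + cumsum(p_rate) * 0.25, each = nx), nx)
  smap <- classify_dpmap(toy_dpmap(D, P))
  truth_tD <- ifelse(d_rate / 0.4 < -1, 1L, ifelse(d_rate / 0.4 > 1, 3L, 2L))
  truth_tP <- ifelse(p_rate / 3 < -1, 1L, ifelse(p_rate / 3 > 1, 3L, 2L))
  interior <- which(seq_len(nt) %% 24 > 4 & seq_len(nt) %% 24 < 21)
  acc <- mean(smap$trend_D[2, interior] == truth_tD[interior] &
                smap$trend_P[2, interior] == truth_tP[interior])
  expect_gte(acc, 0.95)
})
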