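#' Specify one propelled bolus for the synthetic generator
#'
#' A bolus is a Gaussian dilation bump translated analward at constant
#' speed, with pressure coupled to the dilation (fluid arriving raises
#' local pressure). Optionally accompanied by an oral active-contraction
#' band (squeeze grading down toward the bolus, with a synchronous pressure
#' wave) and an anal active-relaxation band (dilation ramp ahead of the
#' bolus with a small pressure dip).
#'
#' @param t0_s Onset time (s).
#' @param x0_mm Initial bolus centre (mm).
#' @param speed_mm_s Propulsion speed (mm/s, positive = analward).
#' @param amplitude_mm Peak dilation above the occluded baseline (mm).
#' @param sigma_mm Spatial standard deviation of the bump (mm).
#' @param travel_mm Distance travelled before the bolus dissipates (mm).
#' @param duration_s Active duration for stationary boluses (used when
#'   `speed_mm_s` is 0).
#' @param with_oral_contraction Attach the oral squeeze band?
#' @param with_anal_relaxation Attach the anal relaxation band?
#' @param contraction_depth_mm,contraction_pressure_mmhg Oral band depth
#'   and pressure-wave height.
#' @param relaxation_amp_mm,relaxation_dip_mmhg Anal band dilation and
#'   pressure dip.
#' @return A `bolus_spec` list.
#' @export
bolus_spec <- function(t0_s, x0_mm, speed_mm_s, amplitude_mm,
                       sigma_mm = 10, travel_mm = 70, duration_s = 30,
                       with_oral_contraction = TRUE,
                       with_anal_relaxation = TRUE,
                       contraction_depth_mm = 2.5,
                       contraction_pressure_mmhg = 40,
                       relaxation_amp_mm = 1.2,
                       relaxation_dip_mmhg = 5) {
  stopifnot(amplitude_mm >= 0, sigma_mm > 0, speed_mm_s >= 0)
  structure(as.list(environment()), class = "bolus_spec")
}

#' Specify one standalone active contraction
#'
#' A Gaussian squeeze (with synchronous pressure pulse) that may be
#' stationary (a non-propagating contraction) or travel analward (a
#' propagating contraction band). An optional slow pre-dilation bump peaks
#' at the moment of initiation: it ramps up and down slowly enough to stay
#' below the quiescence scale, so it offsets diameter without itself
#' registering as activity.
#'
#' @param t0_s Initiation time (s).
#' @param x0_mm Initiation site (mm).
#' @param speed_mm_s Travel speed (0 = stationary).
#' @param travel_mm Travel distance (0 = stationary).
#' @param depth_mm Squeeze depth (mm).
#' @param sigma_mm Spatial standard deviation of the squeeze (mm).
#' @param pressure_mmhg Pressure pulse height (mmHg).
#' @param duration_s Per-point squeeze duration (s); the field's typical
#'   value is about 4 s.
#' @param pre_dilation_mm Amplitude of the slow pre-dilation bump (mm).
#' @param pre_sigma_mm Spatial spread of the pre-dilation bump.
#' @return A `contraction_spec` list.
#' @export
contraction_spec <- function(t0_s, x0_mm, speed_mm_s = 0, travel_mm = 0,
                             depth_mm = 2, sigma_mm = 5,
                             pressure_mmhg = 12, duration_s = 4,
                             pre_dilation_mm = 0, pre_sigma_mm = 15) {
  stopifnot(depth_mm >= 0, sigma_mm > 0)
  structure(as.list(environment()), class = "contraction_spec")
}

#' Configuration of a synthetic preparation
#'
#' Defines the study conditions the generator emulates: a 25 cm fluid-filled
#' preparation mapped at 4 Hz and 1 mm, a 3 mm occluded baseline (the
#' catheter width), propelled boluses with polarised oral
#' contraction / anal relaxation bands, sparse sensor pressures at 10 mm
#' pitch, low-amplitude rhythmic myogenic ripple, and additive noise.
#'
#' @param length_mm Preparation length (default 250).
#' @param duration_s Recording duration (default 600).
#' @param dx_mm,fps Map grid (defaults 1 mm, 4 Hz).
#' @param occluded_diameter_mm Occluded diameter (default 3, the catheter
#'   width): a hard silhouette floor, since the gut cannot appear narrower
#'   than the indwelling catheter.
#' @param resting_tone_mm How far above the catheter the resting gut sits
#'   (default 0.8 mm); the myogenic ripple rides on this tone.
#' @param baseline_pressure_mmhg Resting intraluminal pressure (default 2).
#' @param boluses List of [bolus_spec()]s.
#' @param contractions List of [contraction_spec()]s.
#' @param myogenic_amp_mm,myogenic_freq_hz,myogenic_wavelength_mm,myogenic_pressure_mmhg
#'   Myogenic travelling-ripple parameters (defaults 0.3 mm, 0.25 Hz,
#'   60 mm, 0.2 mmHg).
#' @param ttx_myogenic_scale Myogenic amplitude multiplier under TTX
#'   (default 4/3): removing tonic neural inhibition modestly disinhibits
#'   the pacemaker-driven ripple.
#' @param pressure_coupling Passive pressure rise per mm of bolus dilation
#'   (mmHg/mm, default 2).
#' @param noise_d_sd_mm,noise_p_sd_mmhg Additive Gaussian noise SDs
#'   (defaults 0.05 mm, 0.2 mmHg).
#' @param sensor_pitch_mm Manometry sensor spacing (default 10).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(length_mm = 250, duration_s = 600,
                         dx_mm = 1, fps = 4,
                         occluded_diameter_mm = 3,
                         resting_tone_mm = 0.8,
                         baseline_pressure_mmhg = 6,
                         boluses = default_bolus_set(),
                         contractions = default_contraction_set(),
                         myogenic_amp_mm = 0.3,
                         myogenic_freq_hz = 0.25,
                         myogenic_wavelength_mm = 60,
                         myogenic_pressure_mmhg = 0.2,
                         ttx_myogenic_scale = 4 / 3,
                         pressure_coupling = 2,
                         noise_d_sd_mm = 0.05,
                         noise_p_sd_mmhg = 0.2,
                         sensor_pitch_mm = 10,
                         seed = 1) {
  structure(as.list(environment()), class = "synth_config")
}

#' Default seeded event sets of the synthetic preparation
#'
#' Twelve propelled boluses at the typical propagation speed (6.4 mm/s),
#' amplitudes cycling 3-6 mm, each with an oral contraction band; anal
#' relaxation attaches to the larger boluses (amplitude >= 4 mm), mirroring
#' the diameter dependence of anal inhibition. Plus six stationary
#' non-propagating contractions with modest pre-dilation.
#' @return List of specs.
#' @export
default_bolus_set <- function() {
  lapply(0:11, function(k)
    bolus_spec(t0_s = 25 + 48 * k,
               x0_mm = 85 + 15 * (k %% 4),
               speed_mm_s = 6.4,
               amplitude_mm = 3 + (k %% 4),
               travel_mm = 70,
               with_anal_relaxation = (3 + (k %% 4)) >= 4))
}

#' @rdname default_bolus_set
#' @export
default_contraction_set <- function() {
  lapply(0:5, function(k)
    contraction_spec(t0_s = 63 + 96 * k,
                     x0_mm = 60 + 30 * (k %% 3),
                     depth_mm = 2, sigma_mm = 5, duration_s = 4,
                     pre_dilation_mm = 1.5))
}

# linear ramp clamped to [0, 1]
clamp01 <- function(u) pmin(pmax(u, 0), 1)

# rectangular binary dilation of a logical (position x time) matrix
dilate_mask <- function(M, dpos, dtime) {
  out <- M
  nr <- nrow(M); nc <- ncol(M)
  for (di in -dpos:dpos) for (dj in -dtime:dtime) {
    if (di == 0 && dj == 0) next
    sr <- max(1, 1 + di):min(nr, nr + di)
    tr <- max(1, 1 - di):min(nr, nr - di)
    sc <- max(1, 1 + dj):min(nc, nc + dj)
    tc <- max(1, 1 - dj):min(nc, nc - dj)
    out[sr, sc] <- out[sr, sc] | M[tr, tc]
  }
  out
}

# raised-cosine on/off envelope over [t0, t1] with `ramp`-second shoulders
rc_env <- function(t, t0, t1, ramp = 1) {
  up <- clamp01((t - t0) / ramp)
  dn <- clamp01((t1 - t) / ramp)
  e <- pmin(up, dn)
  0.5 * (1 - cos(pi * e))
}

# slow symmetric envelope for pre-dilation: rise `rise`, hold `hold`, fall
# `rise`; slow enough that the ramp alone stays below the quiescence scale
slow_env <- function(t, t_peak, rise = 24, hold = 2) {
  u <- ifelse(t < t_peak,
              clamp01((t - (t_peak - rise)) / rise),
              ifelse(t <= t_peak + hold, 1,
                     clamp01(((t_peak + hold + rise) - t) / rise)))
  0.5 * (1 - cos(pi * u))
}

# oral contraction band shape in bolus-edge coordinate s = x - oral_edge:
# linear squeeze ramp over the 40 mm oral of the edge (constant squeeze
# rate when moving), then linear recovery further orally
band_g <- function(s) clamp01((5 - s) / 40) * clamp01((s + 65) / 30)
band_h <- function(s) clamp01((10 - s) / 60) * clamp01((s + 80) / 25)
# anal relaxation ramp in s2 = x - anal_edge: grows as the bolus approaches,
# zero-offset near the edge so the 2 mm contour is not displaced; hands
# over to the bolus bump after passage
relax_q <- function(s2) ifelse(s2 >= 0, clamp01((28 - s2) / 20),
                               clamp01(1 + s2 / 10))

#' Generate a ground-truthed synthetic preparation
#'
#' Builds the diameter and pressure fields from the configured components
#' (occluded baseline, bolus bumps with pressure coupling, oral squeeze
#' bands, anal relaxation bands, slow pre-dilations, myogenic ripple,
#' noise), returns them as a `dpmap` together with sensor-sampled pressure
#' records and a complete ground truth: twelve-state labels and groups
#' derived from the noiseless analytic derivatives, per-frame bolus edges,
#' initiation points, and masks separating neurogenic-event support from
#' pure myogenic activity.
#'
#' @param config A [synth_config()].
#' @param condition Stored condition tag (default "synthetic").
#' @return List with elements `dpmap`, `truth`, `records` (data frame
#'   `time_s, s01..sNN`), `sensor_positions_mm`, `config`.
#' @export
generate_preparation <- function(config, condition = "synthetic") {
  set.seed(config$seed)
  nx <- round(config$length_mm / config$dx_mm)
  nt <- round(config$duration_s * config$fps) + 1
  X <- (seq_len(nx) - 0.5) * config$dx_mm
  tms <- (seq_len(nt) - 1) / config$fps
  resting <- config$occluded_diameter_mm + (config$resting_tone_mm %||% 0.8)
  D0 <- matrix(resting, nx, nt)
  P0 <- matrix(config$baseline_pressure_mmhg, nx, nt)
  contraction_field <- matrix(0, nx, nt)
  relaxation_field <- matrix(0, nx, nt)
  # event contributions to the noiseless field, accumulated separately so
  # the ground truth can distinguish event-driven from pure-myogenic cells
  Dev <- matrix(0, nx, nt)
  Pev <- matrix(0, nx, nt)
  truth_boluses <- list()
  truth_inits <- list()

  for (b in config$boluses) {
    v <- b$speed_mm_s
    t1 <- if (v > 0) b$t0_s + b$travel_mm / v else b$t0_s + b$duration_s
    if (b$x0_mm < 0 || b$x0_mm + (if (v > 0) b$travel_mm else 0) > config$length_mm)
      stop("bolus travels outside the preparation")
    fr <- which(tms >= b$t0_s - 2 & tms <= t1 + 12)
    # rapid onset; gradual dissipation en route (the bolus spreads and
    # leaks past the catheter as it travels, so the tracked dilation ends
    # while still moving, without a terminal collapse transient); slow
    # sub-threshold clearance after arrest
    tt <- tms[fr]
    # en-route dissipation brings the peak to just above the 2 mm tracking
    # threshold by arrest, so the tracked dilation ends while still moving
    diss_target <- max(1.0, b$amplitude_mm - 0.35 * (t1 - b$t0_s))
    dissip <- 1 - (1 - min(1, diss_target / max(b$amplitude_mm, 0.1))) *
      clamp01((tt - b$t0_s) / max(t1 - b$t0_s, 1))
    onoff <- 0.5 * (1 - cos(pi * clamp01((tt - b$t0_s) / 1.5))) *
      0.5 * (1 - cos(pi * clamp01((t1 + 10 - tt) / 10)))
    env <- onoff * dissip
    # the attached bands keep constant strength while the bolus travels and
    # release slowly (sub-threshold rate) after arrest; the relaxation band
    # additionally fades over the final 15% of travel, as descending
    # inhibition follows the waning distension
    env_band <- onoff
    env_relax <- onoff * (1 - 0.5 * clamp01((tt - (b$t0_s + 0.85 * (t1 - b$t0_s))) /
                                              max(0.15 * (t1 - b$t0_s), 0.5)))
    w0 <- if (b$amplitude_mm > 2)
      b$sigma_mm * sqrt(2 * log(b$amplitude_mm / 2)) else 0
    edges <- matrix(NA_real_, length(fr), 2)
    for (j in seq_along(fr)) {
      t <- tms[fr[j]]
      xc <- b$x0_mm + v * min(max(t - b$t0_s, 0), t1 - b$t0_s)
      bump <- b$amplitude_mm * env[j] * exp(-(X - xc)^2 / (2 * b$sigma_mm^2))
      Dev[, fr[j]] <- Dev[, fr[j]] + bump
      Pev[, fr[j]] <- Pev[, fr[j]] + config$pressure_coupling * bump
      a_eff <- b$amplitude_mm * env[j]
      if (a_eff > 2) {
        w <- b$sigma_mm * sqrt(2 * log(a_eff / 2))
        edges[j, ] <- c(xc - w, xc + w)
      }
      if (b$with_oral_contraction) {
        s <- X - (xc - w0)
        g <- band_g(s); h <- band_h(s)
        sq <- b$contraction_depth_mm * env_band[j] * g
        Dev[, fr[j]] <- Dev[, fr[j]] - sq
        Pev[, fr[j]] <- Pev[, fr[j]] + b$contraction_pressure_mmhg * env_band[j] * h
        contraction_field[, fr[j]] <- contraction_field[, fr[j]] + sq
      }
      if (isTRUE(b$with_anal_relaxation)) {
        s2 <- X - (xc + w0)
        q <- relax_q(s2)
        rx <- b$relaxation_amp_mm * env_relax[j] * q
        Dev[, fr[j]] <- Dev[, fr[j]] + rx
        Pev[, fr[j]] <- Pev[, fr[j]] - b$relaxation_dip_mmhg * env_relax[j] *
          clamp01((30 - s2) / 20) * (s2 > 0)
        relaxation_field[, fr[j]] <- relaxation_field[, fr[j]] + rx
      }
    }
    truth_boluses[[length(truth_boluses) + 1]] <- list(
      spec = b, frames = fr, times_s = tms[fr],
      oral_edge_mm = edges[, 1], anal_edge_mm = edges[, 2],
      speed_mm_s = v)
  }

  for (cn in config$contractions) {
    v <- cn$speed_mm_s
    travel_t <- if (v > 0) cn$travel_mm / v else 0
    t1 <- cn$t0_s + travel_t + cn$duration_s
    fr <- which(tms >= cn$t0_s - 1 & tms <= t1 + 1)
    for (j in seq_along(fr)) {
      t <- tms[fr[j]]
      xc <- cn$x0_mm + v * clamp01(if (travel_t > 0) (t - cn$t0_s) / travel_t else 0) *
        travel_t
      # per-point raised-cosine squeeze of the configured duration
      phase <- (t - cn$t0_s - (if (v > 0) (xc - cn$x0_mm) / v else 0)) / cn$duration_s
      env <- if (v > 0) {
        # moving squeeze: sustained while travelling, cosine shoulders
        rc_env(t, cn$t0_s, cn$t0_s + travel_t, ramp = cn$duration_s / 2)
      } else {
        if (phase < 0 || phase > 1) 0 else 0.5 * (1 - cos(2 * pi * phase))
      }
      if (env <= 0) next
      prof <- exp(-(X - xc)^2 / (2 * cn$sigma_mm^2))
      sq <- cn$depth_mm * env * prof
      Dev[, fr[j]] <- Dev[, fr[j]] - sq
      Pev[, fr[j]] <- Pev[, fr[j]] + cn$pressure_mmhg * env * prof
      contraction_field[, fr[j]] <- contraction_field[, fr[j]] + sq
    }
    if (cn$pre_dilation_mm > 0) {
      frp <- which(tms >= cn$t0_s - 20 & tms <= cn$t0_s + 20)
      envp <- slow_env(tms[frp], cn$t0_s)
      bump <- cn$pre_dilation_mm *
        exp(-(X - cn$x0_mm)^2 / (2 * cn$pre_sigma_mm^2))
      Dev[, frp] <- Dev[, frp] + outer(bump, envp)
      Pev[, frp] <- Pev[, frp] + 0.3 * outer(bump, envp)
    }
    truth_inits[[length(truth_inits) + 1]] <- list(
      x_mm = cn$x0_mm, t_s = cn$t0_s,
      pre_dilation_mm = cn$pre_dilation_mm,
      propagating = (cn$travel_mm + 4 * cn$sigma_mm) >= 20)
  }

  if (any(contraction_field > 0.25 & relaxation_field > 0.25))
    stop("contradictory specs: contraction and relaxation overlap")

  # myogenic travelling ripple: rhythmic but non-sinusoidal (a second
  # harmonic sharpens the contraction phase, as pacemaker-driven activity
  # does) with slow amplitude modulation so orbit lengths form a spread
  # distribution rather than a single atom
  phase <- outer(-2 * pi * X / config$myogenic_wavelength_mm,
                 2 * pi * config$myogenic_freq_hz * tms, "+")
  am <- 1 + 0.4 * outer(sin(2 * pi * X / 150),
                        sin(2 * pi * tms / 60), "+") / 2
  wave <- sin(phase) + 0.6 * sin(2 * phase)
  myo_D <- config$myogenic_amp_mm * am * wave
  myo_P <- config$myogenic_pressure_mmhg * am *
    (sin(phase + pi / 4) + 0.6 * sin(2 * phase + pi / 4))
  D0 <- D0 + myo_D
  P0 <- P0 + myo_P

  # assemble the noiseless field. The indwelling catheter imposes a hard
  # silhouette floor at the occluded diameter: squeezes and ripple troughs
  # cannot make the gut appear narrower than the catheter, so contractions
  # of an occluded segment register through pressure alone (the occluded
  # isometric regime).
  D0 <- pmax(D0 + Dev, config$occluded_diameter_mm)
  P0 <- P0 + Pev

  # per-frame truth bolus edges from the full noiseless field, using the
  # same baseline rule as the detector (per-position 5th percentile over
  # time): outermost contiguous positions around the bump centre dilated
  # more than 2 mm above that baseline
  base0 <- apply(D0, 1, stats::quantile, probs = 0.05, names = FALSE)
  for (k in seq_along(truth_boluses)) {
    tb <- truth_boluses[[k]]
    for (j in seq_along(tb$frames)) {
      if (is.na(tb$oral_edge_mm[j])) next
      col <- D0[, tb$frames[j]] - base0 > 2
      ci <- which.min(abs(X - (tb$oral_edge_mm[j] + tb$anal_edge_mm[j]) / 2))
      if (!col[ci]) { tb$oral_edge_mm[j] <- NA; tb$anal_edge_mm[j] <- NA; next }
      lo <- ci; while (lo > 1 && col[lo - 1]) lo <- lo - 1
      hi <- ci; while (hi < length(col) && col[hi + 1]) hi <- hi + 1
      tb$oral_edge_mm[j] <- X[lo]; tb$anal_edge_mm[j] <- X[hi]
    }
    truth_boluses[[k]] <- tb
  }

  # neurogenic support = cells where event components move the field
  # non-negligibly, dilated by the derivative-smoothing window and decoder
  # hysteresis margin so boundary cells whose decoded activity is
  # event-driven count as neurogenic rather than myogenic
  dt_s <- 1 / config$fps
  neuro <- dilate_mask(
    abs(.cdiff_time(Dev, dt_s)) / C_DIAMETER > 0.5 |
      abs(.cdiff_time(Pev, dt_s)) / C_PRESSURE > 0.5,
    dpos = 2, dtime = 12)
  truth <- .truth_from_field(D0, P0, X, tms, neuro)
  truth$boluses <- truth_boluses
  truth$initiations <- truth_inits
  truth$neurogenic_support <- neuro

  D <- D0 + matrix(stats::rnorm(nx * nt, 0, config$noise_d_sd_mm), nx, nt)
  D <- pmax(D, 0)
  P <- P0 + matrix(stats::rnorm(nx * nt, 0, config$noise_p_sd_mmhg), nx, nt)

  dmap <- new_dmap(X, tms, D)
  pmap <- new_pmap(X, tms, P)
  dp <- bundle_dpmap(dmap, pmap, list(id = "synthetic", condition = condition))

  sensors <- seq(config$sensor_pitch_mm / 2, config$length_mm,
                 by = config$sensor_pitch_mm)
  si <- vapply(sensors, function(s) which.min(abs(X - s)), integer(1))
  records <- data.frame(time_s = tms, t(P[si, , drop = FALSE]))
  names(records) <- c("time_s", sprintf("s%02d", seq_along(sensors)))
  list(dpmap = dp, truth = truth, records = records,
       sensor_positions_mm = X[si], config = config,
       noiseless = list(D = D0, P = P0))
}

# central time differences (one-sided at the boundaries)
.cdiff_time <- function(M, dt) {
  nt <- ncol(M)
  Dv <- matrix(0, nrow(M), nt)
  if (nt > 2) Dv[, 2:(nt - 1)] <- (M[, 3:nt] - M[, 1:(nt - 2)]) / (2 * dt)
  Dv[, 1] <- (M[, 2] - M[, 1]) / dt
  Dv[, nt] <- (M[, nt] - M[, nt - 1]) / dt
  Dv
}

# truth labels from analytic (noiseless) derivatives: trend = argmax of the
# three shifted-Gaussian emissions pointwise, i.e. boundaries at |z| = 1
.truth_from_field <- function(D0, P0, X, tms, neuro) {
  dt <- tms[2] - tms[1]
  zD <- .cdiff_time(D0, dt) / C_DIAMETER
  zP <- .cdiff_time(P0, dt) / C_PRESSURE
  tr <- function(z) {
    out <- matrix(2L, nrow(z), ncol(z))
    out[z < -1] <- 1L
    out[z > 1] <- 3L
    out
  }
  lv <- diameter_levels(new_dmap(X, tms, pmax(D0, 0)))
  smap <- classify_states(tr(zD), tr(zP), lv)
  active <- smap$group != "other"
  list(label = smap$label, group = smap$group,
       myogenic_active = active & !neuro,
       neurogenic_active = active & neuro)
}

#' Generate a nerve-blocked (TTX) calibration recording
#'
#' Only the myogenic ripple and noise remain; all event components are
#' removed. The ripple amplitude is scaled by `ttx_myogenic_scale`
#' (default 4/3), reflecting disinhibition of pacemaker-driven activity
#' when tonic neural inhibition is blocked.
#'
#' @param config A [synth_config()].
#' @return Same structure as [generate_preparation()], condition `"ttx"`.
#' @export
generate_ttx <- function(config) {
  cfg <- config
  cfg$boluses <- list()
  cfg$contractions <- list()
  cfg$myogenic_amp_mm <- config$myogenic_amp_mm * config$ttx_myogenic_scale
  cfg$myogenic_pressure_mmhg <- config$myogenic_pressure_mmhg * config$ttx_myogenic_scale
  cfg$seed <- config$seed + 1000L
  generate_preparation(cfg, condition = "ttx")
}

#' Render a diameter map as a silhouette image stack
#'
#' For each frame a symmetric dark band (intensity 0) of per-column width
#' `D / mm_per_pixel` is drawn on a light background (intensity 1), giving
#' an idealised back-lit silhouette video for end-to-end testing of the
#' map builder.
#'
#' @param dmap A `diameter_map`.
#' @param calib A [calibration_config()]; its `mm_per_pixel` sets the
#'   rendering resolution and the map's frame rate is taken as the stack's
#'   frame rate.
#' @param height_px Image height in pixels; must exceed the largest
#'   diameter.
#' @return List of grayscale matrices (one per frame).
#' @export
render_silhouette_stack <- function(dmap, calib, height_px = NULL) {
  mpp <- calib$mm_per_pixel
  if (is.null(height_px))
    height_px <- 2 * ceiling(max(dmap$D) / mpp / 2) + 11
  if (max(dmap$D) / mpp >= height_px)
    stop("diameter exceeds image height")
  px_per_bin <- round(diff(dmap$positions_mm[1:2]) / mpp)
  ncol_px <- nrow(dmap$D) * px_per_bin
  mid <- (height_px + 1) / 2
  lapply(seq_along(dmap$times_s), function(t) {
    fr <- matrix(1, height_px, ncol_px)
    w_px <- round(dmap$D[, t] / mpp)
    for (i in seq_len(nrow(dmap$D))) {
      if (w_px[i] <= 0) next
      r0 <- as.integer(round(mid - w_px[i] / 2))
      rows <- max(1, r0):min(height_px, r0 + w_px[i] - 1L)
      cols <- ((i - 1) * px_per_bin + 1):(i * px_per_bin)
      fr[rows, cols] <- 0
    }
    fr
  })
}
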