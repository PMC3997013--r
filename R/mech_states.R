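#' @name quiescence-constants
#' @title Quiescence scale constants
#' @description Scale constants of the Gaussian quiescence model: a time
#'   derivative is normalised by these before entering the model, so `z = 1`
#'   means "changing exactly at the quiescence scale". Pressure scale
#'   3 mmHg/s, diameter scale 0.4 mm/s.
#' @export
C_PRESSURE <- 3    # mmHg/s

#' @rdname quiescence-constants
#' @export
C_DIAMETER <- 0.4  # mm/s

#' The twelve mechanical muscle states
#'
#' Vocabulary of per-cell labels assigned by [classify_states()], and the
#' fixed grouping into active contraction (3 states), active relaxation
#' (2 states) and other (7 passive/quiescent states).
#' @export
MECH_STATES <- c(
  "occluded_isometric_contraction",
  "auxotonic_contraction",
  "isotonic_contraction",
  "auxotonic_relaxation",
  "isotonic_relaxation",
  "occluded_isometric_relaxation",
  "distended_isometric_pressure_increase",
  "distended_isometric_pressure_decrease",
  "passive_shortening",
  "passive_dilation",
  "occluded_quiescence",
  "distended_quiescence"
)

#' @rdname MECH_STATES
#' @export
STATE_GROUPS <- c(
  occluded_isometric_contraction = "active_contraction",
  auxotonic_contraction          = "active_contraction",
  isotonic_contraction           = "active_contraction",
  auxotonic_relaxation           = "active_relaxation",
  isotonic_relaxation            = "active_relaxation",
  occluded_isometric_relaxation          = "other",
  distended_isometric_pressure_increase  = "other",
  distended_isometric_pressure_decrease  = "other",
  passive_shortening   = "other",
  passive_dilation     = "other",
  occluded_quiescence  = "other",
  distended_quiescence = "other"
)

#' Conditional probability of quiescence
#'
#' The Gaussian quiescence model: given a normalised time derivative `z`
#' (derivative divided by its scale constant), the conditional probability
#' that the muscle is quiescent is `exp(-z^2/2)`. Symmetric, equal to 1 at
#' `z = 0`, strictly decreasing in `|z|`.
#'
#' @param z Normalised derivative (any numeric array).
#' @return Probabilities in `(0, 1]`, same shape as `z`.
#' @export
quiescence_probability <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  exp(-z^2 / 2)
}

#' Time derivatives of a diameter/pressure map
#'
#' Applies a centred moving average of `smooth_frames` frames per position,
#' then central differences over time (one-sided at the boundaries), and
#' normalises by the quiescence constants.
#'
#' @param dpmap A `dpmap` from [bundle_dpmap()].
#' @param smooth_frames Odd smoothing width in frames (default 5 = 1.25 s at
#'   4 Hz, comfortably shorter than a typical contraction).
#' @param c_D,c_P Quiescence scale constants (mm/s, mmHg/s).
#' @return A `derivative_field` with matrices `dDdt`, `dPdt`, `zD`, `zP` on
#'   the map's grids.
#' @export
compute_derivatives <- function(dpmap, smooth_frames = 5,
                                c_D = C_DIAMETER, c_P = C_PRESSURE) {
  stopifnot(smooth_frames >= 1, smooth_frames %% 2 == 1)
  nt <- length(dpmap$diameter$times_s)
  if (nt < max(smooth_frames, 2)) stop("recording shorter than smoothing window")
  dt <- diff(dpmap$diameter$times_s[1:2])
  deriv <- function(M) {
    S <- t(apply(M, 1, smooth_ma, k = smooth_frames))
    Dv <- matrix(0, nrow(M), nt)
    if (nt > 2) Dv[, 2:(nt - 1)] <- (S[, 3:nt] - S[, 1:(nt - 2)]) / (2 * dt)
    Dv[, 1] <- (S[, 2] - S[, 1]) / dt
    Dv[, nt] <- (S[, nt] - S[, nt - 1]) / dt
    Dv
  }
  dDdt <- deriv(dpmap$diameter$D)
  dPdt <- deriv(dpmap$pressure$P)
  structure(list(positions_mm = dpmap$diameter$positions_mm,
                 times_s = dpmap$diameter$times_s,
                 dDdt = dDdt, dPdt = dPdt,
                 zD = dDdt / c_D, zP = dPdt / c_P,
                 c_D = c_D, c_P = c_P),
            class = "derivative_field")
}

# centred moving average with edge truncation (partial windows at the ends)
smooth_ma <- function(x, k) {
  if (k <= 1) return(x)
  h <- (k - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Parameters of the three-state trend hidden Markov model
#'
#' Per-channel chain over \{falling, quiescent, rising\}. The quiescent state
#' emits with the Gaussian quiescence model `exp(-z^2/2)`; the moving states
#' emit with the same-width Gaussian shifted to `mu = -2` (falling) and
#' `mu = +2` (rising). Self-transition probability `p_stay` per frame, the
#' remainder split evenly between the other two states.
#'
#' @param p_stay Self-transition probability per 0.25 s frame (default 0.95).
#' @param mu Emission centre of the moving states (default 2).
#' @return A `trend_hmm_params` object with the transition matrix and
#'   emission centres.
#' @export
trend_hmm_params <- function(p_stay = 0.95, mu = 2) {
  stopifnot(p_stay > 0, p_stay < 1, mu > 0)
  A <- matrix((1 - p_stay) / 2, 3, 3)
  diag(A) <- p_stay
  dimnames(A) <- list(TREND_STATES, TREND_STATES)
  structure(list(p_stay = p_stay, mu = c(-mu, 0, mu), A = A),
            class = "trend_hmm_params")
}

TREND_STATES <- c("falling", "quiescent", "rising")
# deterministic tie-break: quiescent preferred, then falling, then rising
TREND_PREF <- c(falling = 2, quiescent = 1, rising = 3)

#' Decode the trend of one normalised-derivative series
#'
#' Viterbi decoding of the three-state trend chain with uniform initial
#' distribution. Deterministic: ties are broken toward quiescent, then
#' falling, then rising.
#'
#' @param z_series Numeric vector of normalised derivatives.
#' @param params A [trend_hmm_params()].
#' @return Factor vector over \{falling, quiescent, rising\}, same length.
#' @export
decode_trend <- function(z_series, params = trend_hmm_params()) {
  if (any(!is.finite(z_series))) stop("z_series must be finite")
  M <- decode_trend_matrix(matrix(z_series, nrow = 1), params)
  factor(TREND_STATES[M[1, ]], levels = TREND_STATES)
}

# Vectorised Viterbi over all positions at once: Z is (position x time).
# Returns an integer matrix of state indices into TREND_STATES.
decode_trend_matrix <- function(Z, params = trend_hmm_params()) {
  if (any(!is.finite(Z))) stop("derivatives must be finite")
  n <- nrow(Z); nt <- ncol(Z)
  mu <- params$mu
  logA <- log(params$A)
  # emission log-density at time t for the 3 states: (n x 3)
  emis <- function(t) {
    z <- Z[, t]
    cbind(-(z - mu[1])^2 / 2, -(z - mu[2])^2 / 2, -(z - mu[3])^2 / 2)
  }
  delta <- emis(1)  # uniform prior drops out
  back <- array(1L, dim = c(n, 3, nt))
  pref <- TREND_PREF[TREND_STATES]
  if (nt > 1) {
    for (t in 2:nt) {
      e <- emis(t)
      newdelta <- matrix(-Inf, n, 3)
      for (j in 1:3) {
        cand <- delta + rep(logA[, j], each = n)     # n x 3 over predecessors
        # argmax with fixed tie preference: scan columns in preference order
        ord <- order(pref)                            # quiescent, falling, rising
        bi <- ord[max.col(cand[, ord, drop = FALSE], ties.method = "first")]
        back[, j, t] <- bi
        newdelta[, j] <- cand[cbind(seq_len(n), bi)] + e[, j]
      }
      delta <- newdelta
    }
  }
  ord <- order(TREND_PREF[TREND_STATES])
  path <- matrix(1L, n, nt)
  path[, nt] <- ord[max.col(delta[, ord, drop = FALSE], ties.method = "first")]
  if (nt > 1)
    for (t in (nt - 1):1)
      path[, t] <- back[cbind(seq_len(n), path[, t + 1], t + 1)]
  path
}

#' Occluded/distended level of every map cell
#'
#' Per position, the robust diameter range is taken as the 5th and 95th
#' percentile over time; `rho` is the diameter's position in that range,
#' clipped to `[0, 1]`. Cells with `rho < 0.5` are "occluded" (near minimum
#' diameter, lumen closed around the catheter), the rest "distended". A
#' position whose diameter never varies is treated as occluded.
#'
#' @param dmap A `diameter_map`.
#' @param probs Robust range percentiles (default `c(0.05, 0.95)`).
#' @return A `diameter_level_field` with matrices `rho` and logical
#'   `distended`.
#' @export
diameter_levels <- function(dmap, probs = c(0.05, 0.95)) {
  qs <- t(apply(dmap$D, 1, stats::quantile, probs = probs, names = FALSE))
  lo <- qs[, 1]; hi <- qs[, 2]
  rng <- hi - lo
  rho <- (dmap$D - lo) / ifelse(rng > 1e-9, rng, 1)
  rho[rng <= 1e-9, ] <- 0
  rho <- pmin(pmax(rho, 0), 1)
  structure(list(positions_mm = dmap$positions_mm, times_s = dmap$times_s,
                 rho = matrix(rho, nrow = nrow(dmap$D)),
                 distended = matrix(rho >= 0.5, nrow = nrow(dmap$D)),
                 D_lo = lo, D_hi = hi),
            class = "diameter_level_field")
}

# integer decision table: indices into MECH_STATES
classify_cell <- function(tD, tP, distended) {
  # tD, tP in 1..3 (falling, quiescent, rising)
  if (tD == 1 && tP == 3) return(2L)  # auxotonic_contraction
  if (tD == 1 && tP == 2) return(3L)  # isotonic_contraction
  if (tD == 1 && tP == 1) return(9L)  # passive_shortening
  if (tD == 3 && tP == 1) return(4L)  # auxotonic_relaxation
  if (tD == 3 && tP == 2) return(5L)  # isotonic_relaxation
  if (tD == 3 && tP == 3) return(10L) # passive_dilation
  if (tD == 2 && tP == 3) return(if (distended) 7L else 1L)
  if (tD == 2 && tP == 1) return(if (distended) 8L else 6L)
  if (distended) 12L else 11L
}

#' Classify every map cell into one of the twelve mechanical states
#'
#' Applies the total decision table over the decoded diameter trend, pressure
#' trend and occluded/distended level: e.g. diameter falling with pressure
#' rising is an auxotonic contraction; both quiescent at low diameter is
#' occluded quiescence. The fixed grouping assigns each label to active
#' contraction, active relaxation or other.
#'
#' @param trend_D,trend_P Integer matrices of trend indices (1 = falling,
#'   2 = quiescent, 3 = rising) as returned by the internal decoder, on
#'   identical grids.
#' @param levels A `diameter_level_field` from [diameter_levels()].
#' @return A `mech_state_map` with integer `label` matrix (indices into
#'   [MECH_STATES]), character-factor matrix `group`, and grids.
#' @export
classify_states <- function(trend_D, trend_P, levels) {
  stopifnot(all(dim(trend_D) == dim(trend_P)),
            all(dim(trend_D) == dim(levels$distended)))
  # vectorised table lookup: code = (tD-1)*6 + (tP-1)*2 + distended + 1
  code <- (trend_D - 1L) * 6L + (trend_P - 1L) * 2L + levels$distended + 1L
  lut <- integer(18)
  for (tD in 1:3) for (tP in 1:3) for (d in 0:1)
    lut[(tD - 1L) * 6L + (tP - 1L) * 2L + d + 1L] <- classify_cell(tD, tP, d == 1)
  label <- matrix(lut[code], nrow = nrow(trend_D))
  grp <- matrix(unname(STATE_GROUPS[MECH_STATES[label]]), nrow = nrow(label))
  structure(list(positions_mm = levels$positions_mm, times_s = levels$times_s,
                 label = label, group = grp,
                 trend_D = trend_D, trend_P = trend_P),
            class = "mech_state_map")
}

#' Decode trends and classify a whole map
#'
#' Convenience wrapper: derivatives -> per-position Viterbi trend decoding of
#' both channels -> level split -> twelve-state classification.
#'
#' @param dpmap A `dpmap`.
#' @param smooth_frames Smoothing width for [compute_derivatives()].
#' @param params Trend HMM parameters.
#' @return A `mech_state_map`.
#' @export
classify_dpmap <- function(dpmap, smooth_frames = 5, params = trend_hmm_params()) {
  dv <- compute_derivatives(dpmap, smooth_frames)
  tD <- decode_trend_matrix(dv$zD, params)
  tP <- decode_trend_matrix(dv$zP, params)
  lv <- diameter_levels(dpmap$diameter)
  out <- classify_states(tD, tP, lv)
  out$derivatives <- dv
  out
}

#' Fraction of space-time occupied by each mechanical state
#'
#' @param smap A `mech_state_map`.
#' @return Named numeric vector over [MECH_STATES], summing to 1, with
#'   attribute `group_occupancy` (the three group fractions).
#' @export
state_occupancy <- function(smap) {
  stopifnot(length(smap$label) > 0)
  occ <- tabulate(smap$label, nbins = 12) / length(smap$label)
  names(occ) <- MECH_STATES
  g <- c(active_contraction = mean(smap$group == "active_contraction"),
         active_relaxation = mean(smap$group == "active_relaxation"),
         other = mean(smap$group == "other"))
  attr(occ, "group_occupancy") <- g
  occ
}
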