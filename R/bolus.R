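BOLUS_DILATION_MM <- 2     # dilation above minimum occluded diameter
BOLUS_MIN_SPAN_S <- 0.5    # minimum persistence of a tracked bolus

#' Per-position minimum occluded diameter (baseline)
#'
#' The 5th-percentile diameter over time at each position; shared by bolus
#' detection and the initiation analysis as the "baseline diameter".
#'
#' @param dmap A `diameter_map`.
#' @return Numeric vector, one value per position (mm).
#' @export
occluded_baseline <- function(dmap) {
  apply(dmap$D, 1, stats::quantile, probs = 0.05, names = FALSE)
}

#' Detect and track boluses on a diameter map
#'
#' A bolus is a region where the gut is dilated more than 2 mm above its
#' minimum occluded diameter, persisting at least 0.5 s. Supra-threshold
#' runs are linked frame to frame by spatial overlap; on merges and splits
#' the largest-overlap fragment keeps the track identity, smaller fragments
#' start new tracks.
#'
#' @param dmap A `diameter_map`.
#' @param threshold_mm Dilation threshold (default 2 mm).
#' @param min_span_s Minimum persistence, from first to last tracked frame
#'   (default 0.5 s).
#' @return List of `bolus` objects, each with a `track` data frame
#'   (`time_idx`, `time_s`, `oral_edge_mm`, `anal_edge_mm`, `length_mm`,
#'   `max_dilation_mm`) and a scalar `max_dilation_mm`. Oral edge is the
#'   edge nearer the oral (low-position) end.
#' @export
detect_boluses <- function(dmap, threshold_mm = BOLUS_DILATION_MM,
                           min_span_s = BOLUS_MIN_SPAN_S) {
  base <- occluded_baseline(dmap)
  dil <- dmap$D - base
  pos <- dmap$positions_mm
  dt <- if (length(dmap$times_s) > 1) diff(dmap$times_s[1:2]) else 0.25
  nt <- ncol(dil)
  open <- list()   # each: list(rows, last = c(i1, i2), miss = 0)
  done <- list()
  coast_frames <- 2L  # tracks survive brief detection dropouts
  gap_cells <- max(1L, round(3 / if (length(pos) > 1) diff(pos[1:2]) else 1))
  for (t in seq_len(nt)) {
    above <- dil[, t] > threshold_mm
    # close sub-resolution gaps (<= 3 mm) so one bolus momentarily dipping
    # to threshold at a single point is not split into two regions
    r0 <- rle(above)
    if (length(r0$lengths) > 2) {
      inner <- 2:(length(r0$lengths) - 1)
      fill <- !r0$values[inner] & r0$lengths[inner] <= gap_cells
      r0$values[inner][fill] <- TRUE
      above <- inverse.rle(r0)
    }
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    regs <- cbind(starts[r$values], ends[r$values])
    matched_track <- rep(NA_integer_, nrow(regs))
    if (length(open) && nrow(regs)) {
      ov <- sapply(seq_along(open), function(k) {
        last <- open[[k]]$last
        pmax(0, pmin(regs[, 2], last[2]) - pmax(regs[, 1], last[1]) + 1)
      })
      ov <- matrix(ov, nrow = nrow(regs))
      # greedy largest-overlap assignment: tracks and regions pair off in
      # decreasing overlap, so the largest fragment keeps the identity
      repeat {
        m <- which(ov == max(ov), arr.ind = TRUE)
        if (max(ov) == 0) break
        ri <- m[1, 1]; ki <- m[1, 2]
        matched_track[ri] <- ki
        ov[ri, ] <- 0; ov[, ki] <- 0
      }
    }
    new_open <- list()
    for (ri in seq_len(nrow(regs))) {
      i1 <- regs[ri, 1]; i2 <- regs[ri, 2]
      rec <- data.frame(
        time_idx = t, time_s = dmap$times_s[t],
        oral_edge_mm = pos[i1], anal_edge_mm = pos[i2],
        length_mm = pos[i2] - pos[i1],
        max_dilation_mm = max(dil[i1:i2, t]))
      if (!is.na(matched_track[ri])) {
        tr <- open[[matched_track[ri]]]
        tr$rows[[length(tr$rows) + 1]] <- rec
        tr$last <- c(i1, i2)
        tr$miss <- 0L
        new_open[[length(new_open) + 1]] <- tr
      } else {
        new_open[[length(new_open) + 1]] <-
          list(rows = list(rec), last = c(i1, i2), miss = 0L)
      }
    }
    if (length(open)) {
      unmatched <- setdiff(seq_along(open), matched_track[!is.na(matched_track)])
      for (k in unmatched) {
        tr <- open[[k]]
        tr$miss <- tr$miss + 1L
        if (tr$miss > coast_frames) done <- c(done, list(tr))
        else new_open[[length(new_open) + 1]] <- tr
      }
    }
    open <- new_open
  }
  done <- c(done, open)
  boluses <- lapply(done, function(tr) {
    track <- do.call(rbind, tr$rows)
    structure(list(track = track,
                   max_dilation_mm = max(track$max_dilation_mm),
                   max_length_mm = max(track$length_mm)),
              class = "bolus")
  })
  keep <- vapply(boluses, function(b) {
    span <- diff(range(b$track$time_s))
    span >= min_span_s - 1e-9
  }, logical(1))
  boluses[keep]
}

# Theil-Sen slope (median of pairwise slopes), subsampled for long tracks
theil_sen <- function(x, y, max_n = 150) {
  n <- length(x)
  if (n > max_n) {
    idx <- round(seq(1, n, length.out = max_n))
    x <- x[idx]; y <- y[idx]; n <- max_n
  }
  cmb <- utils::combn(n, 2)
  s <- (y[cmb[2, ]] - y[cmb[1, ]]) / (x[cmb[2, ]] - x[cmb[1, ]])
  stats::median(s)
}

#' Estimate bolus propulsion speed and assign a speed bin
#'
#' Both edge trajectories are smoothed with a 5-frame moving average, each
#' fitted with a robust (Theil-Sen) slope, and the speed is the mean of the
#' two. Positive speed is anal (propulsive) movement. Bins: fast > 7 mm/s,
#' mid > 3 and <= 7, slow > 0 and <= 3, stationary below 0.5 mm/s in
#' magnitude.
#'
#' @param bolus A `bolus` from [detect_boluses()].
#' @return The bolus with `speed_mm_s` and `speed_bin` filled in.
#' @export
estimate_speed <- function(bolus) {
  tr <- bolus$track
  if (nrow(tr) < 3) stop("track must span at least 3 frames")
  # drop birth/death shoulders where the supra-threshold region is growing
  # or collapsing in place rather than translating: frames whose (smoothed)
  # centre has not yet left the initial, or already reached the final,
  # centre position. Skipped when it would discard most of the track
  # (a genuinely stationary bolus).
  n <- nrow(tr)
  if (n >= 10) {
    mid <- smooth_ma((tr$oral_edge_mm + tr$anal_edge_mm) / 2, 5)
    v <- abs(diff(mid)) / pmax(diff(tr$time_s), 1e-9)
    v <- smooth_ma(c(v[1], v), 5)
    r <- rle(v > max(0.5, 0.3 * max(v)))
    if (any(r$values)) {
      ends <- cumsum(r$lengths)
      runs <- which(r$values)
      best <- runs[which.max(r$lengths[runs])]
      i1 <- ends[best] - r$lengths[best] + 1; i2 <- ends[best]
      if (i2 - i1 + 1 >= max(5, 0.3 * n))
        tr <- tr[i1:i2, , drop = FALSE]
    }
  }
  bolus$track_moving <- tr
  t <- tr$time_s
  v <- if (nrow(tr) >= 10) {
    so <- theil_sen(t, smooth_ma(tr$oral_edge_mm, 5))
    sa <- theil_sen(t, smooth_ma(tr$anal_edge_mm, 5))
    mean(c(so, sa))
  } else {
    # short tracks: pairwise edge slopes are dominated by growth/decay of
    # the region, not translation; net centre displacement is robust
    mid <- (tr$oral_edge_mm + tr$anal_edge_mm) / 2
    (mean(mid[(nrow(tr) - 1):nrow(tr)]) - mean(mid[1:2])) /
      (mean(t[(nrow(tr) - 1):nrow(tr)]) - mean(t[1:2]))
  }
  av <- abs(v)
  bin <- if (av < 0.5) "stationary"
         else if (av > 7) "fast"
         else if (av > 3) "mid"
         else "slow"
  bolus$speed_mm_s <- v
  bolus$speed_bin <- bin
  bolus
}

# accumulate group fractions at a set of positions (mm) for one frame
.profile_tally <- function(acc, smap, x_mm, t_idx, coord_idx) {
  pos <- smap$positions_mm
  dx <- diff(pos[1:2])
  pi <- round((x_mm - pos[1]) / dx) + 1
  ok <- pi >= 1 & pi <= length(pos)
  if (!any(ok)) return(acc)
  g <- smap$group[cbind(pi[ok], t_idx)]
  ci <- coord_idx[ok]
  acc$n[ci] <- acc$n[ci] + 1
  acc$contraction[ci] <- acc$contraction[ci] + (g == "active_contraction")
  acc$relaxation[ci] <- acc$relaxation[ci] + (g == "active_relaxation")
  acc
}

.profile_from_frames <- function(smap, frame_fun, frames,
                                 flank_mm = 30, n_interior = 21) {
  pos <- smap$positions_mm
  dx <- diff(pos[1:2])
  n_flank <- round(flank_mm / dx)
  n_coord <- 2 * n_flank + n_interior
  acc <- list(n = numeric(n_coord), contraction = numeric(n_coord),
              relaxation = numeric(n_coord))
  for (f in frames) {
    fr <- frame_fun(f)
    if (is.null(fr)) next
    oral <- fr$oral_edge_mm; anal <- fr$anal_edge_mm
    xs <- c(oral - rev(seq_len(n_flank)) * dx,
            seq(oral, anal, length.out = n_interior),
            anal + seq_len(n_flank) * dx)
    acc <- .profile_tally(acc, smap, xs, fr$time_idx, seq_len(n_coord))
  }
  n <- pmax(acc$n, 1)
  zone <- c(rep("oral_flank", n_flank), rep("interior", n_interior),
            rep("anal_flank", n_flank))
  coord <- c(-rev(seq_len(n_flank)) * dx,
             seq(0, 1, length.out = n_interior),
             seq_len(n_flank) * dx)
  fc <- acc$contraction / n
  fr_ <- acc$relaxation / n
  data.frame(zone = zone, coord = coord,
             frac_contraction = fc, frac_relaxation = fr_,
             frac_other = 1 - fc - fr_, n_cells = acc$n)
}

#' Active-state profile along and around boluses
#'
#' For every tracked frame of every bolus in the requested speed bin, the
#' state map is sampled over a 30 mm oral flank, the normalised bolus
#' interior (`[0, 1]`), and a 30 mm anal flank; the fractions of active
#' contraction, active relaxation and other states are averaged per
#' coordinate. Flanks running past the preparation ends are truncated.
#'
#' @param boluses List of `bolus` objects with speeds assigned
#'   ([estimate_speed()]).
#' @param smap The neurogenic `mech_state_map`.
#' @param bin Speed bin to profile (`"fast"`, `"mid"`, `"slow"`,
#'   `"stationary"`), or `NULL` for all.
#' @param flank_mm Flank width (default 30 mm).
#' @param n_interior Number of normalised interior sample coordinates.
#' @return A `bolus_state_profile` data frame: `zone`, `coord`,
#'   `frac_contraction`, `frac_relaxation`, `frac_other`, `n_cells`.
#' @export
state_profile <- function(boluses, smap, bin = "fast",
                          flank_mm = 30, n_interior = 21) {
  if (!is.null(bin)) {
    boluses <- Filter(function(b) identical(b$speed_bin, bin), boluses)
    if (length(boluses) == 0) stop("no boluses in speed bin '", bin, "'")
  }
  # moving boluses are profiled over their moving frames (the frames that
  # define the speed bin); stationary boluses over their whole track
  tracks <- lapply(boluses, function(b) {
    if (!identical(b$speed_bin, "stationary") && !is.null(b$track_moving))
      b$track_moving else b$track
  })
  frames <- do.call(rbind, lapply(seq_along(tracks), function(i)
    cbind(b = i, r = seq_len(nrow(tracks[[i]])))))
  prof <- .profile_from_frames(
    smap,
    frame_fun = function(f) tracks[[f[1]]][f[2], ],
    frames = split(frames, seq_len(nrow(frames))),
    flank_mm = flank_mm, n_interior = n_interior)
  class(prof) <- c("bolus_state_profile", class(prof))
  prof
}

#' Control profile at random map points
#'
#' Builds the same profile as [state_profile()] around uniformly random
#' space-time anchors carrying a fixed-width pseudo-bolus, to confirm that
#' the polarised pattern around real boluses is not a sampling artefact.
#'
#' @param smap A `mech_state_map`.
#' @param n_points Number of random anchors.
#' @param seed Integer seed (profiles are reproducible given the seed).
#' @param span_mm Pseudo-bolus width (default 20 mm).
#' @param flank_mm,n_interior As in [state_profile()].
#' @return A `bolus_state_profile` data frame.
#' @export
random_point_control <- function(smap, n_points, seed, span_mm = 20,
                                 flank_mm = 30, n_interior = 21) {
  stopifnot(n_points >= 1)
  set.seed(seed)
  pos <- smap$positions_mm
  nt <- length(smap$times_s)
  xs <- stats::runif(n_points, min(pos), max(pos))
  ts <- sample.int(nt, n_points, replace = TRUE)
  prof <- .profile_from_frames(
    smap,
    frame_fun = function(f) list(oral_edge_mm = xs[f] - span_mm / 2,
                                 anal_edge_mm = xs[f] + span_mm / 2,
                                 time_idx = ts[f]),
    frames = seq_len(n_points),
    flank_mm = flank_mm, n_interior = n_interior)
  class(prof) <- c("bolus_state_profile", class(prof))
  prof
}

# any active relaxation in the 30 mm anal flank at any tracked frame
bolus_anal_relaxation <- function(bolus, smap, flank_mm = 30) {
  pos <- smap$positions_mm
  dx <- diff(pos[1:2])
  for (r in seq_len(nrow(bolus$track))) {
    fr <- bolus$track[r, ]
    xi <- round((fr$anal_edge_mm - pos[1]) / dx) + 1
    idx <- (xi + 1):min(xi + round(flank_mm / dx), length(pos))
    idx <- idx[idx >= 1 & idx <= length(pos)]
    if (length(idx) &&
        any(smap$group[idx, fr$time_idx] == "active_relaxation"))
      return(TRUE)
  }
  FALSE
}

#' Proportion of fast boluses with anal relaxation, by maximal dilation
#'
#' Bins fast boluses by their maximal dilation above the minimum occluded
#' diameter and reports the per-bin proportion associated with active
#' relaxation in the 30 mm anal flank at any point of the track.
#'
#' @param boluses List of `bolus` objects with speeds assigned; only the
#'   fast bin is used.
#' @param smap The neurogenic `mech_state_map`.
#' @param breaks Dilation bin edges in mm (default `c(2, 3, 4, 5, 6, Inf)`).
#' @param flank_mm Anal flank width (default 30 mm).
#' @return Data frame: `bin`, `n`, `n_relaxation`, `proportion`.
#' @export
dilation_relaxation_curve <- function(boluses, smap,
                                      breaks = c(2, 3, 4, 5, 6, Inf),
                                      flank_mm = 30) {
  fast <- Filter(function(b) identical(b$speed_bin, "fast"), boluses)
  if (length(fast) == 0) stop("no fast boluses")
  dils <- vapply(fast, function(b) b$max_dilation_mm, numeric(1))
  rel <- vapply(fast, bolus_anal_relaxation, logical(1),
                smap = smap, flank_mm = flank_mm)
  bin <- cut(dils, breaks, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(bin), function(l) {
    sel <- !is.na(bin) & bin == l
    data.frame(bin = l, n = sum(sel), n_relaxation = sum(rel[sel]),
               proportion = if (any(sel)) mean(rel[sel]) else NA_real_)
  }))
  out
}

#' Does bolus length matter for anal relaxation?
#'
#' 2x2 table of bolus length class (at or below vs above `cutoff_mm`) against
#' presence of anal active relaxation, tested with Pearson chi-squared
#' (no continuity correction).
#'
#' @param boluses List of `bolus` objects.
#' @param smap The neurogenic `mech_state_map`.
#' @param cutoff_mm Length cutoff (default 20 mm).
#' @param flank_mm Anal flank width.
#' @return List with `table` (2x2) and `test` (`test_result`), plus the two
#'   proportions.
#' @export
length_relaxation_test <- function(boluses, smap, cutoff_mm = 20,
                                   flank_mm = 30) {
  if (length(boluses) == 0) stop("no boluses")
  len <- vapply(boluses, function(b) b$max_length_mm, numeric(1))
  rel <- vapply(boluses, bolus_anal_relaxation, logical(1),
                smap = smap, flank_mm = flank_mm)
  short <- len <= cutoff_mm
  if (!any(short) || all(short)) stop("need boluses in both length classes")
  tab <- matrix(c(sum(short & rel), sum(short & !rel),
                  sum(!short & rel), sum(!short & !rel)),
                2, 2, byrow = TRUE,
                dimnames = list(c("short", "long"),
                                c("relaxation", "no_relaxation")))
  list(table = tab, test = chi2_2x2(tab),
       proportion_short = mean(rel[short]),
       proportion_long = mean(rel[!short]))
}

#' Average diameter in sensor-pitch bins
#'
#' Averages the diameter map into coarse axial bins (default 10 mm, the
#' manometry sensor pitch) so diameter can be correlated with per-sensor
#' pressure at matching resolution.
#'
#' @param dmap A `diameter_map`.
#' @param bin_mm Bin width (default 10 mm).
#' @return A `diameter_map` on the binned position grid.
#' @export
bin_diameter <- function(dmap, bin_mm = 10) {
  bin <- floor((dmap$positions_mm - min(dmap$positions_mm)) / bin_mm)
  D <- apply(dmap$D, 2, function(col) tapply(col, bin, mean))
  centers <- tapply(dmap$positions_mm, bin, mean)
  new_dmap(as.numeric(centers), dmap$times_s,
           matrix(D, nrow = length(centers)))
}

#' One row per tracked bolus
#'
#' @param boluses List of `bolus` objects (speeds assigned).
#' @param smap Optional state map for the anal-relaxation flag.
#' @return Data frame: id, n_frames, t_start_s, t_end_s, max_length_mm,
#'   max_dilation_mm, speed_mm_s, speed_bin (and anal_relaxation when a
#'   state map is given).
#' @export
bolus_table <- function(boluses, smap = NULL) {
  out <- do.call(rbind, lapply(seq_along(boluses), function(i) {
    b <- boluses[[i]]
    data.frame(id = i, n_frames = nrow(b$track),
               t_start_s = min(b$track$time_s), t_end_s = max(b$track$time_s),
               max_length_mm = b$max_length_mm,
               max_dilation_mm = b$max_dilation_mm,
               speed_mm_s = b$speed_mm_s %||% NA_real_,
               speed_bin = b$speed_bin %||% NA_character_)
  }))
  if (!is.null(smap) && !is.null(out))
    out$anal_relaxation <- vapply(boluses, bolus_anal_relaxation, logical(1),
                                  smap = smap)
  out
}

#' Per-bolus association with oral contraction and anal relaxation
#'
#' For each tracked bolus, reports whether any active contraction occurs in
#' its 30 mm oral flank and any active relaxation in its 30 mm anal flank
#' during the track, the per-bolus association rates the polarised-reflex
#' model predicts.
#'
#' @param boluses List of `bolus` objects.
#' @param smap The neurogenic `mech_state_map`.
#' @param flank_mm Flank width (default 30 mm).
#' @return Data frame with logical columns `oral_contraction` and
#'   `anal_relaxation`, one row per bolus.
#' @export
bolus_associations <- function(boluses, smap, flank_mm = 30) {
  pos <- smap$positions_mm
  dx <- diff(pos[1:2])
  nfl <- round(flank_mm / dx)
  one <- function(b) {
    tr <- b$track_moving %||% b$track
    oral <- FALSE; anal <- FALSE
    for (r in seq_len(nrow(tr))) {
      oi <- round((tr$oral_edge_mm[r] - pos[1]) / dx) + 1
      ai <- round((tr$anal_edge_mm[r] - pos[1]) / dx) + 1
      oidx <- (oi - nfl):(oi - 1); oidx <- oidx[oidx >= 1 & oidx <= length(pos)]
      aidx <- (ai + 1):(ai + nfl); aidx <- aidx[aidx >= 1 & aidx <= length(pos)]
      if (length(oidx) &&
          any(smap$group[oidx, tr$time_idx[r]] == "active_contraction"))
        oral <- TRUE
      if (length(aidx) &&
          any(smap$group[aidx, tr$time_idx[r]] == "active_relaxation"))
        anal <- TRUE
      if (oral && anal) break
    }
    c(oral, anal)
  }
  res <- t(vapply(boluses, one, logical(2)))
  data.frame(oral_contraction = res[, 1], anal_relaxation = res[, 2])
}
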