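#' Extract orbit segments from a classified map
#'
#' At every position, each maximal run of frames where either channel's
#' decoded trend is non-quiescent forms one orbit segment. Its path length is
#' the polygonal length of the pressure-diameter trajectory in normalised
#' orbit coordinates (diameter divided by the diameter quiescence constant,
#' pressure by the pressure constant), i.e. the cumulative normalised
#' excursion of the orbit plot over that activity burst. Myogenic ripples
#' trace short, flat orbits; neurogenic contractions trace long ones.
#'
#' @param dpmap The `dpmap` the states were computed from.
#' @param smap A `mech_state_map` from [classify_dpmap()] (its decoded
#'   trends delimit the segments).
#' @param c_D,c_P Quiescence scale constants used for normalisation.
#' @return A data frame with one row per segment: `position_idx`,
#'   `frame_start`, `frame_end`, `path_length`.
#' @export
extract_orbit_segments <- function(dpmap, smap,
                                   c_D = C_DIAMETER, c_P = C_PRESSURE) {
  active <- smap$trend_D != 2L | smap$trend_P != 2L
  D <- dpmap$diameter$D / c_D
  P <- dpmap$pressure$P / c_P
  out <- vector("list", nrow(active))
  for (i in seq_len(nrow(active))) {
    r <- rle(active[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    if (length(runs) == 0) next
    pl <- vapply(runs, function(k) {
      a <- starts[k]; b <- ends[k]
      # include the entry step from the last quiescent frame, if any
      a0 <- max(a - 1, 1)
      if (b == a0) return(0)
      idx <- a0:b
      sum(sqrt(diff(D[i, idx])^2 + diff(P[i, idx])^2))
    }, numeric(1))
    out[[i]] <- data.frame(position_idx = i,
                           frame_start = starts[runs],
                           frame_end = ends[runs],
                           path_length = pl)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(position_idx = integer(0), frame_start = integer(0),
                      frame_end = integer(0), path_length = numeric(0))
  res
}

#' Calibrate the myogenic orbit-length threshold from a TTX recording
#'
#' With all neural activity blocked, any residual activity is myogenic. The
#' threshold is the `q`-quantile (linear-interpolation convention, R type 7)
#' of the orbit path lengths of the nerve-blocked recording: segments below
#' it are attributed to myogenic activity. The threshold is always
#' recalibrated per dataset; published values need not transfer between
#' preparations.
#'
#' @param ttx_dpmap A `dpmap` of the nerve-blocked (TTX) condition.
#' @param q Quantile (default 0.95).
#' @param smooth_frames,params Passed to [classify_dpmap()].
#' @return A `myogenic_threshold`: list with `value`, `q`, `n_segments`.
#' @export
calibrate_threshold <- function(ttx_dpmap, q = 0.95, smooth_frames = 5,
                                params = trend_hmm_params()) {
  smap <- classify_dpmap(ttx_dpmap, smooth_frames, params)
  seg <- extract_orbit_segments(ttx_dpmap, smap)
  if (nrow(seg) == 0)
    stop("no orbit segments in calibration recording; cannot calibrate")
  if (nrow(seg) < 50)
    warning("fewer than 50 calibration segments; threshold may be unstable")
  structure(list(value = unname(stats::quantile(seg$path_length, q, type = 7)),
                 q = q, n_segments = nrow(seg)),
            class = "myogenic_threshold")
}

#' Mask sub-threshold (myogenic) activity from a state map
#'
#' Cells belonging to orbit segments whose path length is at or below the
#' threshold have their group reassigned to `"other"`; the underlying
#' twelve-state labels are kept untouched (audit trail), so masking changes
#' group assignments only. What remains in the active groups is attributed
#' to neurogenic input.
#'
#' @param smap A `mech_state_map`.
#' @param segments Segment table from [extract_orbit_segments()].
#' @param threshold A `myogenic_threshold` (or a bare number).
#' @return The neurogenic `mech_state_map`: same labels, masked `group`,
#'   plus a logical `myogenic_mask` matrix.
#' @export
apply_myogenic_mask <- function(smap, segments, threshold) {
  thr <- if (inherits(threshold, "myogenic_threshold")) threshold$value else threshold
  mask <- matrix(FALSE, nrow(smap$label), ncol(smap$label))
  sub <- segments[segments$path_length <= thr, , drop = FALSE]
  for (k in seq_len(nrow(sub)))
    mask[sub$position_idx[k], sub$frame_start[k]:sub$frame_end[k]] <- TRUE
  out <- smap
  out$group[mask & out$group != "other"] <- "other"
  out$myogenic_mask <- mask
  out$neurogenic <- TRUE
  out
}
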