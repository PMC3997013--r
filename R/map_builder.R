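#' Calibration for converting video + manometry into aligned maps
#'
#' Bundles the geometric and temporal calibration needed to turn a silhouette
#' video stack and sparse pressure records into aligned diameter and pressure
#' maps on a common grid.
#'
#' @param mm_per_pixel Physical size of one pixel (mm); must be > 0.
#' @param source_fps Frame rate of the raw video (Hz).
#' @param target_fps Frame rate of the maps (Hz); default 4, must not exceed
#'   `source_fps`.
#' @param binarize_threshold Silhouette threshold as a fraction of the
#'   intensity range, in `[0, 1]`.
#' @param sensor_positions_mm Strictly increasing positions of the pressure
#'   sensors along the gut axis (mm from the oral end under the default
#'   orientation).
#' @param sync_offset_s Video time minus pressure time (s); a constant offset
#'   standing in for the timing-LED synchronisation.
#' @param oral_end Which end of the position axis is oral: `"low_index"`
#'   (default; positions increase analward) or `"high_index"`.
#' @param dx_mm Axial bin width of the maps (mm); default 1.
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(mm_per_pixel,
                               source_fps,
                               target_fps = 4,
                               binarize_threshold = 0.5,
                               sensor_positions_mm = numeric(0),
                               sync_offset_s = 0,
                               oral_end = c("low_index", "high_index"),
                               dx_mm = 1) {
  oral_end <- match.arg(oral_end)
  stopifnot(is.numeric(mm_per_pixel), length(mm_per_pixel) == 1, mm_per_pixel > 0)
  stopifnot(source_fps > 0, target_fps > 0)
  if (target_fps > source_fps)
    stop("target_fps must not exceed source_fps")
  if (binarize_threshold < 0 || binarize_threshold > 1)
    stop("binarize_threshold must be in [0, 1]")
  if (length(sensor_positions_mm) > 1 && any(diff(sensor_positions_mm) <= 0))
    stop("sensor_positions_mm must be strictly increasing")
  structure(list(
    mm_per_pixel = mm_per_pixel,
    source_fps = source_fps,
    target_fps = target_fps,
    binarize_threshold = binarize_threshold,
    sensor_positions_mm = as.numeric(sensor_positions_mm),
    sync_offset_s = sync_offset_s,
    oral_end = oral_end,
    dx_mm = dx_mm
  ), class = "calibration_config")
}

#' Threshold a grayscale frame into a tissue silhouette mask
#'
#' Foreground (tissue) is the dark side of the threshold: silhouette videos
#' show the gut as a dark band against a back-lit background. The threshold
#' is a fraction of the frame's own intensity range, so absolute exposure
#' does not matter.
#'
#' @param frame Numeric matrix, rows = cross-axis pixels, cols = axial pixels.
#' @param threshold Fraction of the intensity range in `[0, 1]`.
#' @param dark_foreground If `TRUE` (default) pixels at or below the cutoff
#'   are tissue.
#' @return Logical matrix of the same shape with attribute `degenerate`
#'   (`TRUE` when the frame had no contrast or the mask is all one value).
#' @export
binarize_frame <- function(frame, threshold, dark_foreground = TRUE) {
  if (!is.matrix(frame) || length(frame) == 0)
    stop("frame must be a non-empty matrix")
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]")
  rng <- range(frame)
  if (rng[2] - rng[1] <= 0) {
    mask <- matrix(FALSE, nrow(frame), ncol(frame))
    attr(mask, "degenerate") <- TRUE
    return(mask)
  }
  cutoff <- rng[1] + threshold * (rng[2] - rng[1])
  mask <- if (dark_foreground) frame <= cutoff else frame >= cutoff
  attr(mask, "degenerate") <- all(mask) || !any(mask)
  mask
}

#' Extract a diameter profile from a silhouette mask
#'
#' For each axial column, the diameter is the cross-axis extent between the
#' outermost foreground pixels times `mm_per_pixel`. Columns with no
#' foreground get diameter 0 and are flagged.
#'
#' @param mask Logical matrix from [binarize_frame()].
#' @param calib A [calibration_config()].
#' @return Numeric vector of diameters (mm), one per axial column, with
#'   attribute `empty_columns` (logical vector).
#' @export
extract_diameter_profile <- function(mask, calib) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  if (ncol(mask) < nrow(mask))
    stop("mask orientation mismatch: expected gut axis along columns (ncol >= nrow)")
  counts <- apply(mask, 2, function(col) {
    idx <- which(col)
    if (length(idx) == 0) 0L else (idx[length(idx)] - idx[1] + 1L)
  })
  d <- counts * calib$mm_per_pixel
  attr(d, "empty_columns") <- counts == 0L
  d
}

new_dmap <- function(positions_mm, times_s, D) {
  stopifnot(nrow(D) == length(positions_mm), ncol(D) == length(times_s))
  if (any(D < 0)) stop("diameters must be non-negative")
  if (anyNA(D)) stop("diameter map contains missing values")
  structure(list(positions_mm = positions_mm, times_s = times_s, D = D),
            class = "diameter_map")
}

new_pmap <- function(positions_mm, times_s, P) {
  stopifnot(nrow(P) == length(positions_mm), ncol(P) == length(times_s))
  if (any(!is.finite(P))) stop("pressure map must be finite")
  structure(list(positions_mm = positions_mm, times_s = times_s, P = P),
            class = "pressure_map")
}

# block-average columns of a (position x frame) matrix down to target_fps
decimate_time <- function(M, source_fps, target_fps) {
  fac <- source_fps / target_fps
  if (abs(fac - round(fac)) > 1e-8)
    stop("source_fps must be an integer multiple of target_fps")
  fac <- as.integer(round(fac))
  if (fac == 1L) return(M)
  n_out <- ncol(M) %/% fac
  if (n_out < 1) stop("recording shorter than one output frame")
  idx <- rep(seq_len(n_out), each = fac)
  kept <- seq_len(n_out * fac)
  out <- t(apply(M[, kept, drop = FALSE], 1, function(r) tapply(r, idx, mean)))
  matrix(out, nrow = nrow(M), ncol = n_out)
}

# average pixel columns into dx_mm axial bins
bin_axial <- function(M, mm_per_pixel, dx_mm) {
  n_px <- nrow(M)
  pos_px <- (seq_len(n_px) - 0.5) * mm_per_pixel
  bin <- floor(pos_px / dx_mm)
  bin <- bin - min(bin)
  out <- apply(M, 2, function(col) tapply(col, bin, mean))
  positions <- (sort(unique(bin)) + 0.5) * dx_mm
  list(M = matrix(out, nrow = length(positions)), positions_mm = positions)
}

#' Build a spatiotemporal diameter map from a silhouette image stack
#'
#' Each frame is thresholded, a per-column diameter profile extracted, frames
#' block-averaged down to `target_fps` (anti-alias average, so constant input
#' is a fixed point) and pixel columns averaged into `dx_mm` axial bins.
#'
#' @param frames List of grayscale matrices (all the same shape), or a 3-D
#'   array with dim 3 = frame index.
#' @param calib A [calibration_config()].
#' @return A `diameter_map`: uniform `positions_mm` and `times_s` grids and a
#'   `D` matrix (position x time, mm).
#' @export
build_diameter_map <- function(frames, calib) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (length(frames) < 2) stop("need at least 2 frames")
  profiles <- vapply(frames, function(fr) {
    m <- binarize_frame(fr, calib$binarize_threshold)
    as.numeric(extract_diameter_profile(m, calib))
  }, numeric(ncol(frames[[1]])))
  profiles <- matrix(profiles, ncol = length(frames)) # pixel-column x frame
  M <- decimate_time(profiles, calib$source_fps, calib$target_fps)
  ax <- bin_axial(M, calib$mm_per_pixel, calib$dx_mm)
  dt <- 1 / calib$target_fps
  new_dmap(ax$positions_mm, (seq_len(ncol(ax$M)) - 1) * dt, ax$M)
}

#' Build a pressure map aligned to a diameter map
#'
#' Per-sensor series are shifted onto the video clock by `sync_offset_s`,
#' anti-alias block-averaged onto the map's 4 Hz time grid, then linearly
#' interpolated between sensors along position. Positions outside the sensor
#' span take the nearest sensor's value (held constant, never extrapolated).
#'
#' @param records A data frame with a `time_s` column and one column per
#'   sensor, or a list with elements `time_s` and `P` (matrix, time x sensor).
#' @param calib A [calibration_config()] whose `sensor_positions_mm` locate
#'   the sensor columns.
#' @param target A `diameter_map` supplying the output grids.
#' @return A `pressure_map` on the same grids as `target` (mmHg).
#' @export
build_pressure_map <- function(records, calib, target) {
  if (is.data.frame(records)) {
    time_s <- records$time_s
    P <- as.matrix(records[, setdiff(names(records), "time_s"), drop = FALSE])
  } else {
    time_s <- records$time_s
    P <- as.matrix(records$P)
  }
  sensors <- calib$sensor_positions_mm
  if (ncol(P) != length(sensors))
    stop("number of sensor columns does not match sensor_positions_mm")
  if (length(sensors) < 2) stop("need at least 2 sensors")
  if (is.unsorted(time_s, strictly = TRUE)) stop("non-monotone time stamps")
  span <- range(target$positions_mm)
  if (any(sensors < span[1] - 10 | sensors > span[2] + 10))
    stop("sensor positions outside preparation length")
  # onto the video clock
  t_video <- time_s + calib$sync_offset_s
  dt <- diff(target$times_s[1:2])
  # block-average each sensor onto the target time grid
  Pt <- vapply(seq_along(sensors), function(j) {
    vapply(target$times_s, function(tt) {
      w <- t_video >= tt - dt / 2 & t_video < tt + dt / 2
      if (!any(w)) {
        # hold nearest sample when a window is empty (edge of recording)
        P[which.min(abs(t_video - tt)), j]
      } else mean(P[w, j])
    }, numeric(1))
  }, numeric(length(target$times_s)))      # time x sensor
  # linear interpolation along position, ends held at nearest sensor
  Pout <- apply(Pt, 1, function(row)
    stats::approx(sensors, row, xout = target$positions_mm, rule = 2)$y)
  new_pmap(target$positions_mm, target$times_s,
           matrix(Pout, nrow = length(target$positions_mm)))
}

#' Combine matched diameter and pressure maps into one container
#'
#' @param dmap A `diameter_map`.
#' @param pmap A `pressure_map` on identical grids.
#' @param meta Named list; recognised fields: `id`, `condition` (one of
#'   `"control"`, `"ttx"`, `"synthetic"`).
#' @return A `dpmap` with `diameter`, `pressure` and `meta` (including
#'   derived `length_mm` and `duration_s`).
#' @export
bundle_dpmap <- function(dmap, pmap, meta = list()) {
  if (!isTRUE(all.equal(dmap$positions_mm, pmap$positions_mm)))
    stop("grid mismatch on position axis")
  if (!isTRUE(all.equal(dmap$times_s, pmap$times_s)))
    stop("grid mismatch on time axis")
  meta$condition <- meta$condition %||% "control"
  stopifnot(meta$condition %in% c("control", "ttx", "synthetic"))
  nt <- length(dmap$times_s)
  meta$length_mm <- diff(range(dmap$positions_mm)) + diff(dmap$positions_mm[1:2])
  meta$duration_s <- (nt - 1) * diff(dmap$times_s[1:2])
  structure(list(diameter = dmap, pressure = pmap, meta = meta),
            class = "dpmap")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dpmap <- function(x, ...) {
  cat(sprintf(
    "dpmap: %d positions x %d frames (%.0f mm, %.1f s at %.2f s/frame), condition '%s'\n",
    length(x$diameter$positions_mm), length(x$diameter$times_s),
    x$meta$length_mm, x$meta$duration_s, diff(x$diameter$times_s[1:2]),
    x$meta$condition))
  invisible(x)
}
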