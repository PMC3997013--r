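# 8-connected component labelling on a logical (position x time) matrix.
# Depth-first with an explicit stack; each cell is pushed at most once.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  if (length(idx) == 0) return(list(label = lab, n = 0L))
  stack <- integer(length(idx))
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    top <- 1L; stack[1L] <- s; lab[s] <- cur
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      i <- ((p - 1L) %% nr) + 1L
      j <- ((p - 1L) %/% nr) + 1L
      for (dj in -1L:1L) {
        jj <- j + dj
        if (jj < 1L || jj > nc) next
        base <- (jj - 1L) * nr
        for (di in -1L:1L) {
          if (di == 0L && dj == 0L) next
          ii <- i + di
          if (ii < 1L || ii > nr) next
          q <- base + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            top <- top + 1L; stack[top] <- q
          }
        }
      }
    }
  }
  list(label = lab, n = cur)
}

PROPAGATING_MIN_EXTENT_MM <- 20

#' Detect active-contraction events on a (neurogenic) state map
#'
#' Events are 8-connected components of `group == "active_contraction"` in
#' the position-time lattice (8-connectivity keeps an oblique propagating
#' streak in one piece). An event is propagating when its spatial extent is
#' at least 20 mm; its speed is the least-squares slope of the leading
#' (most anal) edge position against time; its initiation is the most oral
#' cell of its earliest frame.
#'
#' @param smap A `mech_state_map`, normally after [apply_myogenic_mask()].
#' @return A list of `active_contraction_event` objects, ordered by
#'   initiation time then position. Each has fields `cells` (two-column
#'   matrix of position/time indices), `extent_mm`, `duration_s`,
#'   `point_duration_s`, `speed_mm_s`, `initiation` (list with `x_mm`,
#'   `t_s`, indices) and `propagating`.
#' @export
find_events <- function(smap) {
  mask <- smap$group == "active_contraction"
  comp <- label_components8(mask)
  if (comp$n == 0L) return(list())
  pos <- smap$positions_mm
  tms <- smap$times_s
  dx <- if (length(pos) > 1) diff(pos[1:2]) else 1
  dt <- if (length(tms) > 1) diff(tms[1:2]) else 0.25
  nr <- nrow(mask)
  cells_idx <- which(comp$label > 0L)
  lab_at <- comp$label[cells_idx]
  ii <- ((cells_idx - 1L) %% nr) + 1L
  jj <- ((cells_idx - 1L) %/% nr) + 1L
  events <- lapply(seq_len(comp$n), function(k) {
    sel <- lab_at == k
    pi <- ii[sel]; ti <- jj[sel]
    extent <- (max(pi) - min(pi) + 1L) * dx
    duration <- (max(ti) - min(ti) + 1L) * dt
    point_dur <- mean(tabulate(pi - min(pi) + 1L,
                               nbins = max(pi) - min(pi) + 1L)[unique(pi) - min(pi) + 1L]) * dt
    # propagation speed: least-squares slope of the event's per-frame
    # spatial midline. The leading edge alone overshoots while the active
    # region grows at onset and freezes while it fades at termination;
    # the midline is insensitive to symmetric growth/decay and equals the
    # edge slope on steadily translating bands.
    frames <- sort(unique(ti))
    mid <- vapply(frames, function(f)
      (max(pi[ti == f]) + min(pi[ti == f])) / 2, numeric(1))
    nf <- length(frames)
    keep <- if (nf >= 10) (ceiling(0.1 * nf) + 1):(nf - ceiling(0.1 * nf))
            else seq_len(nf)
    speed <- if (length(keep) > 1) {
      x <- tms[frames[keep]]
      y <- pos[1] + (mid[keep] - 1) * dx
      sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    } else 0
    t0 <- min(ti)
    x0 <- min(pi[ti == t0])
    structure(list(
      cells = cbind(position_idx = pi, time_idx = ti),
      extent_mm = extent, duration_s = duration,
      point_duration_s = point_dur, speed_mm_s = speed,
      initiation = list(position_idx = x0, time_idx = t0,
                        x_mm = pos[x0], t_s = tms[t0]),
      propagating = extent >= PROPAGATING_MIN_EXTENT_MM
    ), class = "active_contraction_event")
  })
  ord <- order(vapply(events, function(e) e$initiation$t_s, numeric(1)),
               vapply(events, function(e) e$initiation$x_mm, numeric(1)))
  events[ord]
}

#' Initiation window around an active-contraction event
#'
#' Examines the muscle state around the site and moment of initiation: a
#' spatial window 40 mm oral and 80 mm anal of the initiation site, 2 s
#' either side of the initiation moment. Events initiating within 40 mm of
#' the oral end or 80 mm of the anal end are flagged `excluded` (their
#' window would be truncated) and contribute to no group statistic.
#'
#' @param event An `active_contraction_event`.
#' @param dmap The `diameter_map` of the recording.
#' @param smap The neurogenic `mech_state_map`.
#' @param oral_span_mm,anal_span_mm,time_span_s Window geometry (defaults
#'   40 mm, 80 mm, 2 s).
#' @return A one-row data frame: `x_mm`, `t_s`, `mean_dilation_mm` (mean
#'   increase over the per-position baseline in the 2 s before initiation,
#'   within 5 mm of the initiation site -- the distension at the site of
#'   initiation), `window_dilation_mm` (same average over the whole
#'   120 mm window), `anal_inhibition` (fraction of anal-window cells in
#'   active relaxation pre-initiation), `excluded`.
#' @export
initiation_stats <- function(event, dmap, smap,
                             oral_span_mm = 40, anal_span_mm = 80,
                             time_span_s = 2) {
  pos <- dmap$positions_mm
  tms <- dmap$times_s
  x0 <- event$initiation$x_mm
  t0 <- event$initiation$t_s
  excluded <- (x0 - min(pos)) < oral_span_mm || (max(pos) - x0) < anal_span_mm
  baseline <- apply(dmap$D, 1, stats::quantile, probs = 0.05, names = FALSE)
  win_x <- pos >= x0 - oral_span_mm & pos <= x0 + anal_span_mm
  site_x <- pos >= x0 - 5 & pos <= x0 + 5
  pre_t <- tms >= t0 - time_span_s & tms < t0
  dil_site <- dmap$D[site_x, pre_t, drop = FALSE] - baseline[site_x]
  dil_win <- dmap$D[win_x, pre_t, drop = FALSE] - baseline[win_x]
  anal_x <- pos > x0 & pos <= x0 + anal_span_mm
  anal_cells <- smap$group[anal_x, pre_t, drop = FALSE]
  anal_inh <- if (length(anal_cells)) mean(anal_cells == "active_relaxation") else 0
  data.frame(x_mm = x0, t_s = t0,
             mean_dilation_mm = if (length(dil_site)) mean(dil_site) else NA_real_,
             window_dilation_mm = if (length(dil_win)) mean(dil_win) else NA_real_,
             anal_inhibition = anal_inh, excluded = excluded,
             propagating = event$propagating)
}

#' Compare initiation conditions of propagating vs non-propagating events
#'
#' Mann-Whitney U on the pre-initiation mean dilation, and Fisher's exact
#' test on the 2x2 table of (propagating vs not) x (anal active relaxation
#' present vs absent in the pre-initiation window). Excluded windows are
#' dropped first.
#'
#' @param propagating_windows,nonpropagating_windows Data frames of rows
#'   from [initiation_stats()].
#' @return List with `mann_whitney` and `fisher` (`test_result`s), group
#'   means and the 2x2 `inhibition_table`.
#' @export
compare_initiations <- function(propagating_windows, nonpropagating_windows) {
  p <- propagating_windows[!propagating_windows$excluded, , drop = FALSE]
  np <- nonpropagating_windows[!nonpropagating_windows$excluded, , drop = FALSE]
  if (nrow(p) == 0 || nrow(np) == 0)
    stop("both groups must contain at least one non-excluded window")
  if (nrow(p) < 5 || nrow(np) < 5)
    warning("fewer than 5 windows in a group; tests will have little power")
  mw <- mann_whitney_u(p$mean_dilation_mm, np$mean_dilation_mm)
  tab <- matrix(c(sum(p$anal_inhibition > 0), sum(p$anal_inhibition == 0),
                  sum(np$anal_inhibition > 0), sum(np$anal_inhibition == 0)),
                2, 2, byrow = TRUE,
                dimnames = list(c("propagating", "non_propagating"),
                                c("inhibition", "no_inhibition")))
  fis <- if (any(colSums(tab) == 0)) NULL else fisher_exact_2x2(tab)
  list(mann_whitney = mw, fisher = fis,
       mean_dilation_propagating = mean(p$mean_dilation_mm),
       mean_dilation_nonpropagating = mean(np$mean_dilation_mm),
       inhibition_table = tab)
}

#' Summarise detected events
#'
#' @param events List from [find_events()].
#' @param duration_s Recording duration in seconds (> 0).
#' @return List with `n_events`, `n_propagating`, `rate_per_10min`
#'   (propagating), `intervals_s` between successive propagating
#'   initiations, `distances_cm`, `speeds_mm_s` and `point_durations_s`
#'   of propagating events (each with mean and sd), and `table` (one row
#'   per event, exportable via [export_events_csv()]).
#' @export
summarize_events <- function(events, duration_s) {
  if (duration_s <= 0) stop("recording duration must be positive")
  tab <- do.call(rbind, lapply(seq_along(events), function(i) {
    e <- events[[i]]
    data.frame(id = i, t0_s = e$initiation$t_s, x0_mm = e$initiation$x_mm,
               extent_mm = e$extent_mm, duration_s = e$duration_s,
               point_duration_s = e$point_duration_s,
               speed_mm_s = e$speed_mm_s, propagating = e$propagating)
  }))
  if (is.null(tab))
    tab <- data.frame(id = integer(0), t0_s = numeric(0), x0_mm = numeric(0),
                      extent_mm = numeric(0), duration_s = numeric(0),
                      point_duration_s = numeric(0), speed_mm_s = numeric(0),
                      propagating = logical(0))
  prop <- tab[tab$propagating, , drop = FALSE]
  msd <- function(x) c(mean = if (length(x)) mean(x) else NA_real_,
                       sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  list(
    n_events = nrow(tab),
    n_propagating = nrow(prop),
    rate_per_10min = nrow(prop) * 600 / duration_s,
    intervals_s = if (nrow(prop) > 1) diff(sort(prop$t0_s)) else numeric(0),
    distances_cm = msd(prop$extent_mm / 10),
    speeds_mm_s = msd(prop$speed_mm_s),
    point_durations_s = msd(prop$point_duration_s),
    table = tab
  )
}
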