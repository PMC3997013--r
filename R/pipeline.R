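#' Run the full analysis pipeline
#'
#' One-call orchestration: derivatives and trend decoding, twelve-state
#' classification, myogenic-threshold calibration on the nerve-blocked
#' recording, masking, event detection, initiation analysis, bolus tracking
#' and speed binning, state profiles and the dilation/length-relaxation
#' relations. Deterministic: re-running on the same inputs reproduces the
#' report bit for bit.
#'
#' @param control A `dpmap` of the control recording (or the list returned
#'   by [generate_preparation()]).
#' @param ttx A `dpmap` of the nerve-blocked recording used to calibrate
#'   the myogenic threshold (or a [generate_ttx()] result). Required.
#' @param smooth_frames,p_stay Classifier parameters.
#' @param q Myogenic-threshold quantile (default 0.95).
#' @param control_seed Seed for the random-point control profile.
#' @return An `analysis_report` list: `threshold`, `states` (neurogenic
#'   map), `events`, `event_summary`, `initiation` (window table and test
#'   results, when both groups are present), `boluses`, `bolus_table`,
#'   `profiles` (per speed bin present), `random_control`,
#'   `length_relaxation` (when both classes present), `provenance`.
#' @export
run_full_analysis <- function(control, ttx, smooth_frames = 5,
                              p_stay = 0.95, q = 0.95,
                              control_seed = 1L) {
  if (is.list(control) && !inherits(control, "dpmap")) control <- control$dpmap
  if (is.null(ttx)) stop("a TTX recording is required to calibrate the myogenic threshold")
  if (is.list(ttx) && !inherits(ttx, "dpmap")) ttx <- ttx$dpmap
  params <- trend_hmm_params(p_stay)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))

  thr <- stage("calibrate_threshold",
               calibrate_threshold(ttx, q, smooth_frames, params))
  smap <- stage("classify", classify_dpmap(control, smooth_frames, params))
  seg <- stage("orbit_segments", extract_orbit_segments(control, smap))
  neuro <- stage("myogenic_mask", apply_myogenic_mask(smap, seg, thr))
  events <- stage("find_events", find_events(neuro))
  esum <- stage("summarize", summarize_events(events, control$meta$duration_s))

  windows <- do.call(rbind, lapply(events, initiation_stats,
                                   dmap = control$diameter, smap = neuro))
  initiation <- NULL
  if (!is.null(windows)) {
    pw <- windows[windows$propagating & !windows$excluded, , drop = FALSE]
    nw <- windows[!windows$propagating & !windows$excluded, , drop = FALSE]
    if (nrow(pw) > 0 && nrow(nw) > 0)
      initiation <- c(stage("compare_initiations",
                            suppressWarnings(compare_initiations(pw, nw))),
                      list(windows = windows))
    else initiation <- list(windows = windows)
  }

  boluses <- stage("detect_boluses", detect_boluses(control$diameter))
  boluses <- lapply(boluses, function(b)
    if (nrow(b$track) >= 3) estimate_speed(b) else { b$speed_mm_s <- NA; b$speed_bin <- NA; b })
  btab <- bolus_table(boluses, neuro)
  bins_present <- unique(stats::na.omit(vapply(
    boluses, function(b) b$speed_bin %||% NA_character_, character(1))))
  profiles <- lapply(stats::setNames(bins_present, bins_present),
                     function(bn) state_profile(boluses, neuro, bin = bn))
  rand_prof <- stage("random_control",
                     random_point_control(neuro, 500, seed = control_seed))
  lenrel <- tryCatch(length_relaxation_test(boluses, neuro),
                     error = function(e) NULL)
  dilrel <- tryCatch(dilation_relaxation_curve(boluses, neuro),
                     error = function(e) NULL)

  structure(list(
    threshold = thr, states = neuro, events = events,
    event_summary = esum, initiation = initiation,
    boluses = boluses, bolus_table = btab, profiles = profiles,
    random_control = rand_prof,
    length_relaxation = lenrel, dilation_relaxation = dilrel,
    provenance = list(smooth_frames = smooth_frames, p_stay = p_stay,
                      q = q, control_seed = control_seed,
                      package_version = as.character(utils::packageVersion("peristalmap")))
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Peristalsis analysis report\n")
  cat(sprintf("  myogenic threshold: %.3f (q = %.2f, %d segments)\n",
              x$threshold$value, x$threshold$q, x$threshold$n_segments))
  cat(sprintf("  events: %d (%d propagating, %.1f per 10 min)\n",
              x$event_summary$n_events, x$event_summary$n_propagating,
              x$event_summary$rate_per_10min))
  if (!is.null(x$initiation$mann_whitney))
    cat(sprintf("  pre-dilation: %.2f mm (propagating) vs %.2f mm, Mann-Whitney P = %.3g\n",
                x$initiation$mean_dilation_propagating,
                x$initiation$mean_dilation_nonpropagating,
                x$initiation$mann_whitney$p_value))
  cat(sprintf("  boluses tracked: %d\n", length(x$boluses)))
  invisible(x)
}
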