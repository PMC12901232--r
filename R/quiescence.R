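# Quiescent-phase detection: timepoints on the averaged LV time curve,
# interval widths with the 200 ms cap, per-beat acceptance windows, and the
# end-to-end detection pipeline with its S3 interface.

#' Algorithm configuration
#'
#' Tunable parameters of the detection pipeline with their defaults: 50
#' CINE frames, Gaussian kernel sigma 5% of the cycle, top 25% of
#' synchronicity regions retained, amplitude threshold of +/- 3% of the
#' normalized time curve for interval detection, iteratively lowered in
#' steps of 0.25% until the interval duration (via the mean RR) is below
#' the 200 ms cap recommended by standardized protocols.
#'
#' @param n_frames CINE frames per cycle.
#' @param kernel_pct Gaussian phase-kernel sigma (% of cycle).
#' @param top_region_fraction Fraction of regions kept by size ranking.
#' @param amplitude_threshold_pct Initial amplitude band (+/- %, of the
#'   normalized curve) for quiescent-interval detection.
#' @param max_interval_ms Interval duration cap (ms).
#' @param threshold_step_pct Threshold-lowering step (%).
#' @param intensity_floor_fraction Voxel validity floor (fraction of the
#'   global mean intensity).
#' @param min_region_voxels Minimum synchronicity-region size.
#' @param stretch_a,stretch_b Systolic-interval model `ET = a - b HR`.
#' @param margins Physiological-filter acceptance margins (low, high).
#' @param cardiac_band_hz,resp_band_hz Self-gating frequency bands.
#' @param flat_rel_range Detection-failure floor: minimum raw curve range
#'   relative to its mean intensity.
#' @return List of class `sync_control`.
#' @export
sync_control <- function(n_frames = 50, kernel_pct = 5,
                         top_region_fraction = 0.25,
                         amplitude_threshold_pct = 3, max_interval_ms = 200,
                         threshold_step_pct = 0.25,
                         intensity_floor_fraction = 0.2,
                         min_region_voxels = 10,
                         stretch_a = 546, stretch_b = 2.1,
                         margins = c(0.3, 0.3),
                         cardiac_band_hz = c(0.7, 3.0),
                         resp_band_hz = c(0.1, 0.5),
                         flat_rel_range = 0.05) {
  stopifnot(n_frames >= 2, kernel_pct > 0, top_region_fraction > 0,
            top_region_fraction <= 1, amplitude_threshold_pct > 0,
            amplitude_threshold_pct <= 50, max_interval_ms > 0,
            threshold_step_pct > 0)
  structure(as.list(environment()), class = "sync_control")
}

circ_mid_pct <- function(a, b) (a + ((b - a) %% 100) / 2) %% 100

#' Detect the quiescent-phase timepoints on the averaged time curve
#'
#' End-systole is the curve minimum and end-diastole the maximum (taken
#' circularly after end-systole). Mid-diastole is the circular midpoint
#' between the first knee after end-systole — the point of maximum
#' perpendicular distance to the chord from the minimum to the maximum over
#' the rising limb (Kneedle-style) — and end-diastole.
#'
#' Extrema are localized with parabolic sub-frame refinement (a three-point
#' parabola through the extremum and its circular neighbours), which removes
#' the half-frame quantization of the 50-frame sampling.
#'
#' @param curve Normalized mean time curve ([mean_time_curve()]).
#' @param flat_rel_range Failure floor on the raw curve range relative to
#'   its mean (applies when the curve carries a `raw_range` attribute).
#' @return List: `t_pct` (named ES/MD/ED phases in %), `idx` (1-based
#'   frame indices; MD rounded to the nearest frame), `knee_pct`.
#' @export
detect_timepoints <- function(curve, flat_rel_range = 0.05) {
  nf <- length(curve)
  rr <- attr(curve, "raw_range")
  if (!is.null(rr) && diff(rr) < flat_rel_range * mean(rr)) {
    stop("detection failure: time curve is flat")
  }
  step <- 100 / nf
  centers <- step * (seq_len(nf) - 1)
  refine <- function(i) {     # circular 3-point parabolic vertex offset
    y0 <- curve[((i - 2) %% nf) + 1]; y1 <- curve[i]
    y2 <- curve[(i %% nf) + 1]
    den <- y0 - 2 * y1 + y2
    if (abs(den) < 1e-12) return(0)
    max(-0.5, min(0.5, 0.5 * (y0 - y2) / den))
  }
  i_es <- which.min(curve)
  i_ed <- which.max(curve)
  dd <- ((i_ed - i_es) %% nf)
  if (dd == 0) stop("detection failure: degenerate extrema")
  rising <- ((seq_len(nf) - i_es) %% nf)
  cand <- which(rising > 0 & rising < dd)
  # perpendicular distance to the chord in (phase distance %, value) space
  x <- rising[cand] * step
  y <- curve[cand]
  x2 <- dd * step; y2 <- curve[i_ed]; y1 <- curve[i_es]
  dist <- abs((y2 - y1) * x - x2 * (y - y1)) / sqrt(x2^2 + (y2 - y1)^2)
  i_knee <- cand[which.max(dist)]
  knee_pct <- centers[i_knee]
  es_pct <- (centers[i_es] + refine(i_es) * step) %% 100
  ed_pct <- (centers[i_ed] + refine(i_ed) * step) %% 100
  md_pct <- circ_mid_pct(knee_pct, ed_pct)
  i_md <- (round(md_pct / step) %% nf) + 1
  list(t_pct = c(ES = es_pct, MD = md_pct, ED = ed_pct),
       idx = c(ES = i_es, MD = i_md, ED = i_ed), knee_pct = knee_pct)
}

#' Detect a quiescent interval around a timepoint
#'
#' The interval is the maximal contiguous (circular) span of frames
#' containing the timepoint whose curve values stay within `tau` (%) of the
#' curve value at the timepoint; `tau` starts at
#' `amplitude_threshold_pct` and is iteratively lowered by
#' `threshold_step_pct` until the span's duration via the mean RR is below
#' `max_interval_ms`. If `tau` reaches zero without meeting the cap a
#' single-frame interval is returned with a warning.
#'
#' @param curve Normalized mean time curve.
#' @param t_idx 1-based frame index of the timepoint.
#' @param mean_rr_ms Mean RR interval (ms).
#' @param control A [sync_control()].
#' @return List: `start_pct`, `end_pct` (frame-edge phases), `n_frames`,
#'   `duration_pct`, `duration_ms`, `tau_pct`, `capped` (logical: fell back
#'   to a single frame).
#' @export
detect_intervals <- function(curve, t_idx, mean_rr_ms,
                             control = sync_control()) {
  nf <- length(curve)
  step <- 100 / nf
  tau <- control$amplitude_threshold_pct
  capped <- FALSE
  repeat {
    within <- abs(curve - curve[t_idx]) <= tau / 100
    # grow the contiguous circular run outward from t_idx
    lo <- 0
    while (lo < nf - 1 && within[((t_idx - 1 - lo - 1) %% nf) + 1]) lo <- lo + 1
    hi <- 0
    while (hi < nf - 1 - lo && within[((t_idx - 1 + hi + 1) %% nf) + 1]) hi <- hi + 1
    n_span <- 1 + lo + hi
    dur_ms <- n_span * step * mean_rr_ms / 100
    if (dur_ms < control$max_interval_ms) break
    tau <- tau - control$threshold_step_pct
    if (tau <= 0) {
      warning("threshold exhausted: returning a single-frame interval")
      lo <- 0; hi <- 0; n_span <- 1
      dur_ms <- step * mean_rr_ms / 100
      capped <- TRUE
      break
    }
  }
  start_pct <- (step * (t_idx - 1 - lo) - step / 2) %% 100
  list(start_pct = start_pct,
       end_pct = (start_pct + n_span * step) %% 100,
       n_frames = n_span, duration_pct = n_span * step,
       duration_ms = dur_ms, tau_pct = max(tau, 0), capped = capped)
}

#' Map quiescent intervals to per-beat acceptance windows
#'
#' For each beat and each cardiac phase of interest the phase-% interval is
#' mapped to an absolute time window `[onset + start% RR, onset + end% RR]`
#' — both center and width adapt to every beat's own RR. Intervals that
#' wrap phase 0 produce two sub-windows within the beat. A per-line
#' selection mask is derived by circular phase membership.
#'
#' @param intervals Named list of [detect_intervals()] results.
#' @param beats A [beat_sequence()].
#' @param line_phase_pct Per-line phases ([normalize_phases()] against the
#'   same beats); `NA` lines are never selected.
#' @param line_time_ms Optional per-line timestamps kept for reference.
#' @return Object of class `acceptance_window_set`: per target `windows`
#'   (data frame beat/start_ms/end_ms) and `mask` (logical per line);
#'   plus `selected_fraction` per target.
#' @export
build_acceptance_windows <- function(intervals, beats, line_phase_pct,
                                     line_time_ms = NULL) {
  stopifnot(inherits(beats, "beat_sequence"))
  on <- beats$r_times_ms
  rr <- beats$rr_ms
  nb <- length(rr)
  out <- lapply(intervals, function(iv) {
    s <- iv$start_pct; dur <- iv$duration_pct
    e <- s + dur
    if (e <= 100) {
      win <- data.frame(beat = seq_len(nb),
                        start_ms = on[-length(on)] + s / 100 * rr,
                        end_ms = on[-length(on)] + e / 100 * rr)
    } else {                      # wraps phase 0: two sub-windows per beat
      win <- rbind(
        data.frame(beat = seq_len(nb), start_ms = on[-length(on)] + s / 100 * rr,
                   end_ms = on[-length(on)] + rr),
        data.frame(beat = seq_len(nb), start_ms = on[-length(on)],
                   end_ms = on[-length(on)] + (e - 100) / 100 * rr))
      win <- win[order(win$start_ms), ]
    }
    mask <- !is.na(line_phase_pct) &
      ((line_phase_pct - s) %% 100) <= dur
    list(windows = win, mask = mask)
  })
  structure(list(targets = out,
                 selected_fraction = vapply(out, function(t)
                   mean(t$mask), numeric(1)),
                 line_time_ms = line_time_ms),
            class = "acceptance_window_set")
}

#' Detect quiescent cardiac phases in a free-running dataset
#'
#' Runs the full pipeline on a raw free-running dataset: self-gating signal
#' extraction and beat detection (or external trigger times), per-line
#' phase normalization, preliminary Gaussian-kernel CINE, synchronicity map
#' (phase-of-minimum + 26-connectivity), region refinement (size ranking
#' and physiological filter), averaged LV time curve, quiescent timepoint
#' and interval detection, and per-beat adaptive acceptance windows.
#'
#' @param dataset A simulated dataset ([simulate_freerun()]) or a list with
#'   `kspace` (a `kspace_set` including its trajectory) and optional
#'   `triggers` (external beat-onset times, ms).
#' @param control A [sync_control()].
#' @param beats `"selfgating"` (default) or `"trigger"` (use the external
#'   trigger channel instead of detected beats).
#' @param keep_cine Keep the preliminary CINE frames in the result (large).
#' @return Object of class `quiescence`; see [coef.quiescence()],
#'   [summary.quiescence()], [predict.quiescence()], [plot.quiescence()].
#' @export
quiescence <- function(dataset, control = sync_control(),
                       beats = c("selfgating", "trigger"),
                       keep_cine = FALSE) {
  beats <- match.arg(beats)
  ks <- dataset$kspace
  traj <- ks$traj
  if (is.null(ks$plan)) ks$plan <- nufft_plan(traj)
  sg <- NULL
  if (beats == "trigger") {
    if (is.null(dataset$triggers)) stop("dataset has no trigger channel")
    bs <- beat_sequence(dataset$triggers)
  } else {
    sg <- extract_cardiac_sg(si_profiles(ks, traj),
                             cardiac_band_hz = control$cardiac_band_hz,
                             resp_band_hz = control$resp_band_hz)
    bs <- detect_beats(sg)
  }
  ph <- normalize_phases(traj$time_ms, bs)
  mean_rr <- mean(bs$rr_ms)
  cine <- cine_recon(ks, ph, n_frames = control$n_frames,
                     kernel_pct = control$kernel_pct)
  mp <- compute_min_phase_map(cine, control$intensity_floor_fraction)
  sync_all <- connected_regions(mp, control$min_region_voxels)
  sync_top <- select_top_regions(sync_all, control$top_region_fraction)
  model <- stretch_model(a = control$stretch_a, b = control$stretch_b)
  sync <- filter_physiological(sync_top, cine, mean_rr, model,
                               control$margins)
  curve <- mean_time_curve(cine, sync)
  tp <- detect_timepoints(curve, control$flat_rel_range)
  ivs <- lapply(tp$idx, function(i)
    detect_intervals(curve, i, mean_rr, control))
  win <- build_acceptance_windows(ivs, bs, ph, traj$time_ms)
  structure(list(
    t_pct = tp$t_pct, t_ms = tp$t_pct * mean_rr / 100,
    knee_pct = tp$knee_pct, intervals = ivs, windows = win,
    curve = curve, beats = bs, mean_rr_ms = mean_rr,
    line_phase_pct = ph, sg = sg, beat_source = beats,
    sync = sync, sync_sizes = sync_all$regions,
    cine = if (keep_cine) cine else NULL,
    n_lines = ncol(ks$samples), control = control),
    class = "quiescence")
}

#' @export
print.quiescence <- function(x, ...) {
  cat("Quiescent cardiac phase detection (", x$beat_source, " beats)\n", sep = "")
  cat(sprintf("  %d beats, mean RR %.0f ms (HR %.0f bpm)\n",
              length(x$beats$rr_ms), x$mean_rr_ms, 60000 / x$mean_rr_ms))
  for (k in names(x$t_pct)) {
    iv <- x$intervals[[k]]
    cat(sprintf("  %-2s: t = %5.1f%% (%4.0f ms), interval %5.1f%% (%3.0f ms)\n",
                k, x$t_pct[[k]], x$t_ms[[k]], iv$duration_pct, iv$duration_ms))
  }
  invisible(x)
}

#' Detected timepoints
#' @param object A `quiescence` fit.
#' @param units `"pct"` (cardiac phase %) or `"ms"` (via the mean RR).
#' @param ... Unused.
#' @return Named vector (ES, MD, ED).
#' @export
coef.quiescence <- function(object, units = c("pct", "ms"), ...) {
  units <- match.arg(units)
  if (units == "pct") object$t_pct else object$t_ms
}

#' @export
summary.quiescence <- function(object, ...) {
  s <- list(fit = object,
            regions = object$sync$regions,
            selected_fraction = object$windows$selected_fraction)
  class(s) <- "summary.quiescence"
  s
}

#' @export
print.summary.quiescence <- function(x, ...) {
  print(x$fit)
  cat("Synchronicity regions retained:\n")
  print(x$regions, row.names = FALSE)
  cat("Selected data fraction per phase:\n")
  print(round(x$selected_fraction, 3))
  invisible(x)
}

#' Acceptance windows for a (possibly new) beat sequence
#'
#' Re-maps the detected phase-% intervals to per-beat windows, e.g. for
#' trigger-derived beats.
#' @param object A `quiescence` fit.
#' @param newbeats A [beat_sequence()]; defaults to the fit's own beats.
#' @param line_time_ms Line timestamps to mask (defaults to none).
#' @param ... Unused.
#' @return An `acceptance_window_set`.
#' @export
predict.quiescence <- function(object, newbeats = object$beats,
                               line_time_ms = numeric(0), ...) {
  ph <- normalize_phases(line_time_ms, newbeats)
  build_acceptance_windows(object$intervals, newbeats, ph, line_time_ms)
}

#' Plot the averaged time curve with detected phases and intervals
#' @param x A `quiescence` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.quiescence <- function(x, ...) {
  nf <- length(x$curve)
  p <- 100 * (seq_len(nf) - 1) / nf
  graphics::plot(p, x$curve, type = "l", xlab = "cardiac phase (%)",
                 ylab = "normalized LV intensity", ...)
  cols <- c(ES = "blue", MD = "darkgreen", ED = "red")
  for (k in names(x$t_pct)) {
    iv <- x$intervals[[k]]
    graphics::abline(v = x$t_pct[[k]], col = cols[[k]])
    e <- iv$start_pct + iv$duration_pct
    graphics::rect(iv$start_pct, -0.02, min(e, 100), 0,
                   col = grDevices::adjustcolor(cols[[k]], 0.4), border = NA)
    if (e > 100) graphics::rect(0, -0.02, e - 100, 0,
                                col = grDevices::adjustcolor(cols[[k]], 0.4),
                                border = NA)
  }
  graphics::legend("topright", names(cols), col = cols, lty = 1, bty = "n")
  invisible(x)
}
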