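# Reference reconstructions: manually parameterized acceptance windows with
# fixed (ms) or adaptive (% of each beat's RR) geometry, against which the
# automated adaptive windows are compared.

#' Scout-derived manual acceptance-window parameters
#'
#' Emulates the conventional prospective workflow: the scout RR is the mean
#' RR over the first ten seconds of the acquisition, and the operator's
#' mid-diastolic trigger delay and window width are expressed in ms of that
#' scout RR. In `"ground_truth"` mode (automated testing) the delay is
#' derived from the phantom ground truth: `delay = t_MD - width / 2`, with
#' the width capped at 200 ms; `"manual"` mode takes user-entered values.
#'
#' @param dataset A `freerun_dataset` of at least 10 s.
#' @param mode `"ground_truth"` or `"manual"`.
#' @param width_ms Acceptance window width (ms). In ground-truth mode the
#'   default is the "expert" choice: the ground-truth diastolic plateau
#'   duration at the scout RR. Widths are always capped at 200 ms.
#' @param delay_ms Trigger delay (ms), required in manual mode.
#' @return Object of class `manual_params`: `trigger_delay_ms`,
#'   `window_width_ms`, `scout_rr_ms`, `center_pct`, `width_pct`.
#' @export
scout_params <- function(dataset, mode = c("ground_truth", "manual"),
                         width_ms = NULL, delay_ms = NULL) {
  mode <- match.arg(mode)
  beats <- dataset$beats_true
  if (max(beats$r_times_ms) < 10000) {
    stop("scan shorter than the 10 s scout period")
  }
  scout <- beats$rr_ms[beats$r_times_ms[-length(beats$r_times_ms)] < 10000]
  scout_rr <- mean(scout)
  if (mode == "ground_truth") {
    gt <- dataset$ground_truth
    if (is.null(width_ms)) {
      width_ms <- diff(gt$plateau_pct) / 100 * scout_rr
    }
    width_ms <- min(width_ms, 200)
    t_md_ms <- gt$t_lin_pct[["MD"]] / 100 * scout_rr
    delay_ms <- t_md_ms - width_ms / 2
  } else if (is.null(delay_ms) || is.null(width_ms)) {
    stop("manual mode requires delay_ms and width_ms")
  } else {
    width_ms <- min(width_ms, 200)
  }
  if (width_ms <= 0 || delay_ms + width_ms >= scout_rr) {
    stop("invalid manual parameters: delay + width must fit in the scout RR")
  }
  structure(list(trigger_delay_ms = delay_ms, window_width_ms = width_ms,
                 scout_rr_ms = scout_rr,
                 center_pct = (delay_ms + width_ms / 2) / scout_rr * 100,
                 width_pct = width_ms / scout_rr * 100),
            class = "manual_params")
}

#' Fixed-geometry manual acceptance windows
#'
#' Per beat: `[onset + delay, onset + delay + width]` in ms, identical for
#' every beat; windows extending past the beat end are clipped (and
#' counted), beats shorter than the delay get an empty window.
#'
#' @param params A [scout_params()] result.
#' @param beats A [beat_sequence()] (the beats used for reconstruction).
#' @param line_time_ms Per-line timestamps for the selection mask.
#' @return An `acceptance_window_set` with a single `MD` target;
#'   `n_clipped` and `n_empty` report the clipping statistics.
#' @export
windows_manual_fixed <- function(params, beats, line_time_ms) {
  stopifnot(inherits(params, "manual_params"), inherits(beats, "beat_sequence"))
  on <- beats$r_times_ms
  starts <- on[-length(on)] + params$trigger_delay_ms
  ends <- pmin(starts + params$window_width_ms, on[-1])
  empty <- starts >= on[-1]
  clipped <- !empty & (starts + params$window_width_ms > on[-1])
  starts[empty] <- NA; ends[empty] <- NA
  mask <- rep(FALSE, length(line_time_ms))
  for (b in which(!empty)) {
    mask <- mask | (line_time_ms >= starts[b] & line_time_ms <= ends[b])
  }
  win <- data.frame(beat = seq_along(starts), start_ms = starts, end_ms = ends)
  structure(list(targets = list(MD = list(windows = win[!empty, ],
                                          mask = mask)),
                 selected_fraction = c(MD = mean(mask)),
                 n_clipped = sum(clipped), n_empty = sum(empty),
                 line_time_ms = line_time_ms),
            class = "acceptance_window_set")
}

#' Adaptive-geometry manual acceptance windows
#'
#' The scout-derived center and width, expressed as % of the scout RR, are
#' applied per beat to that beat's own RR — the same mechanics as the
#' automated adaptive windows, with manual inputs.
#'
#' @inheritParams windows_manual_fixed
#' @return An `acceptance_window_set` with a single `MD` target.
#' @export
windows_manual_adapt <- function(params, beats, line_time_ms) {
  stopifnot(inherits(params, "manual_params"))
  iv <- list(start_pct = (params$center_pct - params$width_pct / 2) %% 100,
             duration_pct = params$width_pct)
  ph <- normalize_phases(line_time_ms, beats)
  w <- build_acceptance_windows(list(MD = iv), beats, ph, line_time_ms)
  w
}

#' Reconstruct the data selected by a set of acceptance windows
#'
#' @param kspace A `kspace_set`.
#' @param windows An `acceptance_window_set`.
#' @param target Which target's mask to use (default `"MD"`).
#' @param plan Optional [nufft_plan()].
#' @return 3D magnitude volume ([gridded_recon()] of the selected lines).
#' @export
reconstruct_selection <- function(kspace, windows, target = "MD",
                                  plan = kspace$plan) {
  mask <- windows$targets[[target]]$mask
  if (is.null(mask) || !any(mask)) {
    stop("empty selection for target ", target,
         ": no lines fall inside the acceptance windows")
  }
  gridded_recon(kspace, as.numeric(mask), plan)
}
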