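# Validation metrics: temporal error, volumetric error, vessel sharpness,
# and the simulation-grid experiment.

#' Signed circular difference between cardiac phases
#' @param a,b Phases in % of the cycle.
#' @return Difference in `(-50, 50]` %.
#' @export
circular_diff_pct <- function(a, b) {
  d <- (a - b) %% 100
  ifelse(d > 50, d - 100, d)
}

#' Temporal detection error
#'
#' Signed circular difference between a detected and a ground-truth cardiac
#' phase, converted to ms via the mean RR interval.
#'
#' @param detected_pct,truth_pct Phases in % (same reference frame).
#' @param mean_rr_ms Mean RR interval (ms).
#' @return Signed error in ms.
#' @export
temporal_error <- function(detected_pct, truth_pct, mean_rr_ms) {
  circular_diff_pct(detected_pct, truth_pct) * mean_rr_ms / 100
}

#' Evaluate the LV volume curve at arbitrary phases
#'
#' Periodic linear interpolation of the 50 sampled curve values.
#' @param curve A [make_volume_curve()] result.
#' @param phase_pct Phases in % (curve phase).
#' @return Volumes in mL.
#' @export
curve_volume_at <- function(curve, phase_pct) {
  p <- curve$phases_pct
  step <- p[2] - p[1]
  v <- c(curve$v_of_phase, curve$v_of_phase[1])
  q <- phase_pct %% 100
  i <- floor(q / step)
  f <- q / step - i
  v[i + 1] * (1 - f) + v[i + 2] * f
}

#' Map a linear beat fraction to curve (stretched) phase
#'
#' Forward stretch map, the inverse of [linear_phase_of()].
#' @param lin_pct Linear phase in % of the beat.
#' @param rr_ms Beat duration (ms).
#' @param stretch A [stretch_model()].
#' @return Curve phase in %.
#' @export
curve_phase_of <- function(lin_pct, rr_ms, stretch = stretch_model()) {
  n <- max(length(lin_pct), length(rr_ms))
  f <- rep_len((lin_pct %% 100) / 100, n)
  if (!stretch$enabled) return(100 * f)
  fs <- rep_len(systolic_fraction(stretch, rr_ms), n)
  tes <- stretch$t_es_pct
  ifelse(f <= fs, tes * f / fs, tes + (100 - tes) * (f - fs) / (1 - fs))
}

#' Volumetric detection error
#'
#' Percent difference between the LV volume occurring at the detected
#' timepoint and at the ground-truth timepoint,
#' `100 |V(detected) - V(truth)| / V(truth)`, with volumes by periodic
#' linear interpolation of the curve. Phases are in curve-phase units.
#'
#' @param curve A [make_volume_curve()] result.
#' @param detected_pct,truth_pct Curve phases in %.
#' @return Error in %.
#' @export
volumetric_error <- function(curve, detected_pct, truth_pct) {
  vt <- curve_volume_at(curve, truth_pct)
  if (any(vt == 0)) stop("volumetric error undefined: zero reference volume")
  100 * abs(curve_volume_at(curve, detected_pct) - vt) / vt
}

#' Per-beat-averaged volumetric detection error
#'
#' The volumetric error of a detection over a whole acquisition: a detected
#' phase (% of each beat) is mapped through the stretch model of every
#' individual beat to a curve phase, the LV volume occurring at each of
#' those per-beat timepoints is averaged, and compared with the volume at
#' the true event (which occurs at the same curve phase in every beat).
#' With no beat-to-beat variability this reduces to [volumetric_error()].
#'
#' @param curve A [make_volume_curve()] result.
#' @param detected_lin_pct Detected phase, % of the beat (linear frame).
#' @param truth_curve_pct Curve phase (%) of the true event.
#' @param beats The dataset's true [beat_sequence()].
#' @param stretch The simulation's [stretch_model()].
#' @return Error in %.
#' @export
volumetric_error_beats <- function(curve, detected_lin_pct, truth_curve_pct,
                                   beats, stretch = stretch_model()) {
  q_b <- curve_phase_of(detected_lin_pct, beats$rr_ms, stretch)
  v_det <- mean(curve_volume_at(curve, q_b))
  v_tr <- curve_volume_at(curve, truth_curve_pct)
  if (v_tr == 0) stop("volumetric error undefined: zero reference volume")
  100 * abs(v_det - v_tr) / v_tr
}

circular_mean_pct <- function(p) {
  a <- 2 * pi * p / 100
  (Arg(mean(exp(1i * a))) / (2 * pi) * 100) %% 100
}

#' Express a detected phase in the ground-truth beat frame
#'
#' Detected phases live in the self-gating beat frame, whose offset to the
#' true R-wave is unknown. Each detection beat's absolute time of the
#' phase is re-normalized against the reference (e.g. simulated ECG) beats
#' and the per-beat phases are combined by a circular mean.
#'
#' @param t_pct Detected phase (%) in the `from` frame.
#' @param beats_from Beats the detection is based on.
#' @param beats_to Reference beats.
#' @return Phase in % of the reference frame.
#' @export
phase_in_reference_frame <- function(t_pct, beats_from, beats_to) {
  on <- beats_from$r_times_ms
  t_abs <- on[-length(on)] + t_pct / 100 * beats_from$rr_ms
  ph <- normalize_phases(t_abs, beats_to)
  circular_mean_pct(ph[!is.na(ph)])
}

# dataset-level bijection between curve phase and linear phase: the mean
# over actual beats of the event's within-beat time as % of the mean RR
# (the same averaging that defines the ground-truth timings); inverted by
# monotone interpolation
curve_phase_of_avg <- function(lin_pct, beats, stretch) {
  qs <- seq(0, 99.75, by = 0.25)
  lin_qs <- vapply(qs, function(q)
    mean(linear_phase_of(q, beats$rr_ms, stretch) * beats$rr_ms) /
      mean(beats$rr_ms), numeric(1))
  stats::approx(c(lin_qs, 100), c(qs, 100), xout = lin_pct %% 100,
                rule = 2, ties = "ordered")$y
}

#' Validate a detection against a simulated dataset's ground truth
#'
#' Converts the detected timepoints (or quiescent-interval centers) into
#' the ground-truth beat frame, then computes the temporal error (ms via
#' the mean RR) and the volumetric error. The detected phase is mapped back
#' to curve phase through the same dataset-level average of the per-beat
#' stretch maps that defines the ground-truth timings, so truth and
#' detection use one consistent bijection; see [volumetric_error_beats()]
#' for the per-beat-averaged alternative estimator.
#'
#' @param fit A [quiescence()] fit.
#' @param dataset The `freerun_dataset` it was fit to.
#' @param estimator `"timepoint"` (detected t) or `"interval_center"`
#'   (center of the detected quiescent interval, as used for reporting
#'   against expert annotations).
#' @return Data frame with one row per phase (ES, MD, ED): detected and
#'   true phase (%, reference frame), `temporal_error_ms`,
#'   `volumetric_error_pct`, `interval_ms`.
#' @export
validate_detection <- function(fit, dataset,
                               estimator = c("timepoint", "interval_center")) {
  estimator <- match.arg(estimator)
  gt <- dataset$ground_truth
  stretch <- dataset$stretch
  mean_rr <- gt$mean_rr_ms
  res <- lapply(names(fit$t_pct), function(k) {
    p <- if (estimator == "timepoint") fit$t_pct[[k]] else {
      iv <- fit$intervals[[k]]
      (iv$start_pct + iv$duration_pct / 2) %% 100
    }
    p_ref <- phase_in_reference_frame(p, fit$beats, dataset$beats_true)
    tr <- gt$t_lin_pct[[k]]
    q_det <- curve_phase_of_avg(p_ref, dataset$beats_true, stretch)
    data.frame(phase = k, detected_pct = p_ref, truth_pct = tr,
               temporal_error_ms = temporal_error(p_ref, tr, mean_rr),
               volumetric_error_pct = volumetric_error(dataset$curve, q_det,
                                                       gt$t_pct[[k]]),
               interval_ms = fit$intervals[[k]]$duration_ms)
  })
  do.call(rbind, res)
}

# --- vessel sharpness -------------------------------------------------------

trilinear_at <- function(vol, pts_vox) {
  d <- dim(vol)
  f0 <- pmin(pmax(floor(pts_vox), 1), matrix(rep(d - 1, each = nrow(pts_vox)),
                                             ncol = 3))
  fr <- pts_vox - f0
  fr[] <- pmin(pmax(fr, 0), 1)
  out <- numeric(nrow(pts_vox))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
         (if (cy) fr[, 2] else 1 - fr[, 2]) *
         (if (cz) fr[, 3] else 1 - fr[, 3])
    out <- out + w * vol[cbind(f0[, 1] + cx, f0[, 2] + cy, f0[, 3] + cz)]
  }
  out
}

mm_to_vox <- function(pts_mm, n, fov_mm) pts_mm / (fov_mm / n) + n / 2 + 1

#' Coronary vessel sharpness along a known centerline
#'
#' At each centerline point, intensity profiles are sampled along two
#' directions perpendicular to the local tangent; on each side of the
#' vessel center the edge is localized at the maximum-magnitude spatial
#' derivative, and the point sharpness is the mean absolute edge
#' derivative (per mm, scaled by the vessel radius) relative to the center
#' intensity, in percent. Aggregates are reported over the first 4 cm of
#' tracked length and over the full length.
#'
#' @param volume 3D magnitude image.
#' @param centerline_mm Ordered centerline points (n x 3, mm, FOV-centered
#'   coordinates).
#' @param fov_mm Field of view (mm).
#' @param radius_mm Nominal vessel radius (normalization scale; also sets
#'   the probe length `6 * radius_mm` per side).
#' @param step_voxel Profile sampling step in voxels (default 0.25).
#' @return Object of class `sharpness_result`: `per_point` (%, `NA` for
#'   skipped points), `vs_4cm`, `vs_full`, `length_mm`, `n_skipped`.
#' @export
vessel_sharpness <- function(volume, centerline_mm, fov_mm, radius_mm = 7,
                             step_voxel = 0.25) {
  n <- dim(volume)[1]
  vox <- fov_mm / n
  npt <- nrow(centerline_mm)
  seglen <- sqrt(rowSums((centerline_mm[-1, , drop = FALSE] -
                          centerline_mm[-npt, , drop = FALSE])^2))
  arc <- c(0, cumsum(seglen))
  step_mm <- step_voxel * vox
  L <- 6 * radius_mm
  s_off <- seq(-L, L, by = step_mm)
  vs <- rep(NA_real_, npt)
  for (i in seq_len(npt)) {
    i0 <- max(1, i - 1); i1 <- min(npt, i + 1)
    tg <- centerline_mm[i1, ] - centerline_mm[i0, ]
    tg <- tg / sqrt(sum(tg^2))
    ref <- if (abs(tg[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- c(tg[2] * ref[3] - tg[3] * ref[2], tg[3] * ref[1] - tg[1] * ref[3],
           tg[1] * ref[2] - tg[2] * ref[1])
    u <- u / sqrt(sum(u^2))
    v <- c(tg[2] * u[3] - tg[3] * u[2], tg[3] * u[1] - tg[1] * u[3],
           tg[1] * u[2] - tg[2] * u[1])
    i_c <- trilinear_at(volume, mm_to_vox(matrix(centerline_mm[i, ], 1), n, fov_mm))
    if (i_c <= 1e-9 * max(volume)) next   # zero-intensity point: skipped
    derivs <- numeric(0)
    for (dir in list(u, v)) {
      pts <- sweep(outer(s_off, dir), 2, centerline_mm[i, ], `+`)
      prof <- trilinear_at(volume, mm_to_vox(pts, n, fov_mm))
      dp <- diff(prof) / step_mm
      s_mid <- (s_off[-1] + s_off[-length(s_off)]) / 2
      for (side in list(s_mid < 0, s_mid > 0)) {
        if (any(side)) derivs <- c(derivs, max(abs(dp[side])))
      }
    }
    if (max(derivs) <= 1e-9 * i_c) next   # no edge: skipped
    vs[i] <- 100 * radius_mm * mean(derivs) / i_c
  }
  if (all(is.na(vs))) stop("vessel sharpness undefined: all points skipped")
  structure(list(per_point = vs,
                 vs_4cm = mean(vs[arc <= 40], na.rm = TRUE),
                 vs_full = mean(vs, na.rm = TRUE),
                 length_mm = arc[npt], n_skipped = sum(is.na(vs))),
            class = "sharpness_result")
}

# --- grid experiment --------------------------------------------------------

#' Run the simulation grid end to end
#'
#' For each grid configuration: simulate the dataset, run the automated
#' detection, build the three mid-diastolic reconstructions (automated
#' adaptive, manual fixed, manual adaptive), and compute all validation
#' metrics. The trajectory/NUFFT plan is shared across the grid and phase
#' volumes are cached per curve variant.
#'
#' @param configs Grid rows ([grid_configs()]).
#' @param protocol A [protocol_spec()].
#' @param control A [sync_control()].
#' @param width_ms Manual acceptance-window width (ms); by default
#'   the scout-derived plateau width (see [scout_params()]).
#' @param verbose Print per-dataset progress.
#' @return Data frame, one row per dataset x strategy x phase (detection
#'   metrics on the `auto-adaptive` rows; vessel sharpness on the MD
#'   rows of every strategy). Failed datasets yield a row with the error
#'   message in `error`.
#' @export
grid_experiment <- function(configs = grid_configs("desk"),
                            protocol = protocol_spec(),
                            control = sync_control(), width_ms = NULL,
                            verbose = FALSE) {
  traj <- generate_phyllotaxis(protocol)
  plan <- nufft_plan(traj)
  phantom <- phantom_spec(matrix = protocol$matrix, fov_mm = protocol$fov_mm)
  phase_cache <- list()
  rows <- list()
  for (r in seq_len(nrow(configs))) {
    cf <- configs[r, ]
    key <- as.character(cf$variant_id)
    if (is.null(phase_cache[[key]])) {
      phase_cache[[key]] <- render_phases(phantom,
                                          make_volume_curve(cf$variant_id))
    }
    res <- tryCatch({
      ds <- simulate_freerun(cf$rr_base_ms, cf$hrv_ms, cf$variant_id,
                             cf$seed, protocol, phantom, plan,
                             phase_cache[[key]])
      fit <- quiescence(ds, control)
      val <- validate_detection(fit, ds, "timepoint")
      val_c <- validate_detection(fit, ds, "interval_center")
      params <- scout_params(ds, "ground_truth", width_ms)
      tms <- traj$time_ms
      wins <- list(
        "auto-adaptive" = fit$windows,
        "manual-fixed" = windows_manual_fixed(params, ds$beats_true, tms),
        "manual-adapt" = windows_manual_adapt(params, ds$beats_true, tms))
      md_idx <- which.min(abs(ds$curve$phases_pct -
                              ds$ground_truth$t_pct[["MD"]]))
      cl <- ds$centerlines[[md_idx]]
      out <- list()
      for (s in names(wins)) {
        rec <- reconstruct_selection(ds$kspace, wins[[s]], "MD", plan)
        vs <- vessel_sharpness(rec, cl, protocol$fov_mm,
                               phantom$vessel_radius_mm)
        if (s == "auto-adaptive") {
          df <- val
          df$temporal_error_center_ms <- val_c$temporal_error_ms
          df$strategy <- s
        } else {
          df <- data.frame(phase = "MD", detected_pct = NA, truth_pct = NA,
                           temporal_error_ms = NA,
                           volumetric_error_pct = NA, interval_ms = NA,
                           temporal_error_center_ms = NA, strategy = s)
        }
        df$vs_4cm <- ifelse(df$phase == "MD", vs$vs_4cm, NA)
        df$vs_full <- ifelse(df$phase == "MD", vs$vs_full, NA)
        sel <- wins[[s]]$targets$MD$mask
        df$selected_fraction <- ifelse(df$phase == "MD", mean(sel), NA)
        out[[s]] <- df
      }
      df <- do.call(rbind, out)
      df$error <- NA_character_
      df
    }, error = function(e) {
      data.frame(phase = NA, detected_pct = NA, truth_pct = NA,
                 temporal_error_ms = NA, volumetric_error_pct = NA,
                 interval_ms = NA, temporal_error_center_ms = NA,
                 strategy = "error", vs_4cm = NA, vs_full = NA,
                 selected_fraction = NA, error = conditionMessage(e))
    })
    res$rr_base_ms <- cf$rr_base_ms; res$hrv_ms <- cf$hrv_ms
    res$variant_id <- cf$variant_id; res$seed <- cf$seed
    rows[[r]] <- res
    if (verbose) {
      message(sprintf("[%d/%d] RR %g HRV %g variant %d: %s", r, nrow(configs),
                      cf$rr_base_ms, cf$hrv_ms, cf$variant_id,
                      if (all(is.na(res$error))) "ok" else res$error[1]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize grid results per condition
#'
#' Mean and SD of the absolute temporal error, volumetric error and vessel
#' sharpness per (RR, HRV, strategy, phase) cell, averaged over the volume
#' curve variants.
#'
#' @param results A [grid_experiment()] result.
#' @return Aggregated data frame.
#' @export
summarize_grid <- function(results) {
  ok <- results[results$strategy != "error" & !is.na(results$phase), ]
  agg <- stats::aggregate(
    cbind(abs_temporal_error_ms = abs(ok$temporal_error_ms),
          volumetric_error_pct = ok$volumetric_error_pct,
          vs_full = ok$vs_full),
    by = list(rr_base_ms = ok$rr_base_ms, hrv_ms = ok$hrv_ms,
              strategy = ok$strategy, phase = ok$phase),
    FUN = function(x) mean(x, na.rm = TRUE))
  agg[order(agg$strategy, agg$phase, agg$rr_base_ms, agg$hrv_ms), ]
}

#' Paired significance tests between reconstruction strategies
#'
#' Thin reporting utility: paired tests on a per-dataset metric between all
#' strategy pairs, with Bonferroni correction.
#'
#' @param results A [grid_experiment()] result.
#' @param metric Column to compare (default `"vs_full"`).
#' @param test `"t"` (paired t-test) or `"wilcoxon"` (signed-rank).
#' @return Data frame of pairwise comparisons with adjusted p-values.
#' @export
compare_strategies <- function(results, metric = "vs_full",
                               test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  md <- results[results$phase %in% "MD" & results$strategy != "error", ]
  key <- interaction(md$rr_base_ms, md$hrv_ms, md$variant_id, md$seed)
  w <- stats::reshape(
    data.frame(key = key, strategy = md$strategy, value = md[[metric]]),
    idvar = "key", timevar = "strategy", direction = "wide")
  strategies <- sub("^value\\.", "", names(w)[-1])
  pairs <- utils::combn(strategies, 2, simplify = FALSE)
  res <- lapply(pairs, function(p) {
    x <- w[[paste0("value.", p[1])]]; y <- w[[paste0("value.", p[2])]]
    ok <- stats::complete.cases(x, y)
    ht <- if (test == "t") stats::t.test(x[ok], y[ok], paired = TRUE)
          else stats::wilcox.test(x[ok], y[ok], paired = TRUE, exact = FALSE)
    data.frame(a = p[1], b = p[2], mean_a = mean(x[ok]), mean_b = mean(y[ok]),
               p_value = ht$p.value)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "bonferroni")
  res
}
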