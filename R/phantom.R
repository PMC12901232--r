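#' Heart model: baseline rate and beat-to-beat variability
#'
#' @param rr_base_ms Mean R-to-R interval in ms.
#' @param hrv_ms Heart-rate variability: standard deviation of the RR
#'   durations, in ms.
#' @return An object of class `heart_model`.
#' @export
heart_model <- function(rr_base_ms = 800, hrv_ms = 0) {
  if (rr_base_ms <= 0) stop("rr_base_ms must be positive")
  if (hrv_ms < 0) stop("hrv_ms must be non-negative")
  if (hrv_ms >= rr_base_ms) stop("degenerate model: hrv_ms >= rr_base_ms")
  structure(list(rr_base_ms = rr_base_ms, hrv_ms = hrv_ms),
            class = "heart_model")
}

#' Construct a beat sequence from onset times
#' @param r_times_ms Strictly increasing beat onset times (ms); the last
#'   entry closes the final beat.
#' @return Object of class `beat_sequence` with `r_times_ms` and per-beat
#'   durations `rr_ms` (length one less than the onsets).
#' @export
beat_sequence <- function(r_times_ms) {
  rr <- diff(r_times_ms)
  if (length(rr) < 1 || any(rr <= 0)) stop("onsets must be strictly increasing")
  structure(list(r_times_ms = r_times_ms, rr_ms = rr), class = "beat_sequence")
}

#' Sample a heartbeat sequence with Gaussian RR jitter
#'
#' RR durations are drawn i.i.d. from a normal distribution with mean
#' `rr_base_ms` and SD `hrv_ms`, truncated to
#' `[max(300, rr_base - 3 hrv), rr_base + 3 hrv]` to exclude
#' non-physiological beats; beats are appended until the sequence covers
#' `duration_ms`. Reproducible given `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param model A [heart_model()].
#' @param duration_ms Time span to cover (ms).
#' @param seed Integer seed.
#' @return A [beat_sequence()] starting at t = 0.
#' @export
sample_beats <- function(model, duration_ms, seed = 1L) {
  stopifnot(inherits(model, "heart_model"), duration_ms > model$rr_base_ms)
  lo <- max(300, model$rr_base_ms - 3 * model$hrv_ms)
  hi <- model$rr_base_ms + 3 * model$hrv_ms
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  rr <- numeric(0)
  n_guess <- ceiling(duration_ms / model$rr_base_ms) + 8
  while (sum(rr) < duration_ms) {
    draw <- stats::rnorm(n_guess, model$rr_base_ms, model$hrv_ms)
    draw <- draw[draw >= lo & draw <= hi]   # truncation by rejection
    rr <- c(rr, draw)
  }
  rr <- rr[seq_len(which(cumsum(rr) >= duration_ms)[1])]
  beat_sequence(c(0, cumsum(rr)))
}

# --- left-ventricular volume curve ------------------------------------------

#' Parametric left-ventricular volume curve
#'
#' Deterministic cardiac-cycle LV volume curve sampled at the 50 simulated
#' phases (0 to 98% in steps of 2%): end-diastolic peak at phase 0, systolic
#' descent to the end-systolic trough near 36%, rapid early filling, a
#' mid-diastolic plateau, and an atrial kick back to the end-diastolic
#' volume. Ten variants (`variant_id` 0-9) perturb the plateau level, slope
#' and extent; variant 0 has the flattest plateau. The curve is built as a
#' periodic cubic spline through fixed control points.
#'
#' @param variant_id Integer 0-9.
#' @return Object of class `volume_curve`: `variant_id`, `phases_pct` (50
#'   values), `v_of_phase` (mL), `v_fun(p)` continuous periodic evaluator,
#'   `dv_fun(p)` its derivative (mL per % phase), and `t_es_pct` (phase of
#'   the sampled minimum).
#' @export
make_volume_curve <- function(variant_id = 0L) {
  if (length(variant_id) != 1 || variant_id < 0 || variant_id > 9 ||
      variant_id != round(variant_id)) {
    stop("variant_id must be an integer in 0..9")
  }
  v <- as.integer(variant_id)
  level <- 103 + 0.5 * v          # plateau level, mL
  slope <- 0.025 * v              # plateau slope, mL per % phase
  p_end <- 84 - 2 * (v %% 3)      # plateau extent varies with variant
  plateau_p <- c(52, 60, 70, 78, p_end)
  plateau_v <- level + slope * (plateau_p - 70)
  p <- c(0, 4, 12, 22, 30, 36, 40, 46, plateau_p, p_end + 6, 96, 100)
  val <- c(120, 118.5, 104, 78, 57, 50, 56, 82, plateau_v,
           max(utils::tail(plateau_v, 1) + 5, 117), 118.5, 120)
  fn <- stats::splinefun(p, val, method = "periodic")
  phases <- seq(0, 98, by = 2)
  vp <- fn(phases)
  structure(list(variant_id = v, phases_pct = phases, v_of_phase = vp,
                 v_fun = function(q) fn(q %% 100),
                 dv_fun = function(q) fn(q %% 100, deriv = 1),
                 t_es_pct = phases[which.min(vp)]),
            class = "volume_curve")
}

# --- systolic-interval (phase stretch) model --------------------------------

#' Systolic-interval model
#'
#' Linear ejection-time regression `ET(ms) = a - b * HR(bpm)`, used both to
#' stretch simulated cardiac phases non-linearly with the instantaneous
#' heart rate and as the parametric physiological filter on synchronicity
#' regions. The systolic fraction of a beat is clamped to `[0.15, 0.6]`.
#'
#' @param a,b Regression coefficients (ms, ms/bpm).
#' @param t_es_pct Cardiac phase (%) of end-systole on the volume curve; the
#'   systolic sub-interval of each beat maps linearly onto `[0, t_es_pct]`.
#' @param enabled If `FALSE`, phases map linearly over the whole beat.
#' @return Object of class `stretch_model`.
#' @export
stretch_model <- function(a = 546, b = 2.1, t_es_pct = 36, enabled = TRUE) {
  structure(list(a = a, b = b, t_es_pct = t_es_pct, enabled = enabled),
            class = "stretch_model")
}

#' Expected systolic interval at a given heart rate
#' @param model A [stretch_model()].
#' @param hr_bpm Heart rate in beats per minute.
#' @return Ejection time in ms.
#' @export
systolic_interval_ms <- function(model, hr_bpm) model$a - model$b * hr_bpm

systolic_fraction <- function(model, rr_ms) {
  et <- systolic_interval_ms(model, 60000 / rr_ms)
  pmin(pmax(et / rr_ms, 0.15), 0.6)
}

#' Cardiac phase at arbitrary acquisition times
#'
#' Locates the beat containing each time, then maps the within-beat offset
#' to cardiac phase. With stretching enabled the systolic sub-interval
#' (duration from the systolic-interval model at that beat's rate) maps
#' linearly to `[0, t_es_pct]` and the remainder (diastole) to
#' `[t_es_pct, 100)`, so the phase is non-linear in overall beat fraction;
#' with stretching disabled the map is `100 (t - onset) / RR`.
#'
#' @param t_ms Times (ms) within the beat span.
#' @param beats A [beat_sequence()].
#' @param stretch A [stretch_model()].
#' @return Cardiac phases in `[0, 100)`.
#' @export
cardiac_phase_at <- function(t_ms, beats, stretch = stretch_model()) {
  stopifnot(inherits(beats, "beat_sequence"))
  on <- beats$r_times_ms
  if (any(t_ms < on[1] | t_ms >= on[length(on)])) {
    stop("t_ms outside the beat sequence span")
  }
  b <- findInterval(t_ms, on)
  frac <- (t_ms - on[b]) / beats$rr_ms[b]
  if (!stretch$enabled) return(100 * frac)
  fs <- systolic_fraction(stretch, beats$rr_ms[b])
  tes <- stretch$t_es_pct
  ifelse(frac <= fs,
         tes * frac / fs,
         tes + (100 - tes) * (frac - fs) / (1 - fs))
}

#' Beat fraction (linear phase) at which a curve phase occurs
#'
#' Inverse of the stretch map: for a beat of duration `rr_ms`, the fraction
#' of the beat elapsed when cardiac (curve) phase `phase_pct` is reached.
#' @inheritParams cardiac_phase_at
#' @param phase_pct Curve phase in % (vectorized).
#' @param rr_ms Beat duration in ms.
#' @return Linear phase in % of the beat.
#' @export
linear_phase_of <- function(phase_pct, rr_ms, stretch = stretch_model()) {
  n <- max(length(phase_pct), length(rr_ms))
  q <- rep_len(phase_pct %% 100, n)
  if (!stretch$enabled) return(q)
  fs <- rep_len(systolic_fraction(stretch, rr_ms), n)
  tes <- stretch$t_es_pct
  100 * ifelse(q <= tes, q / tes * fs, fs + (q - tes) / (100 - tes) * (1 - fs))
}

# --- phantom geometry and bSSFP contrast ------------------------------------

#' Balanced SSFP steady-state signal
#'
#' On-resonance analytical steady state,
#' `S = PD sin(a) / ((T1/T2 + 1) - cos(a) (T1/T2 - 1))`; banding and
#' off-resonance effects are not modeled.
#'
#' @param t1_ms,t2_ms Relaxation times (ms), `t1_ms >= t2_ms > 0`.
#' @param pd Proton density (arbitrary units).
#' @param flip_deg Flip angle in degrees.
#' @return Signal in arbitrary units.
#' @export
bssfp_signal <- function(t1_ms, t2_ms, pd = 1, flip_deg = 60) {
  stopifnot(all(t2_ms > 0), all(t1_ms >= t2_ms))
  a <- flip_deg * pi / 180
  r <- t1_ms / t2_ms
  pd * sin(a) / ((r + 1) - cos(a) * (r - 1))
}

#' Beating torso phantom specification
#'
#' Analytic stand-in for a dynamic cardiac torso phantom: a soft-tissue
#' torso ellipsoid, an ellipsoidal LV blood pool inside an incompressible
#' myocardial shell (wall volume conserved as the cavity beats), a pulsating
#' outflow-tract/aorta tube whose caliber varies out of phase with the LV,
#' and a coronary-vessel-analog tube riding on the atrioventricular-groove
#' motion (its centerline scales radially about the heart center with the
#' cavity radius). World coordinates in mm, FOV centered at the origin,
#' z = superior-inferior axis; the vessel radius is exaggerated relative to
#' a real coronary so that it spans >= 2 voxels at desk-scale resolution.
#'
#' @param matrix Grid size per axis (voxels).
#' @param fov_mm Field of view (mm).
#' @param flip_deg Flip angle (degrees).
#' @param edv_ml Nominal end-diastolic cavity volume of the base geometry (mL).
#' @param wall_ml Myocardial wall volume (mL), conserved across phases.
#' @param vessel_radius_mm Coronary-analog tube radius (mm).
#' @param tissues Data frame with columns `tissue`, `t1_ms`, `t2_ms`, `pd`
#'   for `torso`, `myocardium`, `blood`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix = 48, fov_mm = 220, flip_deg = 60,
                         edv_ml = 125, wall_ml = 150, vessel_radius_mm = 7,
                         tissues = NULL) {
  if (is.null(tissues)) {
    tissues <- data.frame(
      tissue = c("torso", "myocardium", "blood"),
      t1_ms = c(900, 870, 1660), t2_ms = c(50, 45, 240),
      pd = c(0.8, 0.9, 0.95))
  }
  stopifnot(vessel_radius_mm > 0, edv_ml > 0, wall_ml > 0,
            all(tissues$t1_ms >= tissues$t2_ms), all(tissues$t2_ms > 0))
  geom <- list(
    torso_semi = c(95, 78, 102), torso_center = c(0, 0, 0),
    heart_center = c(-20, 10, 0),
    cav_semi = c(28, 28, 38),        # base cavity ellipsoid (~125 mL)
    outer_semi = c(38, 38, 48),      # base epicardial ellipsoid
    aorta_center_xy = c(-10, 5), aorta_radius = 11,
    aorta_z = c(25, 85), aorta_pulse = 0.12, aorta_shift_pct = 38,
    vessel_arc_radius = 47, vessel_arc_deg = c(20, 120),
    vessel_n_points = 40, vessel_z_amp = 12)
  structure(list(matrix = as.integer(matrix), fov_mm = fov_mm,
                 flip_deg = flip_deg, edv_ml = edv_ml, wall_ml = wall_ml,
                 vessel_radius_mm = vessel_radius_mm, tissues = tissues,
                 geom = geom),
            class = "phantom_spec")
}

phantom_coords <- function(spec) {
  n <- spec$matrix
  ax <- (seq_len(n) - 1 - n / 2) * (spec$fov_mm / n)  # mm, FOV centered
  list(x = ax[slice.index(array(0, c(n, n, n)), 1)],
       y = ax[slice.index(array(0, c(n, n, n)), 2)],
       z = ax[slice.index(array(0, c(n, n, n)), 3)], ax = ax, n = n)
}

vessel_centerline_base <- function(spec) {
  g <- spec$geom
  psi <- seq(g$vessel_arc_deg[1], g$vessel_arc_deg[2],
             length.out = g$vessel_n_points) * pi / 180
  cbind(g$heart_center[1] + g$vessel_arc_radius * cos(psi),
        g$heart_center[2] + g$vessel_arc_radius * sin(psi),
        g$heart_center[3] + g$vessel_z_amp * sin(psi - psi[1]))
}

# distance from voxels (coordinate vectors) to a polyline, vectorized per segment
polyline_distance <- function(px, py, pz, line) {
  d2 <- rep(Inf, length(px))
  for (k in seq_len(nrow(line) - 1)) {
    a <- line[k, ]; ab <- line[k + 1, ] - a
    len2 <- sum(ab^2)
    t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- pmin(d2, (px - a[1] - t * ab[1])^2 + (py - a[2] - t * ab[2])^2 +
                   (pz - a[3] - t * ab[3])^2)
  }
  sqrt(d2)
}

#' Render the 50 cardiac-phase signal volumes of the beating phantom
#'
#' For each of the 50 phases the LV cavity and epicardial ellipsoids are
#' rescaled so that the voxelized cavity volume matches the volume curve
#' (the radius scale is found by exact inversion on the sorted ellipsoid
#' quadratic-form field: the scale whose iso-surface encloses the target
#' voxel count), the wall volume is conserved, the vessel-analog centerline
#' moves with the cavity radius scale, and tissue labels are converted to
#' signal with the bSSFP steady-state equation.
#'
#' @param spec A [phantom_spec()].
#' @param curve A [make_volume_curve()] result.
#' @return Object of class `phase_volume_set`: `volumes` (list of 50 3D
#'   arrays), `lv_volume_ml` (voxelized cavity volume per phase),
#'   `lv_masks` (list of logical arrays), `centerlines` (list of 50
#'   centerline point matrices, mm), `phases_pct`, and the `spec`/`curve`.
#' @export
render_phases <- function(spec, curve) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(curve, "volume_curve"))
  co <- phantom_coords(spec)
  g <- spec$geom
  voxvol_ml <- (spec$fov_mm / spec$matrix)^3 / 1000
  sig <- stats::setNames(
    bssfp_signal(spec$tissues$t1_ms, spec$tissues$t2_ms, spec$tissues$pd,
                 spec$flip_deg),
    spec$tissues$tissue)

  hx <- co$x - g$heart_center[1]; hy <- co$y - g$heart_center[2]
  hz <- co$z - g$heart_center[3]
  e_cav <- (hx / g$cav_semi[1])^2 + (hy / g$cav_semi[2])^2 + (hz / g$cav_semi[3])^2
  e_out <- (hx / g$outer_semi[1])^2 + (hy / g$outer_semi[2])^2 + (hz / g$outer_semi[3])^2
  e_torso <- ((co$x - g$torso_center[1]) / g$torso_semi[1])^2 +
             ((co$y - g$torso_center[2]) / g$torso_semi[2])^2 +
             ((co$z - g$torso_center[3]) / g$torso_semi[3])^2
  s_cav <- sort(e_cav); s_out <- sort(e_out)
  v0_cav <- 4 / 3 * pi * prod(g$cav_semi) / 1000

  scale_for <- function(sorted_e, target_ml) {
    m <- max(1L, min(length(sorted_e), round(target_ml / voxvol_ml)))
    sqrt(sorted_e[m])
  }

  aorta_d2 <- (co$x - g$aorta_center_xy[1])^2 + (co$y - g$aorta_center_xy[2])^2
  in_aorta_z <- co$z >= g$aorta_z[1] & co$z <= g$aorta_z[2]
  base_line <- vessel_centerline_base(spec)
  # normalized pulsation curve for the aorta, phase-shifted from the LV
  vn <- (curve$v_fun(0:99) - min(curve$v_of_phase)) /
        (max(curve$v_of_phase) - min(curve$v_of_phase))

  n_ph <- length(curve$phases_pct)
  volumes <- vector("list", n_ph); lv_masks <- vector("list", n_ph)
  centerlines <- vector("list", n_ph); lv_vol <- numeric(n_ph)
  s_ref <- (curve$v_of_phase[1] / v0_cav)^(1 / 3)
  vr <- spec$vessel_radius_mm
  torso_mask <- e_torso <= 1

  for (i in seq_len(n_ph)) {
    target <- curve$v_of_phase[i]
    if (target > spec$edv_ml * 2 || target <= 0) {
      stop("requested cavity volume unachievable within geometry bounds")
    }
    sc <- scale_for(s_cav, target)
    so <- scale_for(s_out, target + spec$wall_ml)
    cav <- e_cav <= sc^2
    myo <- e_out <= so^2 & !cav
    vol <- array(0, dim = c(co$n, co$n, co$n))
    vol[torso_mask] <- sig["torso"]
    vol[myo] <- sig["myocardium"]
    vol[cav] <- sig["blood"]
    # pulsating outflow tube (blood), caliber out of phase with the LV
    ph_shift <- (curve$phases_pct[i] + g$aorta_shift_pct) %% 100
    r_a <- g$aorta_radius * (1 + g$aorta_pulse * (vn[floor(ph_shift) + 1] - 0.5))
    vol[in_aorta_z & aorta_d2 <= r_a^2 & !cav] <- sig["blood"]
    # coronary-analog tube riding on the AV-groove motion
    s_now <- (target / v0_cav)^(1 / 3)
    line <- sweep(sweep(base_line, 2, g$heart_center) * (s_now / s_ref),
                  2, g$heart_center, `+`)
    bb <- apply(line, 2, range) + c(-1, 1) * (vr + 2)
    near <- co$x >= bb[1, 1] & co$x <= bb[2, 1] &
            co$y >= bb[1, 2] & co$y <= bb[2, 2] &
            co$z >= bb[1, 3] & co$z <= bb[2, 3]
    dist <- polyline_distance(co$x[near], co$y[near], co$z[near], line)
    idx <- which(near)[dist <= vr]
    vol[idx] <- sig["blood"]
    volumes[[i]] <- vol
    lv_masks[[i]] <- cav
    centerlines[[i]] <- line
    lv_vol[i] <- sum(cav) * voxvol_ml
  }
  structure(list(volumes = volumes, lv_volume_ml = lv_vol, lv_masks = lv_masks,
                 centerlines = centerlines, phases_pct = curve$phases_pct,
                 spec = spec, curve = curve),
            class = "phase_volume_set")
}

#' Ground-truth quiescent phases of a simulated dataset
#'
#' End-diastole is the phase of the curve maximum, end-systole the phase of
#' the minimum, and mid-diastole the center of the diastolic plateau (the
#' maximal contiguous span after end-systole where `|dV/dphase|` is below
#' 0.9% of the curve's dynamic range per % phase). Each event's known
#' per-beat timing (via the inverse stretch map at that beat's RR) is
#' averaged over the actual beats and mapped to the average RR — the same
#' per-beat averaging used when detections are converted between beat
#' frames, so truth and detection are treated symmetrically.
#'
#' @param curve A [make_volume_curve()] result.
#' @param beats A [beat_sequence()].
#' @param stretch The [stretch_model()] used in the simulation.
#' @return Object of class `ground_truth`: `t_pct` (curve phase %),
#'   `t_lin_pct` (linear beat fraction %), `t_ms` (ms of the mean RR), each
#'   a named vector (ES, MD, ED); plus `mean_rr_ms` and the `curve`.
#' @export
ground_truth <- function(curve, beats, stretch = stretch_model(t_es_pct = curve$t_es_pct)) {
  stopifnot(inherits(curve, "volume_curve"), inherits(beats, "beat_sequence"))
  p <- curve$phases_pct
  t_ed <- p[which.max(curve$v_of_phase)]
  t_es <- p[which.min(curve$v_of_phase)]
  rng <- diff(range(curve$v_of_phase))
  thr <- 0.009 * rng
  after <- ((p - t_es) %% 100) > 0
  flat <- abs(curve$dv_fun(p)) < thr & after
  if (!any(flat)) stop("degenerate curve: no diastolic plateau found")
  # longest contiguous run of flat phases in circular order after t_es
  ord <- order((p - t_es) %% 100)
  f <- flat[ord]
  runs <- rle(f)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  k <- which(runs$values)[which.max(runs$lengths[runs$values])]
  span <- ord[starts[k]:ends[k]]
  t_md <- p[span[ceiling(length(span) / 2)]]
  t_pct <- c(ES = t_es, MD = t_md, ED = t_ed)
  mean_rr <- mean(beats$rr_ms)
  # mean over beats of the event's absolute within-beat time, as % of the
  # mean RR
  t_lin <- vapply(t_pct, function(q) {
    mean(linear_phase_of(q, beats$rr_ms, stretch) * beats$rr_ms) / mean_rr
  }, numeric(1))
  structure(list(t_pct = t_pct, t_lin_pct = t_lin,
                 t_ms = t_lin * mean_rr / 100,
                 plateau_pct = range(p[span]), mean_rr_ms = mean_rr,
                 curve = curve, stretch = stretch),
            class = "ground_truth")
}
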