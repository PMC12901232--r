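# Cardiac self-gating: SI projections, PCA + spectral component selection,
# zero-crossing beat detection, and per-line phase normalization.

centered_ifft1 <- function(s) {
  n <- length(s)
  sh <- c((ceiling(n / 2) + 1):n, 1:ceiling(n / 2))   # ifftshift
  un <- c((floor(n / 2) + 1):n, 1:floor(n / 2))       # fftshift
  (stats::fft(s[sh], inverse = TRUE) / n)[un]
}

#' Superior-inferior projection profiles from the self-gating readouts
#'
#' Each shot's SI readout (its first segment, oriented along +z) is
#' inverse-Fourier-transformed along the readout into a 1D projection of
#' the object onto the SI axis; magnitudes are collected into a
#' shots-by-position matrix in shot (time) order.
#'
#' @param kspace A `kspace_set`.
#' @param traj The matching `radial_trajectory` (defaults to the one in
#'   `kspace`).
#' @return List: `profiles` (n_shots x n_read magnitude matrix),
#'   `time_ms` (per-shot SI timestamp), `cadence_ms`.
#' @export
si_profiles <- function(kspace, traj = kspace$traj) {
  si <- which(traj$is_si)
  if (length(si) == 0) stop("trajectory contains no SI self-gating lines")
  prof <- t(apply(kspace$samples[, si, drop = FALSE], 2,
                  function(s) Mod(centered_ifft1(s))))
  list(profiles = prof, time_ms = traj$time_ms[si],
       cadence_ms = traj$spec$n_segments * traj$spec$tr_ms)
}

band_power_fraction <- function(x, fs, band) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) / n * fs
  pos <- f > 0 & f <= fs / 2
  inb <- pos & f >= band[1] & f <= band[2]
  if (!any(pos) || sum(p[pos]) == 0) return(0)
  sum(p[inb]) / sum(p[pos])
}

# canonical polarity: sign from the skewness numerator, falling back to the
# first non-zero sample, so a signal and its negation map to the same output
canonical_polarity <- function(x) {
  s3 <- sum(x^3)
  if (abs(s3) > 1e-12 * max(abs(x))^3 * length(x)) return(sign(s3))
  nz <- which(x != 0)
  if (length(nz) == 0) return(1)
  sign(x[nz[1]])
}

#' Extract the cardiac self-gating signal
#'
#' Principal component analysis across the SI-position dimension of the
#' projection profiles; each component's time course is scored by its
#' spectral power inside the cardiac frequency band and the strongest
#' cardiac component is retained, band-pass filtered (zero-phase, 2nd-order
#' Butterworth applied forward and backward) and polarity-normalized. A
#' respiratory component is identified analogously (unused downstream in
#' simulations, which contain no respiratory motion).
#'
#' @param profiles Result of [si_profiles()] (or a plain matrix).
#' @param cadence_ms Sampling cadence in ms (one SI readout per shot).
#' @param cardiac_band_hz,resp_band_hz Frequency bands in Hz.
#' @param time_ms Optional per-sample times (taken from `profiles` if built
#'   by [si_profiles()]).
#' @return Object of class `sg_signal`: `time_ms`, `signal` (filtered,
#'   polarity-normalized), `raw` (unfiltered component score),
#'   `cadence_ms`, `component`, `resp_component`, `dominant_freq_hz`,
#'   `cardiac_band_fraction`.
#' @export
extract_cardiac_sg <- function(profiles, cadence_ms = NULL,
                               cardiac_band_hz = c(0.7, 3.0),
                               resp_band_hz = c(0.1, 0.5), time_ms = NULL) {
  if (is.list(profiles)) {
    if (is.null(cadence_ms)) cadence_ms <- profiles$cadence_ms
    if (is.null(time_ms)) time_ms <- profiles$time_ms
    profiles <- profiles$profiles
  }
  n <- nrow(profiles)
  if (n < 64) stop("need at least 64 shots for self-gating extraction")
  if (is.null(time_ms)) time_ms <- (seq_len(n) - 1) * cadence_ms
  fs <- 1000 / cadence_ms
  if (fs / 2 < cardiac_band_hz[2]) {
    warning("self-gating cadence too coarse: Nyquist below the cardiac band")
  }
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  k <- min(10L, ncol(pc$x))
  frac <- apply(pc$x[, seq_len(k), drop = FALSE], 2,
                band_power_fraction, fs = fs, band = cardiac_band_hz)
  pow <- pc$sdev[seq_len(k)]^2 * frac          # absolute in-band power
  comp <- which.max(pow)
  if (frac[comp] < 0.2) {
    stop("cardiac self-gating selection failed: no component with ",
         "dominant power in the cardiac band")
  }
  rfrac <- apply(pc$x[, seq_len(k), drop = FALSE], 2,
                 band_power_fraction, fs = fs, band = resp_band_hz)
  rcomp <- which.max(pc$sdev[seq_len(k)]^2 * rfrac)
  raw <- pc$x[, comp]
  w <- pmin(pmax(c(cardiac_band_hz[1], min(cardiac_band_hz[2], 0.98 * fs / 2)) /
                 (fs / 2), 1e-3), 0.999)
  bf <- signal::butter(2, w, type = "pass")
  sig <- signal::filtfilt(bf, raw - mean(raw))
  sig <- sig * canonical_polarity(sig)
  pr <- Mod(stats::fft(sig))^2
  fr <- (seq_len(n) - 1) / n * fs
  pos <- fr > 0 & fr <= fs / 2
  structure(list(time_ms = time_ms, signal = sig, raw = raw,
                 cadence_ms = cadence_ms, component = comp,
                 resp_component = rcomp,
                 dominant_freq_hz = fr[pos][which.max(pr[pos])],
                 cardiac_band_fraction = frac[comp]),
            class = "sg_signal")
}

#' Detect heartbeats from the cardiac self-gating signal
#'
#' Beat onsets are placed at rising zero crossings of the mean-centered
#' signal, with sub-sample linear interpolation of the crossing time;
#' crossings closer than `min_rr_ms` are merged (the first is kept). Only
#' beat-to-beat intervals are meaningful: the offset between these onsets
#' and the true R-wave is an internal reference frame.
#'
#' @param sg An `sg_signal` (or a list with `signal` and `time_ms`).
#' @param min_rr_ms Minimum physiological beat duration (ms).
#' @return A [beat_sequence()].
#' @export
detect_beats <- function(sg, min_rr_ms = 300) {
  s <- sg$signal - mean(sg$signal)
  s <- s * canonical_polarity(s)
  t <- sg$time_ms
  i <- which(s[-length(s)] < 0 & s[-1] >= 0)
  if (length(i) < 3) stop("beat detection failure: fewer than 3 zero crossings")
  tc <- t[i] + (t[i + 1] - t[i]) * (-s[i]) / (s[i + 1] - s[i])
  keep <- tc[1]
  for (x in tc[-1]) if (x - keep[length(keep)] >= min_rr_ms) keep <- c(keep, x)
  if (length(keep) < 3) stop("beat detection failure: fewer than 3 zero crossings")
  beat_sequence(keep)
}

#' Normalize acquisition timestamps to cardiac phase
#'
#' Phase of a line at time `t` inside beat `i` is
#' `100 (t - onset_i) / RR_i`, in `[0, 100)`. Lines outside the beat span
#' get `NA` (flagged and excluded downstream).
#'
#' @param time_ms Per-line timestamps (ms).
#' @param beats A [beat_sequence()].
#' @return Per-line phase in %, `NA` outside the span.
#' @export
normalize_phases <- function(time_ms, beats) {
  stopifnot(inherits(beats, "beat_sequence"))
  on <- beats$r_times_ms
  ph <- rep(NA_real_, length(time_ms))
  inside <- time_ms >= on[1] & time_ms < on[length(on)]
  b <- findInterval(time_ms[inside], on)
  ph[inside] <- 100 * (time_ms[inside] - on[b]) / beats$rr_ms[b]
  ph
}
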