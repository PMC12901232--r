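#' Acquisition protocol specification
#'
#' Bundles the geometric and timing parameters of a free-running 3D radial
#' acquisition. Defaults are a desk-scale protocol (reduced matrix and shot
#' count) suitable for simulation studies on a single workstation; the
#' full-scale protocol used for whole-heart imaging (220 mm field of view,
#' 1.15 mm resolution, TR 5.38 ms, 22 segments, 5749 shots) is obtained by
#' passing the corresponding values.
#'
#' @param fov_mm Isotropic field of view in mm.
#' @param matrix Reconstruction matrix size per axis (voxels).
#' @param tr_ms Repetition time in ms (one readout line per TR).
#' @param n_segments Readout lines per interleave (shot).
#' @param n_shots Number of interleaves.
#' @return An object of class `protocol_spec`.
#' @examples
#' protocol_spec()                      # desk scale
#' protocol_spec(matrix = 192, n_shots = 5749)  # full scale
#' @export
protocol_spec <- function(fov_mm = 220, matrix = 48, tr_ms = 5.38,
                          n_segments = 22, n_shots = 600) {
  if (fov_mm <= 0) stop("fov_mm must be positive")
  if (matrix < 8) stop("matrix must be at least 8")
  if (tr_ms <= 0) stop("tr_ms must be positive")
  if (n_segments < 1 || n_shots < 1) stop("n_segments and n_shots must be >= 1")
  structure(list(fov_mm = fov_mm, matrix = as.integer(matrix), tr_ms = tr_ms,
                 n_segments = as.integer(n_segments),
                 n_shots = as.integer(n_shots)),
            class = "protocol_spec")
}

#' Spiral phyllotaxis 3D radial trajectory
#'
#' Generates the readout directions of a spiral phyllotaxis sampling pattern
#' over the half sphere, grouped into interleaves (shots) of segments, with
#' the first segment of every shot replaced by a superior-inferior (SI)
#' readout for cardiac self-gating, and per-line acquisition timestamps.
#'
#' The construction indexes all `n_shots * n_segments` endpoints along a
#' single spiral: endpoint `n` (1-based) has polar angle
#' `theta_n = (pi/2) * sqrt(n / N)` (square-root spacing from pole to
#' equator, uniform area density on the half sphere) and azimuth
#' `phi_n = n * pi * (3 - sqrt(5))` (golden-angle increment). Shot `i`
#' collects every `n_shots`-th endpoint (`n = j * n_shots + i`), giving each
#' interleave a smooth sub-spiral. Lines are full diameters through the
#' k-space centre; conjugate symmetry makes half-sphere coverage sufficient.
#' The z axis is the SI axis (right handed, k-space in cycles/FOV).
#'
#' The first segment of each shot is replaced by (not appended to) an SI
#' line along +z, so one self-gating sample is acquired per shot at a
#' cadence of `n_segments * tr_ms`.
#'
#' @param spec A [protocol_spec()].
#' @return An object of class `radial_trajectory`: list with `directions`
#'   (n_lines x 3 unit vectors, acquisition order), `shot_index` and
#'   `segment_index` (0-based integers), `time_ms` (timestamps, line i at
#'   `i * tr_ms`), `is_si` (logical, self-gating lines), and the `spec`.
#' @examples
#' traj <- generate_phyllotaxis(protocol_spec(n_shots = 10, n_segments = 4))
#' nrow(traj$directions)  # 40
#' @export
generate_phyllotaxis <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  n_lines <- spec$n_shots * spec$n_segments
  golden_angle <- pi * (3 - sqrt(5))
  # spiral index of (shot i, segment j), 0-based: n = j * n_shots + i
  shot <- rep(seq_len(spec$n_shots) - 1L, each = spec$n_segments)
  seg <- rep(seq_len(spec$n_segments) - 1L, times = spec$n_shots)
  n <- seg * spec$n_shots + shot + 1
  theta <- (pi / 2) * sqrt(n / n_lines)
  phi <- n * golden_angle
  dirs <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  si <- seg == 0L
  dirs[si, ] <- rep(c(0, 0, 1), each = sum(si))
  traj <- structure(list(directions = dirs, shot_index = shot,
                         segment_index = seg,
                         time_ms = numeric(n_lines), is_si = si, spec = spec),
                    class = "radial_trajectory")
  assign_timestamps(traj, spec$tr_ms)
}

#' Assign uniform-cadence timestamps to a trajectory
#'
#' Free-running acquisitions sample k-space continuously, one line per TR:
#' line `i` (0-based, acquisition order) is stamped `i * tr_ms`.
#'
#' @param traj A `radial_trajectory`.
#' @param tr_ms Repetition time in ms.
#' @return The trajectory with `time_ms` filled in.
#' @export
assign_timestamps <- function(traj, tr_ms) {
  stopifnot(inherits(traj, "radial_trajectory"), tr_ms > 0)
  traj$time_ms <- (seq_len(nrow(traj$directions)) - 1) * tr_ms
  traj
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf("Spiral phyllotaxis trajectory: %d lines (%d shots x %d segments)\n",
              nrow(x$directions), x$spec$n_shots, x$spec$n_segments))
  cat(sprintf("  TR %.2f ms, scan time %.1f s, %d SI self-gating lines\n",
              x$spec$tr_ms, utils::tail(x$time_ms, 1) / 1000, sum(x$is_si)))
  invisible(x)
}
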