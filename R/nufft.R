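# Gridding NUFFT on a 2x oversampled Cartesian grid with trilinear
# interpolation, expressed as an explicit sparse interpolation operator so
# that the forward map (Cartesian spectrum -> radial samples) and its
# adjoint (spread) are an exactly adjoint pair. Density compensation and
# kernel-rolloff (deapodization) correction are applied only in the image
# reconstruction, not inside the operator pair.

fftshift3 <- function(x) {
  d <- dim(x)
  s <- lapply(d, function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2)))
  x[s[[1]], s[[2]], s[[3]]]
}

ifftshift3 <- function(x) {
  d <- dim(x)
  s <- lapply(d, function(n) c((ceiling(n / 2) + 1):n, 1:ceiling(n / 2)))
  x[s[[1]], s[[2]], s[[3]]]
}

# centered 3D FFT of an image zero-embedded in the oversampled grid
os_fft <- function(vol, n_os) {
  n <- dim(vol)[1]
  pad <- array(0 + 0i, dim = c(n_os, n_os, n_os))
  off <- (n_os - n) / 2
  pad[off + 1:n, off + 1:n, off + 1:n] <- vol
  fftshift3(stats::fft(ifftshift3(pad)))
}

# centered inverse 3D FFT, cropped back to the reconstruction matrix
os_ifft <- function(kgrid, n) {
  n_os <- dim(kgrid)[1]
  img <- fftshift3(stats::fft(ifftshift3(kgrid), inverse = TRUE)) / n_os^3
  off <- (n_os - n) / 2
  img[off + 1:n, off + 1:n, off + 1:n]
}

#' Plan a gridding NUFFT for a radial trajectory
#'
#' Each readout line is a full diameter through the k-space center with
#' `matrix` samples at unit spacing (cycles/FOV), radial index
#' `t = -matrix/2 ... matrix/2 - 1`. Samples are linked to the oversampled
#' Cartesian k-grid by trilinear interpolation, stored as a sparse operator
#' `A` (and its transpose) so forward and adjoint are exact transposes.
#'
#' @param traj A `radial_trajectory`.
#' @param matrix Reconstruction matrix size (defaults to the trajectory's
#'   protocol matrix).
#' @param os Oversampling factor of the k-space grid (default 2).
#' @return Object of class `nufft_plan`.
#' @export
nufft_plan <- function(traj, matrix = traj$spec$matrix, os = 2) {
  stopifnot(inherits(traj, "radial_trajectory"))
  m <- as.integer(matrix)
  n_os <- as.integer(os * m)
  t_rad <- seq(-m / 2, m / 2 - 1)
  n_lines <- nrow(traj$directions)
  # sample k coordinates: k[sample s of line l] = t_rad[s] * dir[l, ]
  kx <- outer(t_rad, traj$directions[, 1])
  ky <- outer(t_rad, traj$directions[, 2])
  kz <- outer(t_rad, traj$directions[, 3])
  gx <- as.numeric(kx) * os + n_os / 2   # 0-based fine-grid coordinates
  gy <- as.numeric(ky) * os + n_os / 2
  gz <- as.numeric(kz) * os + n_os / 2
  n_samp <- length(gx)
  fx <- floor(gx); fy <- floor(gy); fz <- floor(gz)
  wx <- gx - fx; wy <- gy - fy; wz <- gz - fz
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    px <- fx + cx; py <- fy + cy; pz <- fz + cz
    w <- (if (cx) wx else 1 - wx) * (if (cy) wy else 1 - wy) *
         (if (cz) wz else 1 - wz)
    ok <- which(px >= 0 & px < n_os & py >= 0 & py < n_os &
                pz >= 0 & pz < n_os & w > 0)
    ii <- c(ii, ok)
    jj <- c(jj, px[ok] + n_os * (py[ok] + n_os * pz[ok]) + 1)
    vv <- c(vv, w[ok])
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(n_samp, n_os^3))
  structure(list(A = A, At = Matrix::t(A), matrix = m, os = os, n_os = n_os,
                 n_read = m, n_lines = n_lines, t_rad = t_rad,
                 deapod = deapod_array(m, n_os)),
            class = "nufft_plan")
}

# image-domain rolloff of the trilinear kernel: separable sinc^2
deapod_array <- function(m, n_os) {
  u <- seq(-m / 2, m / 2 - 1) + 0.5 * (m %% 2)
  s <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  a <- 1 / s(u / n_os)^2
  outer(outer(a, a), a)
}

nufft_forward_one <- function(plan, vol) {
  fk <- os_fft(vol, plan$n_os)
  re <- as.numeric(plan$A %*% Re(fk))
  im <- as.numeric(plan$A %*% Im(fk))
  complex(real = re, imaginary = im)
}

# exact adjoint of nufft_forward_one (unnormalized inverse DFT = conjugate
# transpose of the unnormalized forward DFT)
nufft_adjoint_raw <- function(plan, y) {
  re <- as.numeric(plan$At %*% Re(y))
  im <- as.numeric(plan$At %*% Im(y))
  kg <- array(complex(real = re, imaginary = im),
              dim = rep(plan$n_os, 3))
  os_ifft(kg, plan$matrix) * plan$n_os^3
}

#' Radial density-compensation weights
#'
#' Ramp weights proportional to `|k|^2` along each 3D radial line
#' (Jacobian of spherical sampling), with the `k = 0` sample assigned the
#' analytic small-volume weight `dk^2 / 12` (the radius-squared average of
#' the central sphere of one sample spacing), normalized to a maximum of 1.
#'
#' @param plan A [nufft_plan()] (also accepts a `radial_trajectory`, from
#'   which a plan-free per-line profile is derived).
#' @return Per-sample weights, ordered sample-fastest within line.
#' @export
density_weights <- function(plan) {
  t_rad <- if (inherits(plan, "nufft_plan")) plan$t_rad
           else seq(-plan$spec$matrix / 2, plan$spec$matrix / 2 - 1)
  w <- t_rad^2
  w[t_rad == 0] <- 1 / 12
  w <- w / max(w)
  n_lines <- if (inherits(plan, "nufft_plan")) plan$n_lines
             else nrow(plan$directions)
  rep(w, times = n_lines)
}

#' Sample radial k-space lines from the beating phantom
#'
#' For every readout line the cardiac phase at its timestamp is computed
#' (via the beat sequence and stretch model), the nearest of the 50 phase
#' volumes is selected, and the radial line through the k-space center along
#' the line's direction is evaluated by the gridding NUFFT of that volume.
#'
#' @param phases A [render_phases()] result.
#' @param traj A `radial_trajectory` whose timestamps lie in the beat span.
#' @param beats A [beat_sequence()].
#' @param stretch A [stretch_model()].
#' @param plan Optional precomputed [nufft_plan()].
#' @return Object of class `kspace_set`: complex `samples`
#'   (`n_read x n_lines`), `traj`, `sim_phase_pct` (the simulated cardiac
#'   phase per line), `n_read`, `plan`.
#' @export
forward_sample <- function(phases, traj, beats, stretch = stretch_model(),
                           plan = NULL) {
  stopifnot(inherits(phases, "phase_volume_set"))
  if (is.null(plan)) plan <- nufft_plan(traj)
  ph <- cardiac_phase_at(traj$time_ms, beats, stretch)
  n_ph <- length(phases$volumes)
  step <- 100 / n_ph
  idx <- (round(ph / step) %% n_ph) + 1   # nearest phase volume
  m <- plan$n_read
  y <- complex(length.out = m * plan$n_lines)
  for (i in sort(unique(idx))) {
    lines <- which(idx == i)
    rows <- as.numeric(outer(seq_len(m), (lines - 1) * m, `+`))
    yi <- nufft_forward_one(plan, phases$volumes[[i]])
    y[rows] <- yi[rows]
  }
  structure(list(samples = matrix(y, nrow = m), traj = traj,
                 sim_phase_pct = ph, n_read = m, plan = plan),
            class = "kspace_set")
}

#' Gridded (adjoint NUFFT) reconstruction
#'
#' Adjoint NUFFT of density-compensated, per-line-weighted samples, with
#' image-domain deapodization; returns the magnitude volume at the
#' reconstruction matrix.
#'
#' @param kspace A [forward_sample()] result (or compatible `kspace_set`).
#' @param line_weights Per-line weights in `[0, 1]` (default all 1).
#' @param plan A [nufft_plan()]; defaults to the one stored in `kspace`.
#' @return 3D magnitude array.
#' @export
gridded_recon <- function(kspace, line_weights = NULL, plan = kspace$plan) {
  m <- kspace$n_read
  n_lines <- ncol(kspace$samples)
  if (is.null(line_weights)) line_weights <- rep(1, n_lines)
  if (all(line_weights == 0)) stop("empty selection: all line weights are zero")
  w <- density_weights(plan) * rep(line_weights, each = m)
  img <- nufft_adjoint_raw(plan, as.vector(kspace$samples) * w)
  Mod(img) * plan$deapod
}

#' Preliminary CINE reconstruction with Gaussian phase kernels
#'
#' Reconstructs a fixed number of cardiac frames from all acquired data:
#' frame `f` is centered at phase `100 f / n_frames` and every line is
#' weighted by `exp(-d^2 / (2 sigma^2))` where `d` is the circular phase
#' distance between the line's cardiac phase and the frame center and
#' `sigma = kernel_pct` (% of the cycle). Each frame is a
#' [gridded_recon()] with those weights.
#'
#' @param kspace A `kspace_set`.
#' @param phases_pct Per-line cardiac phase in % (e.g. from
#'   [normalize_phases()]).
#' @param n_frames Number of frames (default 50).
#' @param kernel_pct Gaussian kernel sigma in % of the cycle (default 5).
#' @param plan Optional [nufft_plan()].
#' @return Object of class `cine_series`: `frames` (4D array, last dim =
#'   frame), `centers_pct`, `weights` (`n_lines x n_frames`), `n_frames`.
#' @export
cine_recon <- function(kspace, phases_pct, n_frames = 50, kernel_pct = 5,
                       plan = kspace$plan) {
  if (n_frames < 2) stop("n_frames must be at least 2")
  stopifnot(length(phases_pct) == ncol(kspace$samples))
  centers <- 100 * (seq_len(n_frames) - 1) / n_frames
  m <- kspace$n_read
  frames <- array(0, dim = c(m, m, m, n_frames))
  wmat <- matrix(0, length(phases_pct), n_frames)
  keep <- !is.na(phases_pct)
  for (f in seq_len(n_frames)) {
    d <- abs(phases_pct - centers[f]) %% 100
    d <- pmin(d, 100 - d)
    w <- exp(-d^2 / (2 * kernel_pct^2))
    w[!keep] <- 0
    wmat[, f] <- w
    # unit-sum weights: frame intensity independent of how many lines
    # happen to fall near this frame center
    frames[, , , f] <- gridded_recon(kspace, w / sum(w), plan)
  }
  structure(list(frames = frames, centers_pct = centers, weights = wmat,
                 n_frames = n_frames, kernel_pct = kernel_pct),
            class = "cine_series")
}
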