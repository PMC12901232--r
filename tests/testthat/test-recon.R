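small_plan <- function() {
  cached("recon_plan", {
    traj <- generate_phyllotaxis(protocol_spec(matrix = 16, n_shots = 40,
                                               n_segments = 3))
    nufft_plan(traj)
  })
}

rand_vol <- function(n, seed) {
  set.seed(seed)
  array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), rep(n, 3))
}

test_that("density weights follow the |k|^2 ramp with a small-volume center", {
  plan <- small_plan()
  w <- density_weights(plan)
  prof <- w[seq_len(plan$n_read)]
  expect_equal(which.min(prof), which(plan$t_rad == 0))
  i1 <- which(plan$t_rad == 2); i2 <- which(plan$t_rad == 4)
  expect_equal(prof[i2] / prof[i1], 4)          # doubling |k| quadruples
  expect_equal(max(prof), 1)
})

test_that("forward sampling is linear and exact at the k-space center", {
  plan <- small_plan()
  x1 <- rand_vol(16, 1); x2 <- rand_vol(16, 2)
  f <- cardiosync:::nufft_forward_one
  expect_equal(f(plan, 3 * x1 + x2), 3 * f(plan, x1) + f(plan, x2),
               tolerance = 1e-12)
  expect_true(all(f(plan, x1 * 0) == 0))
  # DC Fourier identity: the center sample of every line is the spatial sum
  y <- f(plan, x1)
  dc <- y[which(plan$t_rad == 0) + plan$n_read * (0:(plan$n_lines - 1))]
  expect_equal(dc, rep(sum(x1), plan$n_lines), tolerance = 1e-9)
})

test_that("forward and adjoint are an adjoint pair", {
  plan <- small_plan()
  x <- rand_vol(16, 3)
  set.seed(4)
  y <- complex(real = rnorm(plan$n_read * plan$n_lines),
               imaginary = rnorm(plan$n_read * plan$n_lines))
  lhs <- sum(Conj(y) * cardiosync:::nufft_forward_one(plan, x))
  rhs <- sum(Conj(cardiosync:::nufft_adjoint_raw(plan, y)) * x)
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-3)
})

test_that("static phantom round-trips through sampling and reconstruction", {
  sk <- static_kspace()
  rec <- gridded_recon(sk$kspace)
  v <- Re(sk$volume)
  sc <- sum(rec * v) / sum(rec^2)
  nrmse <- sqrt(mean((sc * rec - v)^2)) / diff(range(v))
  expect_lt(nrmse, 0.15)
  # density compensation helps: unweighted adjoint is worse
  raw <- Mod(cardiosync:::nufft_adjoint_raw(sk$plan,
                                            as.vector(sk$kspace$samples)))
  sc2 <- sum(raw * v) / sum(raw^2)
  expect_gt(sqrt(mean((sc2 * raw - v)^2)) / diff(range(v)), nrmse)
  # weight linearity: scaling all line weights scales the image
  r1 <- gridded_recon(sk$kspace, rep(1, ncol(sk$kspace$samples)))
  r3 <- gridded_recon(sk$kspace, rep(3, ncol(sk$kspace$samples)))
  expect_equal(r3, 3 * r1, tolerance = 1e-12)
  # degenerate input contracts
  one <- c(1, rep(0, ncol(sk$kspace$samples) - 1))
  expect_true(all(is.finite(gridded_recon(sk$kspace, one))))
  expect_error(gridded_recon(sk$kspace, one * 0), "empty selection")
})

test_that("forward sampling of the beating phantom picks the nearest phase", {
  ds <- small_dataset()
  expect_equal(dim(ds$kspace$samples), c(32, 260 * 12))
  # the simulated phase of each line round-trips through the stretch model
  expect_equal(ds$kspace$sim_phase_pct,
               cardiac_phase_at(ds$kspace$traj$time_ms, ds$beats_true,
                                ds$stretch))
})

test_that("CINE weighting is a circular Gaussian and frames default to 50", {
  sk <- static_kspace()
  n_lines <- ncol(sk$kspace$samples)
  set.seed(5)
  ph <- runif(n_lines, 0, 100)
  ph[1] <- 0; ph[2] <- 99; ph[3] <- 1
  cine <- cine_recon(sk$kspace, ph, n_frames = 10)
  expect_equal(cine$n_frames, 10)
  expect_equal(dim(cine$frames)[4], 10)
  # a line exactly at a frame center gets that frame's maximum weight
  expect_equal(cine$weights[1, 1], max(cine$weights[, 1]))
  # circular distance: phases 99 and 1 are equally close to center 0
  expect_equal(cine$weights[2, 1], cine$weights[3, 1], tolerance = 1e-12)
  expect_error(cine_recon(sk$kspace, ph, n_frames = 1), "n_frames")
  expect_error(cine_recon(sk$kspace, ph[-1]), "length")
  # static data: frames differ only in the weighting of identical data.
  # With one common phase the unit-sum weights are identical and frames
  # agree exactly; with random phases the residual difference is the
  # angular-coverage streak level of the desk-scale protocol.
  cine0 <- cine_recon(sk$kspace, rep(42, n_lines), n_frames = 4)
  expect_equal(cine0$frames[, , , 2], cine0$frames[, , , 1], tolerance = 1e-10)
  expect_equal(cine0$frames[, , , 4], cine0$frames[, , , 1], tolerance = 1e-10)
  f1 <- cine$frames[, , , 1]
  for (f in 2:10) {
    nrmse <- sqrt(mean((cine$frames[, , , f] - f1)^2)) / diff(range(f1))
    expect_lt(nrmse, 0.05)
  }
})

test_that("default CINE of a simulated dataset emits exactly 50 frames", {
  fit <- small_fit()
  expect_length(fit$curve, 50)
  ds <- small_dataset()
  ph <- normalize_phases(ds$kspace$traj$time_ms, ds$beats_true)
  cine <- cine_recon(ds$kspace, ph)
  expect_equal(cine$n_frames, 50)
  expect_equal(cine$centers_pct, seq(0, 98, 2))
})
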