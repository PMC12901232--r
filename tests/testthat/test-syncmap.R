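test_that("min-phase map equals the brute-force per-voxel argmin", {
  set.seed(21)
  cine <- array(runif(3 * 3 * 3 * 50, 0.5, 1), c(3, 3, 3, 50))
  cine[1, 1, 1, ] <- 0.7               # constant voxel: tie rule
  cine[2, 2, 2, c(5, 9)] <- 0.1        # tie at two frames: first wins
  mp <- compute_min_phase_map(cine, floor_fraction = 0)
  oracle <- array(0L, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    oracle[i, j, k] <- which.min(cine[i, j, k, ])
  }
  expect_identical(mp$phase, oracle)
  expect_equal(mp$phase[1, 1, 1], 1L)
  expect_equal(mp$phase[2, 2, 2], 5L)
})

test_that("the intensity floor invalidates dark voxels and empty cines", {
  cine <- array(1, c(4, 4, 4, 10))
  cine[1, , , ] <- 0.01               # well below 20% of the global mean
  mp <- compute_min_phase_map(cine, floor_fraction = 0.2)
  expect_true(all(!mp$valid[1, , ]))
  expect_true(all(mp$valid[2:4, , ]))
  mp0 <- compute_min_phase_map(array(0, c(4, 4, 4, 10)))
  expect_true(all(!mp0$valid))
})

fake_map <- function(phase, valid = array(TRUE, dim(phase)), n_frames = 50L) {
  structure(list(phase = phase, valid = valid, n_frames = n_frames),
            class = "min_phase_map")
}

test_that("26-connectivity groups faces, edges and corners", {
  ph <- array(1L, c(3, 3, 3))
  sy <- connected_regions(fake_map(ph), min_voxels = 1)
  expect_equal(nrow(sy$regions), 1)
  expect_equal(sy$regions$n_voxels, 27)
  # two voxels touching only at a corner are one region
  ph2 <- array(0L, c(4, 4, 4)); ph2[] <- rep(1:8, length.out = 64)
  ph2 <- array(9L, c(4, 4, 4))
  valid <- array(FALSE, c(4, 4, 4))
  valid[1, 1, 1] <- TRUE; valid[2, 2, 2] <- TRUE
  sy2 <- connected_regions(fake_map(ph2, valid), min_voxels = 1)
  expect_equal(nrow(sy2$regions), 1)
  expect_equal(sy2$regions$n_voxels, 2)
  # same corner contact with different phases: two regions
  ph3 <- ph2; ph3[2, 2, 2] <- 5L
  sy3 <- connected_regions(fake_map(ph3, valid), min_voxels = 1)
  expect_equal(nrow(sy3$regions), 2)
})

test_that("labels of a random phase field match a BFS flood-fill oracle", {
  set.seed(31)
  ph <- array(sample(1:3, 12^3, replace = TRUE), c(12, 12, 12))
  valid <- array(runif(12^3) > 0.2, c(12, 12, 12))
  sy <- connected_regions(fake_map(ph, valid), min_voxels = 1)
  oracle <- bfs_label_oracle(ph, valid)
  expect_true(same_partition(sy$labels, oracle))
  # size filtering drops small oracle components
  sy10 <- connected_regions(fake_map(ph, valid), min_voxels = 10)
  osz <- table(oracle)
  expect_equal(sum(sy10$regions$n_voxels),
               sum(osz[osz >= 10]))
})

test_that("top-region selection is a ceiling sort-and-slice", {
  # four regions of sizes 100, 50, 20, 10 in a flat array
  ph <- array(0L, c(12, 12, 2))
  ph[1:10, 1:10, 1] <- 1L; ph[1:10, 1:5, 2] <- 2L
  ph[11:12, 1:10, 1] <- 3L; ph[11:12, 1:5, 2] <- 4L
  valid <- ph > 0
  ph[!valid] <- 99L
  sy <- connected_regions(fake_map(ph, valid), min_voxels = 1)
  expect_equal(sort(sy$regions$n_voxels, decreasing = TRUE),
               c(100, 50, 20, 10))
  top <- select_top_regions(sy, 0.25)
  expect_equal(top$regions$n_voxels, 100)
  expect_identical(select_top_regions(sy, 1)$regions, sy$regions)
  # larger random fixture against an explicit sort oracle
  set.seed(41)
  ph2 <- array(sample(1:40, 16^3, replace = TRUE), c(16, 16, 16))
  sy2 <- connected_regions(fake_map(ph2), min_voxels = 1)
  top2 <- select_top_regions(sy2, 0.25)
  k <- ceiling(0.25 * nrow(sy2$regions))
  expect_equal(sort(top2$regions$n_voxels, decreasing = TRUE),
               sort(sy2$regions$n_voxels, decreasing = TRUE)[seq_len(k)])
})

# build a cine whose single-phase regions carry prescribed time curves
curve_cine <- function(curves, nx = 6) {
  nf <- length(curves[[1]])
  arr <- array(0.5, c(nx, nx, length(curves), nf))
  for (r in seq_along(curves)) {
    arr[, , r, ] <- rep(curves[[r]], each = nx * nx)
  }
  arr
}

test_that("the physiological filter keeps ejection-time-compatible regions", {
  nf <- 50
  mean_rr <- 800                     # HR 75 -> expected ET 388.5 ms
  # region A: max at frame 1, min at frame 21 -> 40% of RR = 320 ms (kept)
  ca <- rep(1, nf); ca[1] <- 2; ca[21] <- 0
  # region B: extrema 2 frames apart -> 32 ms (noise-like, rejected)
  cb <- rep(1, nf); cb[5] <- 2; cb[6] <- 0
  cine <- curve_cine(list(ca, cb))
  ph <- array(1L, c(6, 6, 2)); ph[, , 2] <- 2L
  sy <- connected_regions(fake_map(ph), min_voxels = 1)
  out <- filter_physiological(sy, cine, mean_rr)
  expect_equal(nrow(out$regions), 1)
  kept <- out$regions
  expect_equal(kept$extrema_interval_ms, 320)
  expect_true(kept$extrema_interval_ms >= 388.5 * 0.7)
  # a phase-shifted outflow-tract analog is rejected, the LV retained
  cc <- rep(1, nf); cc[30] <- 2; cc[33] <- 0   # 3 frames -> 48 ms, rejected
  cine2 <- curve_cine(list(ca, cc))
  out2 <- filter_physiological(sy, cine2, mean_rr)
  expect_equal(nrow(out2$regions), 1)
  # all regions rejected -> diagnostic error listing intervals
  cine3 <- curve_cine(list(cb, cc))
  expect_error(filter_physiological(sy, cine3, mean_rr), "region intervals")
})

test_that("mean time curves match brute force and normalize to [0, 1]", {
  set.seed(51)
  cine <- array(runif(4 * 4 * 4 * 10, 1, 2), c(4, 4, 4, 10))
  mask <- array(FALSE, c(4, 4, 4)); mask[1:2, 1, 1] <- TRUE
  cv <- mean_time_curve(cine, mask)
  brute <- sapply(1:10, function(f) mean(c(cine[1, 1, 1, f], cine[2, 1, 1, f])))
  expect_equal(as.numeric(cv), (brute - min(brute)) / diff(range(brute)))
  expect_equal(min(cv), 0); expect_equal(max(cv), 1)
  # single-voxel mask
  m1 <- array(FALSE, c(4, 4, 4)); m1[3, 3, 3] <- TRUE
  c1 <- mean_time_curve(cine, m1)
  raw <- cine[3, 3, 3, ]
  expect_equal(as.numeric(c1), (raw - min(raw)) / diff(range(raw)))
  expect_error(mean_time_curve(cine, array(FALSE, c(4, 4, 4))), "empty mask")
})
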