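test_that("zero-variability beat sampling gives equal RR intervals", {
  b <- sample_beats(heart_model(800, 0), 60000, seed = 3)
  expect_equal(length(b$rr_ms), 75)
  expect_true(all(b$rr_ms == 800))
  expect_equal(b$r_times_ms[1], 0)
})

test_that("jittered RR moments match the truncated-normal oracle", {
  m <- heart_model(650, 165)
  b <- sample_beats(m, 680000, seed = 1)
  # closed-form truncated normal moments on [max(300, mu-3s), mu+3s]
  a <- (max(300, 650 - 3 * 165) - 650) / 165
  z <- (650 + 3 * 165 - 650) / 165
  zden <- pnorm(z) - pnorm(a)
  mu_tr <- 650 + 165 * (dnorm(a) - dnorm(z)) / zden
  var_tr <- 165^2 * (1 + (a * dnorm(a) - z * dnorm(z)) / zden -
                       ((dnorm(a) - dnorm(z)) / zden)^2)
  n <- length(b$rr_ms)
  expect_lt(abs(mean(b$rr_ms) - mu_tr), 3 * sqrt(var_tr / n))
  expect_lt(abs(sd(b$rr_ms) - sqrt(var_tr)), 4 * sqrt(var_tr / n))
  expect_true(all(b$rr_ms >= max(300, 650 - 3 * 165)))
  expect_true(all(b$rr_ms <= 650 + 3 * 165))
  # reproducibility, and the caller's RNG state is untouched
  set.seed(99); before <- .Random.seed
  b2 <- sample_beats(m, 680000, seed = 1)
  expect_identical(.Random.seed, before)
  expect_identical(b$rr_ms, b2$rr_ms)
})

test_that("degenerate heart models are rejected", {
  expect_error(heart_model(650, 700), "degenerate")
  expect_error(sample_beats(heart_model(800, 0), 500), "duration_ms")
})

test_that("volume-curve variants satisfy the construction constraints", {
  for (v in 0:9) {
    cv <- make_volume_curve(v)
    expect_equal(which.max(cv$v_of_phase), 1)          # ED peak at phase 0
    es <- cv$phases_pct[which.min(cv$v_of_phase)]
    expect_gte(es, 30); expect_lte(es, 45)              # ES trough position
    expect_equal(cv$v_fun(0), cv$v_fun(99.999999), tolerance = 1e-4)
  }
  slopes <- sapply(0:9, function(v)
    mean(make_volume_curve(v)$dv_fun(seq(56, 78, 2))))
  expect_false(any(duplicated(round(slopes, 8))))      # plateaus all differ
  expect_error(make_volume_curve(10), "variant_id")
  expect_error(make_volume_curve(-1), "variant_id")
})

test_that("phase mapping is linear without stretch and stretched with it", {
  b <- beat_sequence(c(0, 800, 1600, 2400))
  off <- stretch_model(enabled = FALSE)
  expect_equal(cardiac_phase_at(c(0, 800, 1600), b, off), c(0, 0, 0))
  expect_equal(cardiac_phase_at(c(400, 1200), b, off), c(50, 50))
  expect_equal(cardiac_phase_at(seq(0, 799, 100), b, off),
               100 * seq(0, 799, 100) / 800)
  # short beats spend a larger fraction of the beat in systole
  b2 <- beat_sequence(c(0, 600, 1700))
  sm <- stretch_model()
  fs_short <- (546 - 2.1 * (60000 / 600)) / 600
  fs_long <- (546 - 2.1 * (60000 / 1100)) / 1100
  expect_gt(fs_short, fs_long)
  # the mapping hits t_es_pct exactly at the modeled systolic fraction
  expect_equal(cardiac_phase_at(600 + fs_long * 1100, b2, sm)[1],
               sm$t_es_pct %% 100, tolerance = 1e-9)
  expect_error(cardiac_phase_at(5000, b2), "span")
  # linear_phase_of inverts the stretch map
  q <- c(10, 36, 60, 90)
  expect_equal(cardiac_phase_at(600 + linear_phase_of(q, 1100, sm) * 11, b2, sm),
               q, tolerance = 1e-9)
})

test_that("bSSFP contrast behaves as the steady-state equation predicts", {
  expect_equal(bssfp_signal(1000, 100, 1, 0), 0)            # sin(0) = 0
  blood <- bssfp_signal(1660, 240, 0.95, 60)
  myo <- bssfp_signal(870, 45, 0.9, 60)
  expect_gt(blood, myo)                                     # T2/T1 weighting
  a <- 60 * pi / 180; r <- 1660 / 240
  expect_equal(blood, 0.95 * sin(a) / ((r + 1) - cos(a) * (r - 1)))
})

test_that("rendered phases track the volume curve within voxelization error", {
  cv <- make_volume_curve(0)
  pv <- cached("render32", render_phases(phantom_spec(matrix = 32), cv))
  expect_length(pv$volumes, 50)
  expect_true(all(abs(pv$lv_volume_ml - cv$v_of_phase) / cv$v_of_phase < 0.02))
  # flip angle 0 -> zero signal everywhere
  pv0 <- render_phases(phantom_spec(matrix = 16, flip_deg = 0),
                       make_volume_curve(0))
  expect_true(all(pv0$volumes[[1]] == 0))
  # monotonicity: a larger requested cavity volume gives more cavity voxels
  cv2 <- cv
  cv2$v_of_phase[10] <- cv$v_of_phase[10] + 10
  pv2 <- render_phases(phantom_spec(matrix = 32), cv2)
  expect_gt(sum(pv2$lv_masks[[10]]), sum(pv$lv_masks[[10]]))
  # vessel centerline moves with the cavity scale
  d_es <- sqrt(sum((pv$centerlines[[19]][1, ] - pv$centerlines[[1]][1, ])^2))
  expect_gt(d_es, 3)   # mm of AV-groove motion between ED and ES
})

test_that("ground truth extrema, plateau center and ms mapping are correct", {
  # triangle-with-plateau fixture: max at 0, min at 50, flat 70..90
  p <- seq(0, 98, 2)
  val <- approx(x = c(0, 50, 70, 90, 100), y = c(120, 50, 110, 110, 120),
                xout = p)$y
  fake <- structure(list(
    variant_id = 0L, phases_pct = p, v_of_phase = val,
    v_fun = function(q) approx(c(0, 50, 70, 90, 100),
                               c(120, 50, 110, 110, 120), q %% 100)$y,
    dv_fun = function(q) {
      qq <- q %% 100
      ifelse(qq < 50, -70 / 50, ifelse(qq < 70, 3, ifelse(qq < 90, 0, 1)))
    },
    t_es_pct = 50), class = "volume_curve")
  b <- beat_sequence(seq(0, 5000, 1000))
  gt <- ground_truth(fake, b, stretch_model(enabled = FALSE))
  expect_equal(unname(gt$t_pct[c("ES", "ED")]), c(50, 0))
  # sampled flat span is 70..88 (dV jumps at 90); its midpoint frame is 78
  expect_equal(unname(gt$t_pct["MD"]), 78)
  expect_equal(unname(gt$t_ms["ES"]), 500)        # 50% of mean RR 1000
  # variant-0 plateau center equals an exhaustive scan oracle
  cv <- make_volume_curve(0)
  gt0 <- ground_truth(cv, b)
  thr <- 0.009 * diff(range(cv$v_of_phase))
  es <- cv$phases_pct[which.min(cv$v_of_phase)]
  ordp <- cv$phases_pct[order((cv$phases_pct - es) %% 100)]
  flat <- abs(cv$dv_fun(ordp)) < thr & ((ordp - es) %% 100) > 0
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  k <- which(r$values)[which.max(r$lengths[r$values])]
  span <- ordp[(ends[k] - r$lengths[k] + 1):ends[k]]
  expect_equal(unname(gt0$t_pct["MD"]), span[ceiling(length(span) / 2)])
})
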