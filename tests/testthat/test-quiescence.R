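frame_curve <- function(f) f(seq(0, 98, 2))
circ_mid_pct_test <- function(a, b) (a + ((b - a) %% 100) / 2) %% 100

test_that("timepoints of a cosine curve sit at its analytic extrema", {
  cv <- frame_curve(function(p) (1 + cos(2 * pi * p / 100)) / 2)
  tp <- detect_timepoints(cv)
  expect_equal(unname(tp$t_pct["ES"]), 50)
  expect_equal(unname(tp$t_pct["ED"]), 0)
})

test_that("the knee and mid-diastole follow the chord-distance construction", {
  # drop to the minimum at 36%, steep rise to 0.9 at 46%, flat plateau,
  # maximum near 96%: knee at the top of the rise, mid-diastole at the
  # circular midpoint between the knee and the maximum
  p <- seq(0, 98, 2)
  val <- numeric(50)
  val[p < 36] <- approx(c(-4, 36), c(1, 0), p[p < 36])$y   # descent from wrap
  val[p >= 36 & p < 46] <- 0.9 * (p[p >= 36 & p < 46] - 36) / 10
  val[p >= 46 & p < 96] <- 0.9
  val[p >= 96] <- 1
  tp <- detect_timepoints(val)
  expect_equal(unname(tp$t_pct["ES"]), 36, tolerance = 0.05)  # sub-frame refined
  expect_equal(unname(tp$t_pct["ED"]), 97, tolerance = 0.05)  # plateau-edge vertex
  expect_equal(tp$knee_pct, 46)
  expect_equal(unname(tp$t_pct["MD"]),
               circ_mid_pct_test(tp$knee_pct, tp$t_pct[["ED"]]))
  # a flat curve is a detection failure
  flat <- rep(0.5, 50)
  attr(flat, "raw_range") <- c(1, 1.01)
  expect_error(detect_timepoints(flat), "flat")
})

test_that("interval detection honors the amplitude band and the 200 ms cap", {
  ctrl <- sync_control()
  # near-flat plateau of 9 frames (18%) at RR 1000 -> 180 ms, unshrunk
  cv <- rep(1, 50); cv[20:28] <- 0 + abs(seq(-4, 4)) * 0.002
  iv <- detect_intervals(cv, 24, 1000, ctrl)
  expect_equal(iv$n_frames, 9)
  expect_equal(iv$duration_ms, 180)
  expect_equal(iv$tau_pct, 3)
  # wide gently sloped plateau at RR 1000 -> iterative lowering below 200 ms
  cv2 <- rep(1, 50); cv2[10:29] <- abs(seq(-9.5, 9.5)) * 0.0028
  iv2 <- detect_intervals(cv2, 20, 1000, ctrl)
  expect_lt(iv2$duration_ms, 200)
  expect_lt(iv2$tau_pct, 3)
  expect_false(iv2$capped)
  # strictly V-shaped curve: single frame = mean RR / 50
  cv3 <- abs(seq_len(50) - 25) / 10
  iv3 <- detect_intervals(cv3, 25, 900, ctrl)
  expect_equal(iv3$n_frames, 1)
  expect_equal(iv3$duration_ms, 900 / 50)
  # perfectly flat wide plateau: threshold exhausts with a warning
  cv4 <- rep(1, 50); cv4[5:29] <- 0
  expect_warning(iv4 <- detect_intervals(cv4, 15, 1000, ctrl), "single-frame")
  expect_true(iv4$capped)
  expect_lt(iv4$duration_ms, 200)
})

test_that("acceptance windows adapt center and width to each beat", {
  iv <- list(ES = list(start_pct = 30, duration_pct = 10))
  b <- beat_sequence(c(0, 700, 1700))
  t_lines <- seq(0, 1699, by = 10)
  ph <- normalize_phases(t_lines, b)
  win <- build_acceptance_windows(iv, b, ph, t_lines)
  w <- win$targets$ES$windows
  expect_equal(w$end_ms - w$start_ms, c(70, 100))   # widths scale with RR
  expect_equal(w$start_ms, c(0, 700) + 0.3 * c(700, 1000))
  # mask selects exactly the lines whose phase is inside the interval
  sel <- win$targets$ES$mask
  expect_true(all(ph[sel] >= 30 & ph[sel] <= 40))
  expect_true(all(ph[!sel] < 30 | ph[!sel] > 40, na.rm = TRUE))
  # equal beats -> identical windows
  b0 <- beat_sequence(seq(0, 4000, 800))
  w0 <- build_acceptance_windows(iv, b0, normalize_phases(NULL, b0))
  expect_equal(unique(round(w0$targets$ES$windows$end_ms -
                            w0$targets$ES$windows$start_ms, 9)), 80)
  # an interval wrapping phase 0 yields two sub-windows inside each beat
  ivw <- list(ED = list(start_pct = 96, duration_pct = 8))
  ww <- build_acceptance_windows(ivw, b0, normalize_phases(t_lines, b0),
                                 t_lines)
  expect_equal(nrow(ww$targets$ED$windows), 2 * length(b0$rr_ms))
  phw <- normalize_phases(t_lines, b0)
  selw <- ww$targets$ED$mask
  expect_true(all(phw[selw] >= 96 | phw[selw] <= 4))
})

test_that("end-to-end detection is accurate, capped, and deterministic", {
  ds <- small_dataset()
  fit <- small_fit()
  # all three intervals below the 200 ms cap via the mean RR
  for (iv in fit$intervals) expect_lt(iv$duration_ms, 200)
  # each timepoint lies inside its interval (circularly)
  for (k in names(fit$t_pct)) {
    iv <- fit$intervals[[k]]
    expect_lte((fit$t_pct[[k]] - iv$start_pct) %% 100, iv$duration_pct)
  }
  # end-to-end temporal accuracy at zero variability: within 2 frames (4%)
  val <- validate_detection(fit, ds)
  es <- val[val$phase == "ES", ]
  expect_lte(abs(circular_diff_pct(es$detected_pct, es$truth_pct)), 4)
  # detection reruns are bit-identical
  fit2 <- quiescence(ds)
  expect_identical(fit$t_pct, fit2$t_pct)
  expect_identical(fit$curve, fit2$curve)
  expect_identical(fit$windows$targets$MD$mask, fit2$windows$targets$MD$mask)
})

test_that("trigger-mode beats leave detections unchanged within one frame", {
  ds <- small_dataset()
  fit_sg <- small_fit()
  fit_tr <- small_fit_trigger()
  for (k in c("ES", "MD", "ED")) {
    p_sg <- phase_in_reference_frame(fit_sg$t_pct[[k]], fit_sg$beats,
                                     ds$beats_true)
    p_tr <- phase_in_reference_frame(fit_tr$t_pct[[k]], fit_tr$beats,
                                     ds$beats_true)
    expect_lte(abs(circular_diff_pct(p_sg, p_tr)), 2.5)
  }
})

test_that("the retained synchronicity region overlaps the left ventricle", {
  ds <- small_dataset()
  fit <- small_fit()
  region <- !is.na(fit$sync$labels)
  expect_gte(mean(ds$lv_mask_ed[region]), 0.5)
})

test_that("the fit object prints, summarizes and predicts", {
  fit <- small_fit()
  expect_output(print(fit), "Quiescent cardiac phase detection")
  expect_output(print(summary(fit)), "Synchronicity regions")
  expect_named(coef(fit), c("ES", "MD", "ED"))
  expect_equal(coef(fit, "ms"), coef(fit) * fit$mean_rr_ms / 100,
               ignore_attr = TRUE)
  nb <- beat_sequence(seq(0, 8000, 750))
  pw <- predict(fit, nb, line_time_ms = seq(0, 7999, 5))
  expect_equal(nrow(pw$targets$ES$windows) %% length(nb$rr_ms), 0)
  js <- report_json(fit)
  expect_true(jsonlite::validate(js))
  p <- jsonlite::fromJSON(js)
  expect_lt(max(unlist(p$intervals)["MD.duration_ms"]), 200)
})
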