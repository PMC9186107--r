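test_that("velocity is exact on constant and linear trajectories", {
  n <- 200
  flat <- cbind(rep(0.3, n), rep(-0.1, n))
  expect_true(all(compute_velocity(flat, 500) == 0))
  # ramp at 1 deg/s: the 5-point stencil is exact on linear input
  t <- (0:(n - 1)) / 500
  ramp <- cbind(t * 1, t * 0)
  v <- compute_velocity(ramp, 500)
  expect_equal(v[5:(n - 4), 1], rep(1, n - 8), tolerance = 1e-10)
  expect_error(compute_velocity(ramp[1:4, ], 500), class = "too_short")
})

test_that("stencil recovers the peak of a raised-cosine pulse within 5%", {
  rate <- 1000
  eye <- inject_pulses(onsets = 2, amplitudes = 0.5, rate = rate,
                       duration = 4, drift_sd = 0.002, seed = 3)
  v <- compute_velocity(eye, rate)
  expect_equal(max(abs(v[, 1])), 100 * 0.5, tolerance = 0.05)
})

test_that("sub-threshold traces yield no events; flat traces warn", {
  set.seed(1)
  n <- 20000
  jitter <- cbind(cumsum(rnorm(n, sd = 1e-4)), cumsum(rnorm(n, sd = 1e-4)))
  jitter <- jitter - stats::filter(jitter, rep(1 / 500, 500), sides = 2,
                                   circular = TRUE)
  expect_equal(nrow(detect_microsaccades(jitter, 500)), 0)
  flat <- cbind(rep(1, 1000), rep(1, 1000))
  expect_warning(out <- detect_microsaccades(flat, 500), "flat")
  expect_equal(nrow(out), 0)
})

test_that("injected pulses are detected with accurate onsets and amplitudes", {
  onsets <- seq(2, 55, by = 2.5)
  amps <- seq(0.1, 0.9, length.out = length(onsets))
  eye <- inject_pulses(onsets, amps, rate = 500, duration = 60, seed = 4)
  det <- detect_microsaccades(eye, 500)
  # every injected pulse is found, at worst one spurious drift excursion
  matched <- vapply(onsets, function(t) {
    j <- which.min(abs(det$onset - t))
    if (abs(det$onset[j] - t) <= 0.010) j else NA_integer_
  }, integer(1))
  expect_false(anyNA(matched))
  expect_lte(nrow(det), length(onsets) + 1)
  expect_equal(det$amplitude[matched], amps, tolerance = 0.15)
})

test_that("events with amplitude above 1 degree are excluded", {
  eye <- inject_pulses(c(5, 10, 15), c(0.5, 1.5, 0.3), rate = 500,
                       duration = 20, seed = 5)
  det <- detect_microsaccades(eye, 500)
  expect_equal(nrow(det), 2)
  expect_equal(match_onsets(c(5, 15), det$onset), 2)
  expect_true(all(det$amplitude <= 1))
})

test_that("events closer than 100 ms are merged into one spanning event", {
  eye <- inject_pulses(c(5, 5.05), c(0.3, 0.3), rate = 500,
                       duration = 10, seed = 6)
  det <- detect_microsaccades(eye, 500)
  expect_equal(nrow(det), 1)
  expect_gt(det$offset - det$onset, 0.05)
})

test_that("detection is invariant to position offsets and equivariant under axis swap", {
  eye <- inject_pulses(seq(2, 18, by = 2), rep(0.4, 9), rate = 500,
                       duration = 20, seed = 7)
  det <- detect_microsaccades(eye, 500)
  det_off <- detect_microsaccades(eye + 3.7, 500)
  expect_equal(det, det_off)
  det_swap <- detect_microsaccades(eye[, c(2, 1)], 500)
  expect_equal(det_swap, det)
})

test_that("detector output satisfies every microsaccade invariant on a full session", {
  rec <- demo_session()
  det <- demo_analysis()$microsaccades
  expect_true(all(det$offset - det$onset >= 0.006 - 1e-9))
  expect_true(all(det$amplitude <= 1))
  expect_true(all(det$peak_velocity <= 100))
  expect_true(all(det$onset[-1] - det$offset[-nrow(det)] >= 0.1 - 1e-9))
  # main sequence of detected events validates the detector
  expect_gt(main_sequence_correlation(det), 0.9)
  expect_error(main_sequence_correlation(det[1:2, ]),
               class = "insufficient_data")
})

test_that("per-period metrics follow their definitions", {
  rec <- demo_session()
  an <- demo_analysis()
  ev <- rec$events
  pre <- ev[ev$period_type == "prestimulus" & !ev$is_initial, ]
  det <- an$microsaccades
  pp <- per_period_metrics(rec, det)
  # rate = count / duration for an arbitrary period
  i <- 25
  cnt <- sum(det$onset >= pre$onset[i] &
               det$onset < pre$onset[i] + pre$duration[i])
  expect_equal(pp$msrate$value[i], cnt / pre$duration[i])
  # initial fixation periods contribute no rate sample
  expect_equal(nrow(pp$msrate), nrow(pre))
  expect_true(all(pp$msrate$time_s %in% pre$onset))
  # reaction times are positive and below the 400-ms deadline (+ tolerance)
  expect_true(all(pp$rt$value > 0 & pp$rt$value < 0.45))
  expect_true(all(pp$sacc_vel$value >= 150))
})

test_that("constant pupil gives that constant in every stimulus period", {
  rec <- demo_session()
  rec2 <- rec
  rec2$eye$pupil <- rep(4.2, nrow(rec2$eye))
  pp <- per_period_metrics(rec2, demo_analysis()$microsaccades)
  expect_true(all(abs(pp$pupil$value - 4.2) < 1e-12))
})
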