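test_that("segments come from non-initial prestimulus periods, average-referenced", {
  rec <- demo_session()
  segs <- extract_segments(rec)
  ev <- rec$events
  n_expected <- sum(ev$period_type == "prestimulus" & !ev$is_initial)
  expect_equal(dim(segs$data)[3], n_expected)
  expect_equal(dim(segs$data)[2], 0.3 * rec$eeg_rate) # 300 ms of samples
  # after average referencing the electrode mean is ~0 at every sample
  reref <- rec$eeg - rep(colMeans(rec$eeg), each = nrow(rec$eeg))
  expect_lt(max(abs(colMeans(reref[, 1:1000]))), 1e-18)
  expect_lt(max(abs(colMeans(segs$data[, , 5]))), 1e-18)
})

test_that("a trial with n prestimulus periods contributes n - 1 segments", {
  rec <- demo_session()
  ev <- rec$events
  segs <- extract_segments(rec)
  tr <- ev[ev$trial == 3 & ev$period_type == "prestimulus", ]
  in_trial <- segs$onsets %in% tr$onset
  expect_equal(sum(in_trial), nrow(tr) - 1)
})

test_that("screening rejects amplitude artifacts, flat channels and noisy-eye segments", {
  rec <- demo_session()
  segs <- extract_segments(rec)
  rate <- rec$eeg_rate
  # inject a 20x amplitude artifact into segment 10, electrode 2
  segs$data[2, , 10] <- segs$data[2, , 10] * 20
  # zero out segment 20, electrode 5 (flat)
  segs$data[5, , 20] <- 0
  scr <- screen_segments(segs, rec)
  log <- attr(scr, "screen_log")
  expect_true(log$rule_amplitude[10])
  expect_true(log$rule_flat[20])
  expect_false(log$kept[10])
  expect_false(log$kept[20])
  # high eye-position variability during a period triggers the eye rule
  rec2 <- rec
  pre <- rec$events[rec$events$period_type == "prestimulus" &
                      !rec$events$is_initial, ]
  i0 <- floor(pre$onset[30] * rec$eye_rate) + 1
  idx <- i0:(i0 + 100)
  rec2$eye$x[idx] <- rec2$eye$x[idx] + cumsum(rep(0.02, length(idx)))
  scr2 <- screen_segments(extract_segments(rec2), rec2)
  expect_true(attr(scr2, "screen_log")$rule_eye[30])
})

test_that("EEG-based rejection rules fire on under 5% of clean synthetic segments", {
  log <- attr(screen_segments(extract_segments(demo_session()),
                              demo_session()), "screen_log")
  expect_lt(mean(log$rule_amplitude | log$rule_flat), 0.05)
})

test_that("rejection depends only on session-level statistics, not other rejections", {
  rec <- demo_session()
  segs <- extract_segments(rec)
  log1 <- attr(screen_segments(segs, rec), "screen_log")
  # recompute rule 1 by hand from pre-rejection session statistics
  sds <- apply(segs$data[, , 1:50], c(1, 3), sd)
  all_sds <- apply(segs$data, c(1, 3), sd)
  manual <- apply(sds > 10 * rowMeans(all_sds), 2, any)
  expect_equal(log1$rule_amplitude[1:50], unname(manual))
})

test_that("segment spectra satisfy Parseval and resolve a pure sinusoid", {
  rate <- 500
  t <- (0:149) / rate
  sine <- rbind(2e-5 * sin(2 * pi * 10 * t), rnorm(150, sd = 1e-6))
  p <- segment_spectrum(sine, rate)
  f <- attr(p, "freq")
  expect_equal(f, 1:50)
  expect_equal(f[which.max(p[1, ])], 10)
  expect_gt(p[1, f == 10], 100 * p[1, f == 30])
  # zero input gives a zero spectrum
  expect_true(all(segment_spectrum(matrix(0, 2, 150), rate) == 0))
  # Parseval on the full grid
  pf <- segment_spectrum(sine, rate, full = TRUE)
  w <- 0.5 * (1 - cos(2 * pi * (0:149) / 149))
  energy <- rowSums((sine * rep(w, each = 2))^2)
  expect_lt(max(abs(rowSums(pf) - energy) / energy), 1e-9)
  expect_error(segment_spectrum(matrix(c(NA, rnorm(299)), 2), rate),
               class = "invalid_input")
})

test_that("batched power equals the per-segment spectrum", {
  rec <- demo_session()
  segs <- extract_segments(rec)
  pw <- segment_power_batch(segs)
  p1 <- segment_spectrum(segs$data[, , 7], segs$rate)
  expect_equal(pw$power[, , 7], t(p1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("spectral binning follows the shared geometry and min_segments rule", {
  # fabricated per-segment power: 3 freqs x 2 electrodes x segments
  onsets <- seq(0, 119 * 60, by = 30)
  ns <- length(onsets)
  pw <- structure(list(power = array(rep(c(1, 2, 3), 2 * ns), c(3, 2, ns)),
                       freq = c(5, 10, 15), onsets = onsets, rate = 1000),
                  class = "segment_power")
  b <- bin_spectra(pw, 120, window = 30, step = 6, min_segments = 10)
  expect_equal(length(b$bin_centers), 16)
  expect_equal(b$bin_centers, seq(15, 105, by = 6))
  # identical spectra in all segments -> every bin equals that spectrum
  expect_true(all(apply(b$power, 3, function(m) all(m == c(1, 2, 3)))))
  b1 <- bin_spectra(pw, 120, window = 30, step = 1, min_segments = 10)
  expect_equal(length(b1$bin_centers), 91)
  # a bin with fewer than min_segments segments is dropped
  pw2 <- pw
  pw2$onsets <- c(rep(10, 30), rep(110 * 60, ns - 30))
  b2 <- bin_spectra(pw2, 120, window = 30, step = 6, min_segments = 10)
  expect_true(all(b2$n_segments >= 10))
  expect_lt(length(b2$bin_centers), 16)
})

test_that("aperiodic removal recovers exponent and leaves bump-only residuals", {
  f <- 1:50
  for (chi in c(0.5, 1, 1.5)) {
    p <- 100 * f^(-chi)
    binned <- structure(list(power = array(p, c(50, 1, 1)), freq = f,
                             bin_centers = 15, n_segments = 50L),
                        class = "binned_spectra")
    rs <- remove_aperiodic(binned)
    # pure power law: residual ~ 0 everywhere
    expect_lt(max(abs(rs$residual)), 1e-6 * 100)
    expect_equal(rs$fits$exponent[1], chi, tolerance = 1e-6)
    # add a Gaussian alpha bump
    p2 <- p + 30 * exp(-(f - 10)^2 / (2 * 1.5^2))
    binned2 <- binned
    binned2$power <- array(p2, c(50, 1, 1))
    rs2 <- remove_aperiodic(binned2)
    expect_equal(rs2$fits$exponent[1], chi, tolerance = 0.05)
    expect_equal(rs2$residual[1, 10], 30, tolerance = 3)
  }
  badp <- 100 * f^(-1)
  badp[5] <- -1 # nonpositive power inside the 3-50 Hz fit range
  bad <- structure(list(power = array(badp, c(50, 1, 1)), freq = f,
                        bin_centers = 15, n_segments = 50L),
                   class = "binned_spectra")
  expect_error(remove_aperiodic(bad), "bin 1, electrode 1",
               class = "invalid_input")
})

test_that("residuals are averaged across electrodes after subtraction", {
  f <- 1:50
  bump <- 30 * exp(-(f - 10)^2 / (2 * 1.5^2))
  p1 <- 100 * f^(-0.5) + bump
  p2 <- 400 * f^(-1.5) + bump
  binned <- structure(list(power = array(c(p1, p2), c(50, 2, 1)), freq = f,
                           bin_centers = 15, n_segments = 50L),
                      class = "binned_spectra")
  rs <- remove_aperiodic(binned)
  # per-electrode fits differ, so residual-then-average != fit of the average;
  # the implemented order leaves only the common bump
  expect_equal(rs$residual[1, 10], 30, tolerance = 3)
  expect_lt(max(abs(rs$residual[1, c(3:6, 20:50)])), 3)
  expect_equal(rs$fits$exponent, c(0.5, 1.5), tolerance = 0.06)
})

test_that("band power integrates half-open intervals on the 1-Hz grid", {
  resid <- matrix(0, 2, 50)
  resid[, 10] <- 4 # bump only at 10 Hz
  rs <- structure(list(residual = resid, freq = 1:50, bin_centers = c(15, 21),
                       n_segments = c(40L, 40L)),
                  class = "residual_spectrum_set")
  expect_equal(band_power(rs, c(8, 12))$value, c(1, 1)) # 4 / |{8,9,10,11}|
  expect_equal(band_power(rs, c(4, 8))$value, c(0, 0))
  expect_equal(band_power(rs, c(12, 30))$value, c(0, 0))
  # 12 Hz belongs to beta, not alpha, under the half-open convention
  rs2 <- rs
  rs2$residual[, 12] <- 100
  expect_equal(band_power(rs2, c(8, 12))$value, c(1, 1))
  # constant residual -> every band equals that constant
  rs3 <- rs
  rs3$residual[] <- 2.5
  for (band in canonical_bands()) {
    expect_equal(band_power(rs3, band)$value, c(2.5, 2.5))
  }
  expect_error(band_power(rs, c(50.5, 50.9)), class = "invalid_parameter")
})

test_that("the sliding scan tiles 2-46 Hz and matches band_power at alpha", {
  resid <- matrix(rnorm(100), 2, 50)
  rs <- structure(list(residual = resid, freq = 1:50, bin_centers = c(15, 21),
                       n_segments = c(40L, 40L)),
                  class = "residual_spectrum_set")
  sl <- sliding_band_power(rs)
  expect_length(sl, 23)
  expect_equal(names(sl)[1], "2")
  expect_equal(sl[["8"]], band_power(rs, c(8, 12)))
  # Gaussian bump centered at 10: the 8-Hz left edge captures it best
  bump <- exp(-(1:50 - 10)^2 / 2)
  rs$residual <- rbind(bump, bump)
  sl2 <- sliding_band_power(rs)
  vals <- vapply(sl2, function(s) s$value[1], numeric(1))
  expect_equal(names(which.max(vals)), "8")
})

test_that("binned alpha power tracks the generating latent", {
  an <- demo_analysis()
  rec <- demo_session()
  alpha <- an$metrics$alpha
  lat_b <- latent_at_bins(rec, alpha$bin_center_min)
  expect_lte(cor(alpha$value, lat_b), -0.7) # alpha_coupling < 0
})
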