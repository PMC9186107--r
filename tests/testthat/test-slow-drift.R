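test_that("residualization removes orientation tuning exactly", {
  ori <- rep(c(45, 135), each = 10)
  counts <- rbind(ifelse(ori == 45, 2, 4),
                  ifelse(ori == 45, 7, 1))
  resid <- residual_counts(counts, ori)
  expect_true(all(abs(resid) < 1e-10))
  # per-orientation means are zero for arbitrary counts
  set.seed(5)
  counts2 <- matrix(rpois(60, 5), nrow = 3)
  resid2 <- residual_counts(counts2, rep(c(45, 135), 10))
  for (o in c(45, 135)) {
    expect_lt(max(abs(rowMeans(resid2[, rep(c(45, 135), 10) == o]))), 1e-10)
  }
  # adding a constant to one neuron leaves residuals unchanged
  counts3 <- counts2
  counts3[2, ] <- counts3[2, ] + 11
  expect_equal(residual_counts(counts3, rep(c(45, 135), 10)), resid2)
  expect_error(residual_counts(counts2, rep(45, 20)),
               class = "invalid_parameter")
})

test_that("residual binning shares geometry with the EEG binning", {
  resid <- matrix(rnorm(2 * 600), nrow = 2)
  times <- seq(0, 7199, length.out = 600)
  b <- bin_residuals(resid, times, 120, window = 30, step = 6)
  expect_equal(attr(b, "bin_centers"), sliding_bins(120, 30, 6)$center_min)
  expect_equal(nrow(b), 16)
  b1 <- bin_residuals(resid, times, 120, window = 30, step = 1)
  expect_equal(nrow(b1), 91)
  # constant residual -> every bin equals the constant
  bc <- bin_residuals(matrix(3, 1, 600), times, 120)
  expect_true(all(bc == 3))
  expect_error(bin_residuals(resid, times, 20), class = "session_too_short")
})

test_that("a rank-1 population recovers the shared series with uniform weights", {
  set.seed(8)
  s <- sin(seq(0, 3 * pi, length.out = 40))
  binned <- outer(s, rep(1, 15)) + matrix(rnorm(600, sd = 1e-4), 40)
  d <- compute_drift(binned)
  expect_gte(abs(cor(d$drift, s)), 0.999)
  expect_true(all(d$weights > 0))
  expect_lt(diff(range(d$weights)), 0.01)
  expect_gt(d$variance_explained, 0.999)
})

test_that("output does not depend on the SVD's arbitrary sign choice", {
  set.seed(9)
  binned <- matrix(rnorm(80), 10, 8)
  d <- compute_drift(binned)
  # independent oracle: PC1 via eigen decomposition, aligned by the same rule
  xc <- sweep(binned, 2, colMeans(binned))
  ev <- eigen(crossprod(xc))
  w <- ev$vectors[, 1]
  if (sum(w < 0) > sum(w >= 0)) w <- -w
  expect_equal(abs(as.numeric(xc %*% w)), abs(d$drift), tolerance = 1e-8)
  expect_equal(abs(w), abs(d$weights), tolerance = 1e-8)
  # negating the input flips the projection but weights stay majority-positive
  d_neg <- compute_drift(-binned)
  expect_equal(d_neg$weights, d$weights, tolerance = 1e-8)
  expect_equal(d_neg$drift, -d$drift, tolerance = 1e-8)
  expect_lt(sum(d$weights < 0), sum(d$weights >= 0))
})

test_that("drift is invariant to neuron order and PC1 is variance-optimal", {
  set.seed(10)
  binned <- matrix(rnorm(120), 12, 10)
  d <- compute_drift(binned)
  perm <- sample(10)
  d_perm <- compute_drift(binned[, perm])
  expect_equal(abs(d_perm$drift), abs(d$drift), tolerance = 1e-10)
  expect_equal(abs(d_perm$weights), abs(d$weights[perm]), tolerance = 1e-10)
  # no random direction explains more variance than PC1
  xc <- sweep(binned, 2, colMeans(binned))
  total <- sum(xc^2)
  shares <- vapply(1:200, function(i) {
    u <- rnorm(10); u <- u / sqrt(sum(u^2))
    sum((xc %*% u)^2) / total
  }, numeric(1))
  expect_true(all(shares <= d$variance_explained + 1e-12))
  expect_true(d$variance_explained >= 0 && d$variance_explained <= 1)
  expect_equal(sum(d$weights^2), 1, tolerance = 1e-12)
})

test_that("degenerate inputs and ties are handled deterministically", {
  expect_error(compute_drift(matrix(2, 5, 3)), class = "degenerate_input")
  expect_error(compute_drift(matrix(1, 1, 3)), class = "invalid_parameter")
  # even split: flip so the weight sum is nonnegative
  xc <- cbind(c(-1, 0, 1, 0, -1, 1), c(-0.5, 0.1, 0.4, 0, -0.4, 0.4))
  d <- compute_drift(xc)
  if (sum(d$weights != 0) == 2 && sum(d$weights < 0) == 1) {
    expect_gte(sum(d$weights), 0)
  }
})

test_that("drift recovers the generating latent on a coupled session", {
  s <- local({
    cfg <- synth_config(session_duration = 60, latent_timescale_sd = 15,
                        n_neurons = 30, eeg_rate = 250, eye_rate = 250)
    lat <- generate_arousal_latent(60, 15, seed = 21)
    evs <- generate_events(cfg, lat, seed = 22)
    spk <- generate_spikes(lat, evs, cfg, seed = 23)
    resid <- residual_counts(spk$counts, spk$orientations)
    b <- bin_residuals(resid, spk$onsets, 60)
    list(drift = compute_drift(b), lat = lat, centers = attr(b, "bin_centers"))
  })
  lat_b <- approx(s$lat$time_s / 60, s$lat$value, xout = s$centers)$y
  expect_gte(cor(s$drift$drift, lat_b), 0.8)
})
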