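# Shared fixtures, built once per test run.

# Small, fast session configuration used when the test is not about the
# default recording scale: 20-min session, 500-Hz traces, 12 neurons.
quick_cfg <- function(...) {
  synth_config(session_duration = 20, eeg_rate = 500, eye_rate = 500,
               latent_timescale_sd = 6, n_neurons = 12, ...)
}

.shared <- new.env(parent = emptyenv())

# One coupled session at the cohort scale (60 min / 500 Hz), cached across
# test files; used for detector-invariant and alpha-recovery checks.
demo_session <- function() {
  if (is.null(.shared$rec)) {
    .shared$rec <- simulate_session(
      synth_config(session_duration = 60, eeg_rate = 500, eye_rate = 500,
                   latent_timescale_sd = 15),
      seed = 424242)
  }
  .shared$rec
}

demo_analysis <- function() {
  if (is.null(.shared$an)) {
    .shared$an <- analyze_session(demo_session(), seed = 99)
  }
  .shared$an
}

# Ground-truth latent interpolated to bin centers (minutes).
latent_at_bins <- function(rec, centers_min) {
  lat <- rec$ground_truth$latent
  stats::approx(lat$time_s / 60, lat$value, xout = centers_min, rule = 2)$y
}

# Greedy one-to-one matching of detected to true event onsets.
match_onsets <- function(true_onset, det_onset, tol = 0.010) {
  used <- rep(FALSE, length(det_onset))
  tp <- 0L
  for (t in true_onset) {
    d <- abs(det_onset - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  tp
}

# Synthetic eye trace with slow drift plus injected raised-cosine pulses;
# returns the trace and the injected truth. Used by detector unit tests.
inject_pulses <- function(onsets, amplitudes, rate = 500, duration = 60,
                          vpeak = 100 * amplitudes, drift_sd = 0.05,
                          seed = 1) {
  set.seed(seed)
  n <- duration * rate
  smooth2 <- function(z) {
    # double moving average ~ low-pass well below the detection threshold
    z <- stats::filter(z, rep(1 / 150, 150), sides = 2)
    as.numeric(stats::filter(z, rep(1 / 150, 150), sides = 2))
  }
  lp <- smooth2(rnorm(n + 600))[301:(n + 300)]
  drift <- lp / stats::sd(lp) * drift_sd
  vx <- numeric(n)
  for (k in seq_along(onsets)) {
    d <- 2 * amplitudes[k] / vpeak[k]
    m <- max(3L, round(d * rate))
    tt <- (seq_len(m) - 0.5) / m
    v <- vpeak[k] * (1 - cos(2 * pi * tt)) / 2
    v <- v * amplitudes[k] / (sum(v) / rate)
    i0 <- round(onsets[k] * rate) + 1L
    vx[i0:(i0 + m - 1L)] <- vx[i0:(i0 + m - 1L)] + v
  }
  x <- drift + cumsum(vx) / rate
  y <- smooth2(rnorm(n + 600))[301:(n + 300)]
  y <- y / stats::sd(y) * drift_sd
  cbind(x = x, y = as.numeric(y))
}
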