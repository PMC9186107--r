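# Waveform-level synthesis: continuous EEG, eye position and pupil traces.

# Spectral noise synthesis. A Hermitian spectrum with the target amplitude
# envelope is drawn (Gaussian complex coefficients, or random-phase/constant
# magnitude for dense spectra, which is cheaper and spectrally identical in
# expectation), inverse-transformed, and normalized to unit RMS. Two real
# series are obtained from a single FFT by packing one spectrum into the real
# part and the other into the imaginary part.

# amp: amplitude for positive-frequency bins 1..floor(n/2) (bin k = k*rate/n Hz)
herm_spec <- function(n, amp, gaussian = TRUE) {
  nh <- n %/% 2
  nz <- which(amp > 0)
  spec <- complex(length.out = n)
  if (gaussian) {
    z <- complex(real = stats::rnorm(length(nz)),
                 imaginary = stats::rnorm(length(nz)))
    coef <- amp[nz] * z
    rms2 <- 2 * sum(Mod(coef)^2)
  } else {
    ph <- stats::runif(length(nz), 0, 2 * pi)
    z <- complex(real = sqrt(2) * cos(ph), imaginary = sqrt(2) * sin(ph))
    coef <- amp[nz] * z
    rms2 <- 4 * sum(amp[nz]^2) # |z|^2 = 2 exactly for random-phase draws
  }
  spec[1 + nz] <- coef
  if (n %% 2 == 0) spec[nh + 1] <- 0 # drop Nyquist so the pair packs cleanly
  spec[(nh + 2):n] <- Conj(spec[seq(n - nh, 2)])
  # Parseval gives the realized time-domain RMS exactly from the coefficients
  attr(spec, "rms") <- sqrt(rms2) / n
  spec
}

# Inverse-transform one or two Hermitian spectra at once; returns real series
# normalized to unit RMS (using the exact Parseval scale, no extra pass).
ifft_noise <- function(spec_a, spec_b = NULL) {
  n <- length(spec_a)
  if (is.null(spec_b)) {
    x <- Re(stats::fft(spec_a, inverse = TRUE)) / n
    return(list(x / attr(spec_a, "rms")))
  }
  x <- stats::fft(spec_a + 1i * spec_b, inverse = TRUE) / n
  list(Re(x) / attr(spec_a, "rms"), Im(x) / attr(spec_b, "rms"))
}

# Unit-RMS noise with power ~ f^(-exponent), flattened below `flatten_below`
# Hz for stationarity over a 2-h session.
colored_noise <- function(n, rate, exponent, flatten_below = 1) {
  f <- seq_len(n %/% 2) * rate / n
  amp <- pmax(f, flatten_below)^(-exponent / 2)
  ifft_noise(herm_spec(n, amp, gaussian = FALSE))[[1]]
}

# Unit-RMS narrow-band noise: Gaussian spectral envelope centered on `center`
# Hz with SD bw/4 (8-12 Hz band at the defaults).
narrowband_noise <- function(n, rate, center, bw = 4) {
  f <- seq_len(n %/% 2) * rate / n
  amp <- exp(-(f - center)^2 / (2 * (bw / 4)^2))
  amp[amp < 1e-8] <- 0
  ifft_noise(herm_spec(n, amp))[[1]]
}

# Unit-RMS low-pass noise with a smooth rolloff above `cutoff` Hz. Synthesis
# length is padded to a 2/3/5-smooth number (FFT cost is dominated by the
# largest prime factor) and truncated.
lowpass_noise <- function(n, rate, cutoff) {
  m <- stats::nextn(n, c(2, 3, 5))
  f <- seq_len(m %/% 2) * rate / m
  amp <- exp(-(f / cutoff)^6)
  amp[amp < 1e-8] <- 0
  ifft_noise(herm_spec(m, amp))[[1]][seq_len(n)]
}

# Band-limited (< `cutoff` Hz) unit-RMS noise on a coarse grid; used for slow
# fixational drift, pupil noise and oscillation envelopes, where synthesizing
# at 1 kHz would waste work on frequencies that carry no power. Returns the
# coarse series and its time grid; upsample with `upsample()`.
coarse_noise_grid <- function(dur_s, cutoff = 2, oversample = 10) {
  coarse_rate <- cutoff * 2 * oversample
  n <- as.integer(ceiling((dur_s + 2) * coarse_rate))
  x <- lowpass_noise(n, coarse_rate, cutoff)
  list(t = (seq_len(n) - 1) / coarse_rate, x = x / stats::sd(x))
}

upsample <- function(grid_t, grid_x, t_out) {
  stats::approx(grid_t, grid_x, xout = t_out, rule = 2, ties = "ordered")$y
}

coarse_noise <- function(dur_s, rate, t_out, cutoff = 2, oversample = 10) {
  g <- coarse_noise_grid(dur_s, cutoff, oversample)
  upsample(g$t, g$x, t_out)
}

# Raised-cosine saccadic velocity pulse sampled at `rate`; displacement
# integrates to `amplitude` with peak velocity `vpeak` (deg/s).
raised_cosine_pulse <- function(amplitude, vpeak, rate,
                                min_dur = 0.008, max_dur = 0.030) {
  d <- 2 * amplitude / vpeak
  d <- min(max(d, min_dur), max_dur)
  vpeak <- 2 * amplitude / d # re-solve after clamping so displacement is exact
  m <- max(3L, round(d * rate))
  tt <- (seq_len(m) - 0.5) / m
  v <- vpeak * (1 - cos(2 * pi * tt)) / 2
  # rescale so the discrete integral matches the amplitude exactly
  v * amplitude / (sum(v) / rate)
}

# Draw microsaccade onset times: inhomogeneous Poisson (thinning) driven by the
# latent, or exactly n_events uniform times. A 150-ms minimum separation is
# enforced so true events remain distinct under the detector's 100-ms merge.
draw_microsaccade_times <- function(latent, dur_s, config, forbidden = NULL,
                                    min_sep = 0.15) {
  base <- config$base_msaccade_rate
  if (!is.null(config$n_microsaccades)) {
    times <- sort(stats::runif(config$n_microsaccades * 3, 0.5, dur_s - 0.5))
  } else {
    if (base <= 0) return(numeric(0))
    lam <- base * exp(config$msrate_coupling * latent$value)
    lam_max <- max(lam)
    n_cand <- stats::rpois(1, lam_max * dur_s)
    cand <- sort(stats::runif(n_cand, 0, dur_s))
    keep <- stats::runif(n_cand) < latent_at_rate(latent, cand, config) / lam_max
    times <- cand[keep]
  }
  # greedy minimum-separation filter; also avoid task-saccade windows
  kept <- numeric(0)
  last <- -Inf
  for (tm in times) {
    if (tm - last < min_sep) next
    if (!is.null(forbidden) &&
        any(tm > forbidden$start & tm < forbidden$end)) next
    kept <- c(kept, tm)
    last <- tm
    if (!is.null(config$n_microsaccades) &&
        length(kept) >= config$n_microsaccades) break
  }
  kept
}

latent_at_rate <- function(latent, times, config) {
  config$base_msaccade_rate * exp(config$msrate_coupling *
                                    latent_at(latent, times))
}

#' Generate continuous EEG, eye position and pupil traces
#'
#' EEG: each electrode is independent 1/f^chi background noise
#' (`eeg_background_rms` volts RMS) plus narrow-band rhythms projected to the
#' electrodes with random dipolar gains: an 8-12 Hz alpha component whose
#' instantaneous amplitude is `alpha_rms * exp(alpha_coupling * latent(t))` -
#' with a negative coupling, alpha power falls when arousal rises - and
#' arousal-independent nuisance rhythms (`nuisance_bands`) whose power
#' fluctuates slowly on its own. Eye position: slow low-pass fixational
#' drift (SD `eye_drift_sd` deg per axis, < 2 Hz) plus tiny tracker noise,
#' with raised-cosine microsaccade pulses injected at latent-modulated Poisson
#' times (amplitudes uniform in `ms_amplitude_range`, peak velocity
#' `main_sequence_slope * amplitude` with 4% lognormal scatter) and large
#' (> 150 deg/s) task saccades on hit/false-alarm trials. Pupil:
#' `pupil_baseline + pupil_coupling * latent(t)` plus slow noise.
#'
#' @param latent An `arousal_latent` covering the session.
#' @param events Event table from [generate_events()].
#' @param config A [synth_config()].
#' @param seed Optional integer seed.
#' @return List with `eeg` (electrodes x samples matrix, volts), `eye`
#'   (data.frame `x`, `y`, `pupil` at `eye_rate`), and `true_microsaccades`
#'   (data.frame `onset`, `offset`, `amplitude`, `peak_velocity`).
#' @export
generate_eeg_and_eye <- function(latent, events, config, seed = NULL) {
  validate_synth_config(config)
  sd_check(config$eeg_rate >= 100 && config$eye_rate >= 100,
           "invalid_parameter", "sampling rates must be >= 100 Hz")
  dur_s <- attr(events, "duration_s") %||% (config$session_duration * 60)
  with_seed(seed, {
    ne <- config$n_electrodes
    n_eeg <- as.integer(round(dur_s * config$eeg_rate))
    t_eeg <- (seq_len(n_eeg) - 1) / config$eeg_rate
    # The 1/f^chi background is synthesized at 250 Hz (the recorded EEG was
    # low-pass filtered online anyway) and linearly upsampled; the spectral
    # envelope is pre-emphasized by the inverse of the interpolation response
    # sinc^2(f/fs) so the in-band (<= 50 Hz) power law is exact.
    bg_rate <- min(config$eeg_rate, 250)
    n_bg <- as.integer(round(dur_s * bg_rate))
    n_syn <- stats::nextn(n_bg, c(2, 3, 5)) # smooth FFT length, then truncate
    t_bg <- (seq_len(n_bg) - 1) / bg_rate
    f_bg <- seq_len(n_syn %/% 2) * bg_rate / n_syn
    amp_bg <- pmax(f_bg, 1)^(-config$aperiodic_exponent / 2)
    if (bg_rate < config$eeg_rate) {
      xs <- f_bg / bg_rate
      amp_bg <- amp_bg / (sin(pi * xs) / (pi * xs))^2
    }
    # Oscillatory components: alpha (latent-coupled gain) plus nuisance
    # rhythms whose power fluctuates slowly and independently of arousal.
    # Gains are shared across electrodes (brain-wide rhythms); carriers are
    # electrode-independent so average referencing does not cancel them.
    nuis_sd <- min(config$nuisance_timescale_sd, config$session_duration / 2)
    osc <- list()
    if (config$alpha_rms > 0) {
      osc[[length(osc) + 1]] <- list(
        center = config$alpha_center, bw = config$alpha_bw,
        gain_fun = function(t) {
          config$alpha_rms * exp(config$alpha_coupling * latent_at(latent, t))
        })
    }
    for (nb in config$nuisance_bands) {
      if (nb$rms <= 0) next
      nuis <- generate_arousal_latent(dur_s / 60, nuis_sd)
      osc[[length(osc) + 1]] <- list(
        center = nb$center, bw = nb$bw,
        gain_fun = local({
          nl <- nuis; r <- nb$rms
          function(t) r * exp(config$band_gain_sd * latent_at(nl, t))
        }))
    }
    # Build each rhythm once (complex demodulation: a slow complex envelope of
    # half-bandwidth bw/2 multiplies the carrier, with the component's gain
    # applied at the coarse grid) and project it to electrodes with random
    # dipolar gains N(0, 1) - a cortical source reaches every electrode with a
    # different sign/magnitude, so average referencing does not cancel it.
    comps <- lapply(osc, function(o) {
      g_re <- coarse_noise_grid(dur_s, cutoff = o$bw / 2)
      g_im <- coarse_noise_grid(dur_s, cutoff = o$bw / 2)
      env_gain <- o$gain_fun(g_re$t)
      re_up <- upsample(g_re$t, g_re$x * env_gain, t_eeg)
      im_up <- upsample(g_im$t, g_im$x * env_gain, t_eeg)
      re_up * cos(2 * pi * o$center * t_eeg) -
        im_up * sin(2 * pi * o$center * t_eeg)
    })
    w_comp <- matrix(stats::rnorm(ne * length(osc)), nrow = ne)
    eeg <- matrix(0, nrow = ne, ncol = n_eeg)
    for (e in seq(1, ne, by = 2)) {
      # two electrode backgrounds per FFT (Hermitian packing)
      pair <- ifft_noise(herm_spec(n_syn, amp_bg, gaussian = FALSE),
                         herm_spec(n_syn, amp_bg, gaussian = FALSE))
      for (k in 1:2) {
        if (e + k - 1 > ne) break
        bg <- if (bg_rate < config$eeg_rate) {
          upsample(t_bg, pair[[k]][seq_len(n_bg)], t_eeg)
        } else {
          pair[[k]][seq_len(n_eeg)]
        }
        x <- bg * config$eeg_background_rms
        for (j in seq_along(comps)) {
          x <- x + w_comp[e + k - 1, j] * comps[[j]]
        }
        eeg[e + k - 1, ] <- x
      }
    }
    rm(comps)

    # ---- eye traces ----
    n_eye <- as.integer(round(dur_s * config$eye_rate))
    t_eye <- (seq_len(n_eye) - 1) / config$eye_rate
    drift_x <- coarse_noise(dur_s, config$eye_rate, t_eye, cutoff = 2) *
      config$eye_drift_sd
    drift_y <- coarse_noise(dur_s, config$eye_rate, t_eye, cutoff = 2) *
      config$eye_drift_sd

    # task saccades on hit / false-alarm trials (out + return)
    sacc <- events[!is.na(events$saccade_time), , drop = FALSE]
    forbidden <- NULL
    if (nrow(sacc) > 0) {
      forbidden <- data.frame(start = sacc$saccade_time - 0.2,
                              end = sacc$saccade_time + 0.5)
    }
    ms_times <- draw_microsaccade_times(latent, dur_s, config, forbidden)
    n_ms <- length(ms_times)
    amps <- stats::runif(n_ms, config$ms_amplitude_range[1],
                         config$ms_amplitude_range[2])
    vpeaks <- config$main_sequence_slope * amps *
      exp(stats::rnorm(n_ms, sd = 0.04))

    vx <- numeric(n_eye)
    vy <- numeric(n_eye)
    offset_x <- 0
    offset_y <- 0
    true_ms <- vector("list", n_ms)
    for (k in seq_len(n_ms)) {
      pulse <- raised_cosine_pulse(amps[k], vpeaks[k], config$eye_rate)
      i0 <- as.integer(round(ms_times[k] * config$eye_rate)) + 1L
      idx <- i0:(i0 + length(pulse) - 1L)
      if (max(idx) > n_eye) next
      # direction biased back toward fixation so position stays bounded
      theta <- atan2(-offset_y, -offset_x) + stats::rnorm(1, sd = 0.6)
      if (offset_x == 0 && offset_y == 0) theta <- stats::runif(1, 0, 2 * pi)
      vx[idx] <- vx[idx] + pulse * cos(theta)
      vy[idx] <- vy[idx] + pulse * sin(theta)
      offset_x <- offset_x + amps[k] * cos(theta)
      offset_y <- offset_y + amps[k] * sin(theta)
      true_ms[[k]] <- c(onset = ms_times[k],
                        offset = ms_times[k] + length(pulse) / config$eye_rate,
                        amplitude = amps[k], peak_velocity = max(pulse))
    }
    if (nrow(sacc) > 0) {
      for (k in seq_len(nrow(sacc))) {
        amp <- stats::runif(1, 5, 7)
        vp <- 50 * amp
        pulse <- raised_cosine_pulse(amp, vp, config$eye_rate,
                                     min_dur = 0.03, max_dur = 0.06)
        theta <- stats::runif(1, 0, 2 * pi)
        for (leg in c(0, 0.25)) { # outward saccade then return to fixation
          i0 <- as.integer(round((sacc$saccade_time[k] + leg) *
                                   config$eye_rate)) + 1L
          idx <- i0:(i0 + length(pulse) - 1L)
          if (max(idx) > n_eye) next
          sgn <- if (leg == 0) 1 else -1
          vx[idx] <- vx[idx] + sgn * pulse * cos(theta)
          vy[idx] <- vy[idx] + sgn * pulse * sin(theta)
        }
      }
    }
    x <- drift_x + cumsum(vx) / config$eye_rate +
      stats::rnorm(n_eye, sd = 5e-4)
    y <- drift_y + cumsum(vy) / config$eye_rate +
      stats::rnorm(n_eye, sd = 5e-4)

    pupil_noise <- coarse_noise(dur_s, config$eye_rate, t_eye, 0.5) * 0.1
    pupil <- config$pupil_baseline +
      config$pupil_coupling * latent_at(latent, t_eye) + pupil_noise
    pupil <- pmax(pupil, 0.01)

    true_ms <- do.call(rbind, true_ms)
    true_ms <- if (is.null(true_ms)) {
      data.frame(onset = numeric(0), offset = numeric(0),
                 amplitude = numeric(0), peak_velocity = numeric(0))
    } else {
      as.data.frame(true_ms)
    }
    list(eeg = eeg,
         eye = data.frame(x = x, y = y, pupil = pupil),
         true_microsaccades = true_ms)
  })
}
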