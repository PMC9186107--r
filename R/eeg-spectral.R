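# Prestimulus EEG spectral pipeline: segment extraction, artifact screening,
# Hanning FFT power, sliding-window binning, aperiodic (1/f) removal and band
# power.

hanning_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' Extract 300-ms prestimulus EEG segments
#'
#' The EEG is first rereferenced to the session-wide average across electrodes,
#' then one segment is cut from the first 300 ms of every prestimulus period
#' except each trial's initial fixation (eye position is still settling there).
#' A constant 300-ms duration is required by the aperiodic fit downstream.
#'
#' @param rec A `session_recording`.
#' @param segment_ms Segment duration, ms (default 300).
#' @return Object of class `eeg_segments`: list with `data` (electrodes x
#'   samples x segments array, volts), `onsets` (s), `rate`.
#' @export
extract_segments <- function(rec, segment_ms = 300) {
  validate_session_recording(rec)
  eeg <- rec$eeg - rep(colMeans(rec$eeg), each = nrow(rec$eeg))
  rate <- rec$eeg_rate
  nsamp <- as.integer(round(segment_ms / 1000 * rate))
  ev <- rec$events
  pre <- ev[ev$period_type == "prestimulus" & !ev$is_initial, , drop = FALSE]
  keep <- logical(nrow(pre))
  segs <- vector("list", nrow(pre))
  for (i in seq_len(nrow(pre))) {
    i0 <- as.integer(round(pre$onset[i] * rate)) + 1L
    i1 <- i0 + nsamp - 1L
    if (i1 > ncol(eeg)) {
      warning(sprintf("EEG does not cover prestimulus period at %.1f s; skipped",
                      pre$onset[i]))
      next
    }
    segs[[i]] <- eeg[, i0:i1, drop = FALSE]
    keep[i] <- TRUE
  }
  data <- array(unlist(segs[keep]),
                dim = c(nrow(eeg), nsamp, sum(keep)))
  structure(list(data = data, onsets = pre$onset[keep],
                 period_duration = pre$duration[keep], rate = rate),
            class = "eeg_segments")
}

#' Screen EEG segments for artifacts
#'
#' Three rejection rules, each computed from session-level statistics taken
#' over all segments before any rejection (so a segment's fate is independent
#' of other segments' fates): (1) any electrode's within-segment SD exceeds 10
#' times that electrode's session-mean within-segment SD; (2) any electrode is
#' flat (SD < 300 nV); (3) the within-period SD of 1-D eye speed exceeds twice
#' the session-mean eye speed over all prestimulus periods (removing segments
#' contaminated by eye movements, including those containing microsaccades).
#'
#' @param segments An `eeg_segments` object.
#' @param rec The source `session_recording` (for the eye trace).
#' @param speed Optional precomputed 1-D eye speed (deg/s) at the eye rate.
#' @return An `eeg_segments` object restricted to kept segments, with the
#'   per-segment rejection log in attribute `"screen_log"` (data.frame with
#'   logical columns `rule_amplitude`, `rule_flat`, `rule_eye`, `kept`).
#' @export
screen_segments <- function(segments, rec, speed = NULL) {
  sd_check(length(segments$onsets) > 0, "empty_input", "no segments to screen")
  d <- segments$data
  n_seg <- dim(d)[3]
  ne <- dim(d)[1]
  ns <- dim(d)[2]
  # electrodes x segments SD matrix (vectorized over the flattened array)
  m <- matrix(aperm(d, c(2, 1, 3)), nrow = ns)
  sds <- matrix(sqrt(pmax(colSums(m^2) - colSums(m)^2 / ns, 0) / (ns - 1)),
                nrow = ne)
  rm(m)
  mean_sd <- rowMeans(sds)
  rule_amplitude <- apply(sds > 10 * mean_sd, 2, any)
  rule_flat <- apply(sds < 300e-9, 2, any)

  if (is.null(speed)) {
    v <- compute_velocity(rec$eye, rec$eye_rate)
    speed <- sqrt(v[, 1]^2 + v[, 2]^2)
  }
  ev <- rec$events
  pre_all <- ev[ev$period_type == "prestimulus", , drop = FALSE]
  idx_of <- function(onset, duration) {
    i0 <- floor(onset * rec$eye_rate) + 1
    i1 <- min(floor((onset + duration) * rec$eye_rate), length(speed))
    i0:i1
  }
  all_speed <- unlist(lapply(seq_len(nrow(pre_all)), function(i) {
    speed[idx_of(pre_all$onset[i], pre_all$duration[i])]
  }))
  mean_speed <- mean(all_speed)
  rule_eye <- vapply(seq_len(n_seg), function(i) {
    stats::sd(speed[idx_of(segments$onsets[i],
                           segments$period_duration[i])]) > 2 * mean_speed
  }, logical(1))

  kept <- !(rule_amplitude | rule_flat | rule_eye)
  sd_check(any(kept), "empty_output", "all EEG segments were rejected")
  log <- data.frame(onset = segments$onsets,
                    rule_amplitude = rule_amplitude, rule_flat = rule_flat,
                    rule_eye = rule_eye, kept = kept)
  out <- structure(list(data = segments$data[, , kept, drop = FALSE],
                        onsets = segments$onsets[kept],
                        period_duration = segments$period_duration[kept],
                        rate = segments$rate),
                   class = "eeg_segments")
  attr(out, "screen_log") <- log
  out
}

#' Power spectrum of one EEG segment
#'
#' Each electrode's 300-ms segment is Hanning-windowed, zero-padded to 1 s
#' (giving a 1-Hz analysis grid, needed for the 4-Hz sliding-frequency scan)
#' and Fourier transformed; power is `|X_k|^2 / N`, so the sum of power over
#' the full grid equals the windowed-signal energy (Parseval). Frequencies
#' 1-50 Hz are retained unless `full = TRUE`.
#'
#' @param segment Electrodes x samples matrix (volts).
#' @param rate Sampling rate, Hz.
#' @param fmax Highest retained frequency, Hz.
#' @param full Return the full DFT grid instead of 1-`fmax` Hz.
#' @return Electrodes x frequencies power matrix with attribute `"freq"` (Hz).
#' @export
segment_spectrum <- function(segment, rate, fmax = 50, full = FALSE) {
  segment <- as.matrix(segment)
  sd_check(!anyNA(segment), "invalid_input", "segment contains NA samples")
  n <- ncol(segment)
  npad <- as.integer(rate) # zero-pad to 1 s
  w <- hanning_window(n)
  xw <- segment * rep(w, each = nrow(segment))
  padded <- cbind(xw, matrix(0, nrow(segment), npad - n))
  sp <- t(stats::mvfft(t(padded)))
  power <- Mod(sp)^2 / npad
  freq_all <- (seq_len(npad) - 1) * rate / npad
  if (full) {
    attr(power, "freq") <- freq_all
    return(power)
  }
  keep <- freq_all >= 1 & freq_all <= fmax
  out <- power[, keep, drop = FALSE]
  attr(out, "freq") <- freq_all[keep]
  out
}

# Batch power for all segments on the 1-50 Hz grid via a direct DFT basis
# (equivalent to zero-padded FFT, but only the needed bins are evaluated).
segment_power_batch <- function(segments, fmax = 50) {
  d <- segments$data
  ne <- dim(d)[1]; ns <- dim(d)[2]; nseg <- dim(d)[3]
  rate <- segments$rate
  npad <- as.integer(rate)
  freqs <- seq_len(fmax)
  w <- hanning_window(ns)
  # flatten to samples x (electrode*segment)
  x <- matrix(aperm(d, c(2, 1, 3)), nrow = ns) * w
  ang <- -2 * pi * outer(freqs, (0:(ns - 1))) / npad
  re <- cos(ang) %*% x
  im <- sin(ang) %*% x
  p <- (re^2 + im^2) / npad
  structure(list(power = array(p, dim = c(length(freqs), ne, nseg)),
                 freq = freqs, onsets = segments$onsets, rate = rate),
            class = "segment_power")
}

#' Bin per-segment spectra with a sliding window
#'
#' @param power A `segment_power` object from [segment_power_batch()] (also
#'   accepted: an `eeg_segments` object, which is transformed first).
#' @param duration_min Session duration, minutes.
#' @param window,step Bin geometry, minutes (defaults 30 / 6; the timescale
#'   analysis uses `step = 1`).
#' @param min_segments Bins with fewer segments are dropped (default 10).
#' @return Object of class `binned_spectra`: `power` (freq x electrode x bin
#'   array of mean spectra), `freq`, `bin_centers` (min), `n_segments`.
#' @export
bin_spectra <- function(power, duration_min, window = 30, step = 6,
                        min_segments = 10) {
  if (inherits(power, "eeg_segments")) power <- segment_power_batch(power)
  bins <- sliding_bins(duration_min, window, step)
  t_min <- power$onsets / 60
  keep <- logical(nrow(bins))
  out <- vector("list", nrow(bins))
  counts <- integer(nrow(bins))
  for (i in seq_len(nrow(bins))) {
    in_bin <- t_min >= bins$start_min[i] & t_min < bins$end_min[i]
    counts[i] <- sum(in_bin)
    if (counts[i] < min_segments) next
    keep[i] <- TRUE
    out[[i]] <- rowMeans(power$power[, , in_bin, drop = FALSE], dims = 2)
  }
  sd_check(any(keep), "empty_output", "no bin reached min_segments")
  arr <- array(unlist(out[keep]),
               dim = c(length(power$freq), dim(power$power)[2], sum(keep)))
  structure(list(power = arr, freq = power$freq,
                 bin_centers = bins$center_min[keep],
                 n_segments = counts[keep]),
            class = "binned_spectra")
}

#' Remove the aperiodic (1/f) component from binned spectra
#'
#' For every bin and electrode the aperiodic background is fit as
#' `log10 P(f) = c - chi * log10 f` by least squares over 3-50 Hz, excluding
#' 7-14 Hz so the alpha peak does not bias the fit; the residual is
#' `P(f) - 10^(c - chi log10 f)`. Residuals are averaged across electrodes
#' *after* subtraction, so electrode-specific backgrounds are removed first.
#'
#' @param binned A `binned_spectra` object.
#' @param fit_range Frequency range of the fit, Hz (default c(3, 50)).
#' @param guard Frequencies excluded from the fit, Hz (default c(7, 14)).
#' @return Object of class `residual_spectrum_set`: `residual` (bins x
#'   frequencies matrix, electrode-averaged), `freq`, `bin_centers`,
#'   `fits` (per bin/electrode offset and exponent), `n_segments`.
#' @export
remove_aperiodic <- function(binned, fit_range = c(3, 50), guard = c(7, 14)) {
  f <- binned$freq
  fit_idx <- which(f >= fit_range[1] & f <= fit_range[2] &
                     !(f >= guard[1] & f <= guard[2]))
  ne <- dim(binned$power)[2]
  nb <- dim(binned$power)[3]
  lf <- log10(f[fit_idx])
  X <- cbind(1, lf)
  XtXi_Xt <- solve(crossprod(X), t(X))
  resid <- matrix(0, nb, length(f))
  fits <- vector("list", nb * ne)
  for (b in seq_len(nb)) {
    rb <- matrix(0, ne, length(f))
    for (e in seq_len(ne)) {
      p <- binned$power[, e, b]
      if (any(p[fit_idx] <= 0)) {
        sd_stop("invalid_input",
                "nonpositive power in fit range (bin %d, electrode %d)", b, e)
      }
      beta <- XtXi_Xt %*% log10(p[fit_idx])
      ap <- 10^(beta[1] + beta[2] * log10(f))
      rb[e, ] <- p - ap
      fits[[(b - 1) * ne + e]] <- data.frame(
        bin = b, electrode = e, offset = beta[1], exponent = -beta[2])
    }
    resid[b, ] <- colMeans(rb)
  }
  structure(list(residual = resid, freq = f,
                 bin_centers = binned$bin_centers,
                 fits = do.call(rbind, fits),
                 n_segments = binned$n_segments),
            class = "residual_spectrum_set")
}

#' Residual band power per time bin
#'
#' Mean residual power over grid frequencies in the half-open interval
#' `[lo, hi)`. Canonical bands: theta 4-8, alpha 8-12, beta 12-30,
#' gamma 30-50 Hz.
#'
#' @param resset A `residual_spectrum_set`.
#' @param band Numeric `c(lo, hi)` in Hz.
#' @return Binned series data.frame (`bin_center_min`, `value`, `n`).
#' @export
band_power <- function(resset, band = c(8, 12)) {
  idx <- which(resset$freq >= band[1] & resset$freq < band[2])
  sd_check(length(idx) > 0, "invalid_parameter",
           "band [%g, %g) contains no grid frequencies", band[1], band[2])
  data.frame(bin_center_min = resset$bin_centers,
             value = rowMeans(resset$residual[, idx, drop = FALSE]),
             n = resset$n_segments)
}

#' Sliding 4-Hz band-power scan
#'
#' [band_power()] applied to half-open 4-Hz windows stepped every 2 Hz; list
#' names give the window's left edge (2 to 46 Hz, 23 windows). The window with
#' left edge 8 reproduces the canonical alpha band exactly.
#'
#' @param resset A `residual_spectrum_set`.
#' @param width,step Window width and step, Hz.
#' @param edges Optional explicit left edges, Hz.
#' @return Named list of binned series.
#' @export
sliding_band_power <- function(resset, width = 4, step = 2, edges = NULL) {
  if (is.null(edges)) edges <- seq(2, 46, by = step)
  out <- lapply(edges, function(lo) band_power(resset, c(lo, lo + width)))
  names(out) <- as.character(edges)
  out
}

#' Canonical frequency bands
#' @return Named list of `c(lo, hi)` band edges in Hz.
#' @export
canonical_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30), gamma = c(30, 50))
}
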