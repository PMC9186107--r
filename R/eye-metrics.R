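#' Eye velocity via a 5-point central difference
#'
#' `v_t = rate * (x_{t+2} + x_{t+1} - x_{t-1} - x_{t-2}) / 6` per component.
#' The stencil implicitly smooths over 5 samples, which is the standard
#' companion to median-based velocity thresholding (raw differencing would
#' inflate the noise estimate). The first/last two samples are padded with the
#' nearest interior velocity.
#'
#' @param eye Matrix or data.frame whose first two columns are x/y position in
#'   degrees.
#' @param rate Sampling rate, Hz.
#' @return n x 2 matrix of velocities (deg/s).
#' @export
compute_velocity <- function(eye, rate) {
  pos <- as.matrix(eye[, 1:2, drop = FALSE])
  n <- nrow(pos)
  sd_check(n >= 5, "too_short", "need at least 5 samples to compute velocity")
  v <- matrix(0, n, 2)
  for (k in 1:2) {
    x <- pos[, k]
    core <- rate * (x[5:n] + x[4:(n - 1)] - x[2:(n - 3)] - x[1:(n - 4)]) / 6
    v[, k] <- c(core[1], core[1], core, core[length(core)],
                core[length(core)])
  }
  colnames(v) <- c("vx", "vy")
  v
}

#' Detect microsaccades with a median-based velocity threshold
#'
#' Component thresholds use the robust estimator
#' `sigma_k = sqrt(median(v_k^2) - median(v_k)^2)`; samples satisfying the
#' elliptic criterion `(v_x / (lambda sigma_x))^2 + (v_y / (lambda sigma_y))^2 > 1`
#' with `lambda = 6` are candidates. Runs of at least 6 ms become events;
#' events separated by less than 100 ms are merged into a single event spanning
#' both; amplitude is the Euclidean displacement between onset and offset
#' positions; finally events with amplitude > 1 degree or peak velocity
#' > 100 deg/s are removed (they are regular saccades, not microsaccades).
#'
#' @param eye Matrix/data.frame with x/y position (deg) in the first two
#'   columns.
#' @param rate Sampling rate, Hz.
#' @param lambda Threshold multiplier (default 6).
#' @param min_duration Minimum event duration, s (default 0.006).
#' @param min_separation Events closer than this are merged, s (default 0.1).
#' @param max_amplitude,max_velocity Exclusion bounds (1 deg, 100 deg/s).
#' @param velocity Optional precomputed velocity from [compute_velocity()]
#'   (avoids recomputation when several stages share it).
#' @return Data.frame with `onset`, `offset` (s), `amplitude` (deg),
#'   `peak_velocity` (deg/s); zero rows if nothing crosses threshold.
#' @export
detect_microsaccades <- function(eye, rate, lambda = 6,
                                 min_duration = 0.006, min_separation = 0.1,
                                 max_amplitude = 1, max_velocity = 100,
                                 velocity = NULL) {
  pos <- as.matrix(eye[, 1:2, drop = FALSE])
  v <- velocity %||% compute_velocity(pos, rate)
  sd_check(all(is.finite(v)), "invalid_input", "velocity must be finite")
  sig <- sqrt(pmax(apply(v, 2, function(k) {
    stats::median(k^2) - stats::median(k)^2
  }), 0))
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0))
  if (any(sig == 0)) {
    warning("degenerate (flat) eye trace: velocity SD is zero; no events")
    return(empty)
  }
  crit <- (v[, 1] / (lambda * sig[1]))^2 + (v[, 2] / (lambda * sig[2]))^2 > 1
  r <- rle(crit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= ceiling(min_duration * rate)
  if (!any(keep)) return(empty)
  on_idx <- starts[keep]
  off_idx <- ends[keep]
  # merge events separated by < min_separation into one spanning event
  gap_s <- (on_idx[-1] - off_idx[-length(off_idx)]) / rate
  grp <- cumsum(c(1, gap_s >= min_separation))
  on_idx <- tapply(on_idx, grp, min)
  off_idx <- tapply(off_idx, grp, max)
  speed <- sqrt(v[, 1]^2 + v[, 2]^2)
  amplitude <- sqrt((pos[off_idx, 1] - pos[on_idx, 1])^2 +
                      (pos[off_idx, 2] - pos[on_idx, 2])^2)
  peak_velocity <- mapply(function(a, b) max(speed[a:b]), on_idx, off_idx)
  # half-open event interval: a run of k suprathreshold samples lasts k/rate
  out <- data.frame(onset = (on_idx - 1) / rate,
                    offset = off_idx / rate,
                    amplitude = as.numeric(amplitude),
                    peak_velocity = as.numeric(peak_velocity))
  out <- out[out$amplitude <= max_amplitude &
               out$peak_velocity <= max_velocity, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Main-sequence correlation of detected microsaccades
#'
#' Pearson correlation between amplitude and peak velocity; values near 1
#' indicate that detected events fall on the stereotyped saccadic main
#' sequence, validating the detector.
#'
#' @param events Data.frame from [detect_microsaccades()].
#' @return Pearson r.
#' @export
main_sequence_correlation <- function(events) {
  sd_check(nrow(events) >= 3, "insufficient_data",
           "need at least 3 events for a main-sequence correlation")
  stats::cor(events$amplitude, events$peak_velocity)
}

#' Per-period eye and behavioral metrics
#'
#' Microsaccade rate (events/s) per non-initial prestimulus period - the
#' initial fixation of each trial is excluded because eye position is still
#' settling there; mean pupil diameter per 400-ms stimulus period; and, on hit
#' trials only, reaction time (from the orientation change to the first
#' 150 deg/s crossing of eye speed) and the peak velocity of that saccade.
#'
#' @param rec A `session_recording`.
#' @param events Detected microsaccades from [detect_microsaccades()].
#' @param rt_threshold Saccade-onset speed threshold, deg/s (default 150).
#' @param speed Optional precomputed 1-D eye speed (deg/s) at the eye rate.
#' @return List of data.frames `msrate`, `pupil`, `rt`, `sacc_vel`, each with
#'   columns `time_s`, `value` (empty when no qualifying periods exist).
#' @export
per_period_metrics <- function(rec, events, rt_threshold = 150, speed = NULL) {
  ev <- rec$events
  rate <- rec$eye_rate
  pre <- ev[ev$period_type == "prestimulus" & !ev$is_initial, , drop = FALSE]
  ms_count <- vapply(seq_len(nrow(pre)), function(i) {
    sum(events$onset >= pre$onset[i] &
          events$onset < pre$onset[i] + pre$duration[i])
  }, numeric(1))
  msrate <- data.frame(time_s = pre$onset, value = ms_count / pre$duration)

  stim <- ev[ev$period_type == "stimulus", , drop = FALSE]
  pupil_trace <- rec$eye$pupil
  pupil <- data.frame(time_s = stim$onset,
                      value = vapply(seq_len(nrow(stim)), function(i) {
                        i0 <- floor(stim$onset[i] * rate) + 1
                        i1 <- min(floor((stim$onset[i] + stim$duration[i]) *
                                          rate), length(pupil_trace))
                        mean(pupil_trace[i0:i1])
                      }, numeric(1)))

  hits <- ev[!is.na(ev$outcome) & ev$outcome == "hit", , drop = FALSE]
  rt <- data.frame(time_s = numeric(0), value = numeric(0))
  sacc_vel <- data.frame(time_s = numeric(0), value = numeric(0))
  if (nrow(hits) > 0) {
    if (is.null(speed)) {
      v <- compute_velocity(rec$eye, rate)
      speed <- sqrt(v[, 1]^2 + v[, 2]^2)
    }
    for (i in seq_len(nrow(hits))) {
      ct <- hits$change_time[i]
      i0 <- floor(ct * rate) + 1
      i1 <- min(floor((ct + 0.45) * rate), length(speed))
      if (i0 >= i1) next
      cross <- which(speed[i0:i1] >= rt_threshold)
      if (length(cross) == 0) next
      t_cross <- (i0 + cross[1] - 2) / rate
      rt <- rbind(rt, data.frame(time_s = ct, value = t_cross - ct))
      j1 <- min(floor((t_cross + 0.08) * rate), length(speed))
      sacc_vel <- rbind(sacc_vel,
                       data.frame(time_s = ct,
                                  value = max(speed[(i0 + cross[1] - 1):j1])))
    }
  }
  list(msrate = msrate, pupil = pupil, rt = rt, sacc_vel = sacc_vel)
}
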