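#' Simulate a complete synthetic session
#'
#' Draws the slow arousal latent, the trial/period event table, population
#' spike counts, and (in `"full"` fidelity) continuous EEG, eye-position and
#' pupil traces. Ground truth (latent, neuron loadings, true microsaccade
#' list, per-prestimulus alpha gain) is attached so downstream stages can be
#' validated against what generated the data.
#'
#' The `"summary"` fidelity samples the identical statistical model at the
#' period level - per-segment alpha band power (lognormal segment noise on the
#' latent-modulated gain), per-stimulus pupil means, Poisson per-period
#' microsaccade counts, and the same spike-count model - without synthesizing
#' 1-kHz waveforms. It exists for large replicate-cohort statistics where only
#' the binned metric series matter; it exercises binning, slow-drift
#' extraction and all session-level statistics, but not the detector or the
#' spectral stages.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed (overrides `config$seed`).
#' @param fidelity `"full"` (waveforms) or `"summary"` (period-level metrics).
#' @return An object of class `session_recording` (full) or `session_summary`.
#' @export
simulate_session <- function(config = synth_config(), seed = NULL,
                             fidelity = c("full", "summary")) {
  fidelity <- match.arg(fidelity)
  validate_synth_config(config)
  seed <- seed %||% config$seed
  seeds <- derive_seeds(seed, 5)
  latent <- generate_arousal_latent(config$session_duration,
                                    config$latent_timescale_sd,
                                    seed = seeds[[1]])
  events <- generate_events(config, latent, seed = seeds[[2]])
  spk <- generate_spikes(latent, events, config, seed = seeds[[3]])
  pre <- events$period_type == "prestimulus"
  ground_truth <- list(
    latent = latent,
    neuron_loadings = spk$loadings,
    alpha_gain = exp(config$alpha_coupling *
                       latent_at(latent, events$onset[pre])),
    true_microsaccades = NULL)

  if (fidelity == "full") {
    sig <- generate_eeg_and_eye(latent, events, config, seed = seeds[[4]])
    ground_truth$true_microsaccades <- sig$true_microsaccades
    rec <- session_recording(
      session_id = "synthetic",
      subject_id = "synthetic",
      spike_counts = spk$counts,
      orientations = spk$orientations,
      eeg = sig$eeg, eeg_rate = config$eeg_rate,
      eye = sig$eye, eye_rate = config$eye_rate,
      events = events,
      ground_truth = ground_truth)
    return(rec)
  }

  # period-level fidelity
  with_seed(seeds[[4]], {
    seg <- events[pre & !events$is_initial, , drop = FALSE]
    lat_seg <- latent_at(latent, seg$onset)
    alpha_power <- (config$alpha_rms * exp(config$alpha_coupling * lat_seg))^2 *
      stats::rlnorm(nrow(seg), sdlog = 0.6)
    ms_counts <- stats::rpois(nrow(seg),
                              seg$duration * config$base_msaccade_rate *
                                exp(config$msrate_coupling * lat_seg))
    stim <- events[events$period_type == "stimulus", , drop = FALSE]
    pupil <- config$pupil_baseline +
      config$pupil_coupling * latent_at(latent, stim$onset) +
      stats::rnorm(nrow(stim), sd = 0.1)
    structure(list(
      session_id = "synthetic", subject_id = "synthetic",
      events = events,
      spike_counts = spk$counts, orientations = spk$orientations,
      spike_onsets = spk$onsets,
      segment_onsets = seg$onset,
      segment_alpha_power = alpha_power,
      segment_ms_counts = ms_counts, segment_durations = seg$duration,
      stim_onsets = stim$onset, stim_pupil = pupil,
      duration_s = attr(events, "duration_s"),
      ground_truth = ground_truth), class = "session_summary")
  })
}

#' Construct and validate a session recording
#'
#' Container for one session's multimodal data: spike counts per stimulus
#' period with orientation labels, multi-electrode EEG, monocular eye trace
#' with pupil diameter, and the trial/period event table.
#'
#' @param session_id,subject_id Identifier strings.
#' @param spike_counts Integer matrix, neurons x stimulus periods.
#' @param orientations Orientation label (45/135) per stimulus period.
#' @param eeg Numeric matrix, electrodes x samples (volts).
#' @param eeg_rate,eye_rate Sampling rates, Hz.
#' @param eye Data.frame with columns `x`, `y` (deg) and `pupil`.
#' @param events Event table (see [generate_events()] for the schema).
#' @param ground_truth Optional list of generator ground truth.
#' @return A validated object of class `session_recording`.
#' @export
session_recording <- function(session_id, subject_id, spike_counts,
                              orientations, eeg, eeg_rate, eye, eye_rate,
                              events, ground_truth = NULL) {
  rec <- structure(list(
    session_id = session_id, subject_id = subject_id,
    spike_counts = spike_counts, orientations = orientations,
    eeg = eeg, eeg_rate = eeg_rate, eye = eye, eye_rate = eye_rate,
    events = events,
    duration_s = attr(events, "duration_s") %||%
      (ncol(eeg) / eeg_rate),
    ground_truth = ground_truth), class = "session_recording")
  validate_session_recording(rec)
  rec
}

validate_session_recording <- function(rec) {
  required <- c("session_id", "subject_id", "spike_counts", "orientations",
                "eeg", "eeg_rate", "eye", "eye_rate", "events")
  for (f in required) {
    sd_check(!is.null(rec[[f]]), "schema_error", "missing field: %s", f)
  }
  sd_check(rec$eeg_rate > 0 && rec$eye_rate > 0, "validation_error",
           "sampling rates must be positive")
  sd_check(all(rec$spike_counts >= 0), "validation_error",
           "spike counts must be nonnegative")
  sd_check(ncol(rec$spike_counts) == length(rec$orientations),
           "validation_error",
           "one orientation label per stimulus period is required")
  sd_check(all(rec$orientations %in% c(45, 135)), "validation_error",
           "orientations must be 45 or 135")
  sd_check(nrow(rec$eeg) >= 2, "validation_error",
           "at least 2 EEG electrodes are required")
  ev <- rec$events
  sd_check(all(diff(ev$onset) >= 0), "validation_error",
           "event periods must be time-ordered")
  ends <- ev$onset + ev$duration
  sd_check(all(ev$onset[-1] - ends[-length(ends)] > -1e-9),
           "validation_error", "event periods must not overlap")
  span <- max(ends)
  sd_check(ncol(rec$eeg) / rec$eeg_rate >= span - 1e-6, "validation_error",
           "EEG does not cover all event times")
  sd_check(nrow(rec$eye) / rec$eye_rate >= span - 1e-6, "validation_error",
           "eye trace does not cover all event times")
  invisible(rec)
}
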