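#' Configuration for the synthetic-session generator
#'
#' The generator emulates a ~2-h change-detection session in which a single
#' slow arousal latent (standardized, Gaussian-smoothed noise with a
#' `latent_timescale_sd`-minute smoothing SD) simultaneously (1) scales
#' per-neuron firing through majority-positive loadings, (2) inversely
#' modulates narrow-band 8-12 Hz EEG power riding on a 1/f^chi background,
#' (3) positively drives pupil diameter, and (4) inversely drives Poisson
#' microsaccade occurrence with a main-sequence amplitude-velocity law.
#' Defaults mirror the recorded sessions the pipeline is designed for:
#' 1-kHz EEG and eye traces, 8 scalp electrodes, 400-ms stimulus periods
#' separated by 300-500 ms fixation periods, and a V4-sized population of
#' ~40 neurons.
#'
#' Coupling signs follow the arousal interpretation: `alpha_coupling < 0`
#' (alpha power falls as arousal rises), `pupil_coupling > 0`,
#' `msrate_coupling < 0`, `drift_coupling > 0` (majority-positive loadings), and
#' `fa_coupling > 0` (more impulsive false alarms at high arousal).
#'
#' @param session_duration Session length, minutes.
#' @param n_neurons Number of simultaneously recorded neurons.
#' @param n_electrodes Number of scalp electrodes (>= 2).
#' @param eeg_rate,eye_rate Sampling rates, Hz.
#' @param prestimulus_range Uniform range of fixation-period durations, ms.
#' @param stimulus_duration Stimulus-period duration, ms.
#' @param latent_timescale_sd Smoothing SD of the arousal latent, minutes.
#' @param aperiodic_exponent Exponent chi of the 1/f^chi EEG background.
#' @param alpha_center Center frequency of the alpha oscillation, Hz.
#' @param alpha_coupling,pupil_coupling,msrate_coupling,drift_coupling,hit_coupling,fa_coupling
#'   Signed effect sizes of the latent on each modality.
#' @param base_msaccade_rate Baseline microsaccade rate, events/s.
#' @param main_sequence_slope Peak-velocity/amplitude slope, (deg/s)/deg.
#' @param ms_amplitude_range Uniform range of microsaccade amplitudes, deg.
#' @param n_microsaccades If non-NULL, draw exactly this many microsaccades
#'   (uniform in time, minimum separation enforced) instead of a Poisson
#'   process; used for detector-recovery experiments.
#' @param positive_fraction Fraction of neurons given positive latent loadings.
#' @param base_count_range Uniform range of baseline spike counts per 400-ms
#'   stimulus period.
#' @param tuning_sd SD of per-neuron log-scale orientation tuning.
#' @param p_change Probability a stimulus period contains an orientation change.
#' @param p_hit Baseline hit probability given a change.
#' @param p_fa Baseline false-alarm probability per unchanged stimulus.
#' @param eeg_background_rms RMS of the aperiodic EEG background, volts.
#' @param alpha_rms Baseline RMS of the alpha oscillation, volts.
#' @param alpha_bw Full bandwidth of the alpha oscillation, Hz (8-12 Hz at
#'   the defaults).
#' @param nuisance_bands List of arousal-independent rhythms, each
#'   `list(center =, rms =, bw =)` (Hz, volts, Hz). Real EEG has rhythms in
#'   neighboring bands whose power fluctuates independently of arousal;
#'   without them, spectral leakage of the alpha peak (a 300-ms Hanning
#'   window smears it over several Hz) would make every band a noiseless copy
#'   of alpha. Defaults: theta (5 Hz), low beta (14 Hz), high beta (22 Hz).
#' @param band_gain_sd Log-scale SD of the slow, arousal-independent power
#'   fluctuations of the nuisance rhythms.
#' @param nuisance_timescale_sd Smoothing SD (minutes) of those fluctuations
#'   (clamped to half the session duration).
#' @param pupil_baseline Baseline pupil diameter, arbitrary units.
#' @param eye_drift_sd SD of slow fixational eye drift, deg.
#' @param seed Optional integer seed stored with the config.
#' @return An object of class `synth_config` (validated list).
#' @export
synth_config <- function(session_duration = 120,
                         n_neurons = 40,
                         n_electrodes = 8,
                         eeg_rate = 1000,
                         eye_rate = 1000,
                         prestimulus_range = c(300, 500),
                         stimulus_duration = 400,
                         latent_timescale_sd = 30,
                         aperiodic_exponent = 1,
                         alpha_center = 10,
                         alpha_coupling = -0.5,
                         pupil_coupling = 0.5,
                         msrate_coupling = -0.5,
                         drift_coupling = 0.5,
                         hit_coupling = 0,
                         fa_coupling = 0.5,
                         base_msaccade_rate = 1.5,
                         main_sequence_slope = 100,
                         ms_amplitude_range = c(0.05, 1),
                         n_microsaccades = NULL,
                         positive_fraction = 0.85,
                         base_count_range = c(4, 12),
                         tuning_sd = 0.35,
                         p_change = 0.3,
                         p_hit = 0.55,
                         p_fa = 0.03,
                         eeg_background_rms = 15e-6,
                         alpha_rms = 6e-6,
                         alpha_bw = 4,
                         nuisance_bands = list(
                           list(center = 5, rms = 4e-6, bw = 4),
                           list(center = 14, rms = 3e-6, bw = 4),
                           list(center = 22, rms = 3e-6, bw = 8)),
                         band_gain_sd = 0.5,
                         nuisance_timescale_sd = 10,
                         pupil_baseline = 5,
                         eye_drift_sd = 0.05,
                         seed = NULL) {
  cfg <- as.list(environment())
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  sd_check(cfg$session_duration > 0 && cfg$stimulus_duration > 0,
           "invalid_parameter", "durations must be positive")
  sd_check(cfg$n_electrodes >= 2, "invalid_parameter",
           "at least 2 electrodes are required for average referencing")
  sd_check(cfg$n_neurons >= 1, "invalid_parameter", "n_neurons must be >= 1")
  sd_check(cfg$eeg_rate > 0 && cfg$eye_rate > 0, "invalid_parameter",
           "sampling rates must be positive")
  sd_check(length(cfg$prestimulus_range) == 2 &&
             cfg$prestimulus_range[1] > 0 &&
             cfg$prestimulus_range[1] <= cfg$prestimulus_range[2],
           "invalid_parameter", "prestimulus_range must be a valid ms range")
  couplings <- c(cfg$alpha_coupling, cfg$pupil_coupling, cfg$msrate_coupling,
                 cfg$drift_coupling, cfg$hit_coupling, cfg$fa_coupling)
  sd_check(all(is.finite(couplings)), "invalid_parameter",
           "couplings must be finite")
  sd_check(cfg$main_sequence_slope > 0, "invalid_parameter",
           "main_sequence_slope must be positive")
  sd_check(cfg$base_msaccade_rate >= 0, "invalid_parameter",
           "base_msaccade_rate must be nonnegative")
  sd_check(cfg$latent_timescale_sd > 0, "invalid_parameter",
           "latent_timescale_sd must be positive")
  invisible(cfg)
}
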