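#' Generate population spike counts for the stimulus periods of a session
#'
#' Counts follow the model the slow-drift analysis assumes: for neuron i and
#' stimulus period t,
#' `count ~ Poisson(exp(b_i + tuning_i(theta_t) + drift_coupling * w_i * latent(t)))`,
#' with log-baselines `b_i` spanning `base_count_range` counts per period,
#' antisymmetric orientation tuning of SD `tuning_sd`, and latent loadings
#' `w_i` whose magnitudes are uniform on [0.5, 1] and whose signs are positive
#' for a fixed majority (`positive_fraction`) of neurons.
#'
#' @param latent An `arousal_latent` covering all event times.
#' @param events Event table from [generate_events()].
#' @param config A [synth_config()].
#' @param seed Optional integer seed.
#' @return List with `counts` (neurons x stimulus-periods integer matrix),
#'   `orientations` (per-period labels), `loadings` (per-neuron signed
#'   weights), `onsets` (stimulus onsets, s).
#' @export
generate_spikes <- function(latent, events, config, seed = NULL) {
  validate_synth_config(config)
  stim <- events[events$period_type == "stimulus", , drop = FALSE]
  sd_check(nrow(stim) > 0, "invalid_parameter", "no stimulus periods in events")
  sd_check(max(stim$onset + stim$duration) <= max(latent$time_s) + 1e-9,
           "invalid_parameter", "latent does not cover all event times")
  with_seed(seed, {
    n <- config$n_neurons
    b <- log(stats::runif(n, config$base_count_range[1],
                          config$base_count_range[2]))
    tuning <- stats::rnorm(n, sd = config$tuning_sd)
    n_pos <- ceiling(config$positive_fraction * n)
    signs <- rep(-1, n)
    signs[sample.int(n, n_pos)] <- 1
    w <- signs * stats::runif(n, 0.5, 1)
    lat <- latent_at(latent, stim$onset + stim$duration / 2)
    ori_sign <- ifelse(stim$orientation == 45, 0.5, -0.5)
    # log-rate matrix: neurons x periods
    eta <- outer(b, rep(1, nrow(stim))) +
      outer(tuning, ori_sign) +
      config$drift_coupling * outer(w, lat)
    sd_check(max(eta) <= 20, "invalid_parameter",
             "spike-rate model overflow: exp argument exceeds cap (20)")
    counts <- matrix(stats::rpois(length(eta), exp(eta)),
                     nrow = n, ncol = nrow(stim))
    rownames(counts) <- sprintf("n%03d", seq_len(n))
    list(counts = counts, orientations = stim$orientation, loadings = w,
         onsets = stim$onset)
  })
}
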