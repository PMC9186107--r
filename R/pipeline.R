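# Cohort orchestration: per-session analysis and across-session summaries.

#' Analyze one session end to end
#'
#' Runs microsaccade detection and per-period eye metrics, the prestimulus
#' EEG spectral pipeline (segment extraction, screening, Hanning FFT, sliding
#' binning, aperiodic removal, band power, optional 4-Hz frequency scan), slow
#' drift extraction, and behavioral rates, all on the shared 30-min/6-min bin
#' geometry. For period-level (`session_summary`) inputs the precomputed
#' period metrics are binned directly and the waveform stages are skipped.
#'
#' @param rec A `session_recording` or `session_summary`.
#' @param window,step Bin geometry, minutes.
#' @param min_segments Minimum EEG segments per bin (default 10).
#' @param sliding Compute the 4-Hz sliding frequency scan (default TRUE).
#' @param timescale_step Step (minutes) of the finer binning used for
#'   timescale estimation (default 1).
#' @param timescales Estimate drift/alpha timescales (default TRUE; needs
#'   `>= 20` fine-step bins).
#' @param seed Seed for the timescale CV folds.
#' @return Object of class `session_analysis`: `metrics` (named list of binned
#'   series: alpha, theta, beta, gamma, pupil, msrate, rt, sacc_vel, drift,
#'   hit_rate, fa_rate), `sliding` (per-left-edge series), `drift_fit`,
#'   `microsaccades`, `main_sequence_r`, `screen_log`, `timescale` (drift and
#'   alpha `timescale_estimate`s), `counts` (per-stage bookkeeping),
#'   `session_id`, `subject_id`, `ground_truth`.
#' @export
analyze_session <- function(rec, window = 30, step = 6, min_segments = 10,
                            sliding = TRUE, timescale_step = 1,
                            timescales = TRUE, seed = NULL) {
  UseMethod("analyze_session")
}

#' @export
analyze_session.session_recording <- function(rec, window = 30, step = 6,
                                              min_segments = 10,
                                              sliding = TRUE,
                                              timescale_step = 1,
                                              timescales = TRUE, seed = NULL) {
  duration_min <- rec$duration_s / 60
  metrics <- list()

  # --- eye metrics (velocity computed once, shared by all stages) ---
  velocity <- compute_velocity(rec$eye, rec$eye_rate)
  speed <- sqrt(velocity[, 1]^2 + velocity[, 2]^2)
  ms <- detect_microsaccades(rec$eye, rec$eye_rate, velocity = velocity)
  per_period <- per_period_metrics(rec, ms, speed = speed)
  metrics$msrate <- bin_series(per_period$msrate$time_s,
                               per_period$msrate$value,
                               duration_min, window, step)
  metrics$pupil <- bin_series(per_period$pupil$time_s, per_period$pupil$value,
                              duration_min, window, step)
  for (nm in c("rt", "sacc_vel")) {
    if (nrow(per_period[[nm]]) > 0) {
      metrics[[nm]] <- bin_series(per_period[[nm]]$time_s,
                                  per_period[[nm]]$value,
                                  duration_min, window, step)
    }
  }
  ms_r <- if (nrow(ms) >= 3) main_sequence_correlation(ms) else NA_real_

  # --- EEG spectral pipeline ---
  segs <- extract_segments(rec)
  screened <- screen_segments(segs, rec, speed = speed)
  rm(velocity, speed)
  pw <- segment_power_batch(screened)
  binned <- bin_spectra(pw, duration_min, window, step, min_segments)
  resset <- remove_aperiodic(binned)
  bands <- canonical_bands()
  for (nm in names(bands)) metrics[[nm]] <- band_power(resset, bands[[nm]])
  sliding_series <- if (sliding) sliding_band_power(resset) else NULL

  # --- slow drift ---
  drift_fit <- session_drift(rec$spike_counts, rec$orientations,
                             stim_onsets(rec$events), duration_min,
                             window, step)
  metrics$drift <- data.frame(bin_center_min = drift_fit$bin_centers,
                              value = drift_fit$drift,
                              n = NA_integer_)

  # --- behavior ---
  beh <- binned_outcome_rates(rec$events, duration_min, window, step)
  metrics$hit_rate <- beh$hit_rate
  metrics$fa_rate <- beh$fa_rate

  # --- timescales on the fine-step variant ---
  ts <- NULL
  if (timescales) {
    ts <- session_timescales(rec, pw = pw, duration_min = duration_min,
                             window = window, step = timescale_step,
                             min_segments = min_segments, seed = seed)
  }

  log <- attr(screened, "screen_log")
  structure(list(
    session_id = rec$session_id, subject_id = rec$subject_id,
    metrics = metrics, sliding = sliding_series,
    drift_fit = drift_fit, microsaccades = ms, main_sequence_r = ms_r,
    screen_log = log, timescale = ts,
    counts = list(n_segments = length(segs$onsets),
                  n_segments_kept = length(screened$onsets),
                  n_microsaccades = nrow(ms),
                  n_bins = length(resset$bin_centers)),
    ground_truth = rec$ground_truth), class = "session_analysis")
}

#' @export
analyze_session.session_summary <- function(rec, window = 30, step = 6,
                                            min_segments = 10, sliding = TRUE,
                                            timescale_step = 1,
                                            timescales = TRUE, seed = NULL) {
  duration_min <- rec$duration_s / 60
  metrics <- list()
  metrics$alpha <- bin_series(rec$segment_onsets, rec$segment_alpha_power,
                              duration_min, window, step,
                              min_count = min_segments)
  metrics$msrate <- bin_series(rec$segment_onsets,
                               rec$segment_ms_counts / rec$segment_durations,
                               duration_min, window, step)
  metrics$pupil <- bin_series(rec$stim_onsets, rec$stim_pupil,
                              duration_min, window, step)
  drift_fit <- session_drift(rec$spike_counts, rec$orientations,
                             rec$spike_onsets, duration_min, window, step)
  metrics$drift <- data.frame(bin_center_min = drift_fit$bin_centers,
                              value = drift_fit$drift, n = NA_integer_)
  beh <- binned_outcome_rates(rec$events, duration_min, window, step)
  metrics$hit_rate <- beh$hit_rate
  metrics$fa_rate <- beh$fa_rate
  structure(list(
    session_id = rec$session_id, subject_id = rec$subject_id,
    metrics = metrics, sliding = NULL, drift_fit = drift_fit,
    microsaccades = NULL, main_sequence_r = NA_real_, screen_log = NULL,
    timescale = NULL,
    counts = list(n_segments = length(rec$segment_onsets),
                  n_bins = nrow(metrics$alpha)),
    ground_truth = rec$ground_truth), class = "session_analysis")
}

stim_onsets <- function(events) {
  events$onset[events$period_type == "stimulus"]
}

# Fine-step (default 1-min) rebinning of drift and alpha power followed by
# cross-validated timescale estimation.
session_timescales <- function(rec, pw = NULL, duration_min = NULL,
                               window = 30, step = 1, min_segments = 10,
                               seed = NULL) {
  duration_min <- duration_min %||% (rec$duration_s / 60)
  if (is.null(pw)) {
    screened <- screen_segments(extract_segments(rec), rec)
    pw <- segment_power_batch(screened)
  }
  binned <- bin_spectra(pw, duration_min, window, step, min_segments)
  alpha <- band_power(remove_aperiodic(binned), c(8, 12))
  drift_fit <- session_drift(rec$spike_counts, rec$orientations,
                             stim_onsets(rec$events), duration_min,
                             window, step)
  seeds <- derive_seeds(seed, 2)
  drift_series <- data.frame(bin_center_min = drift_fit$bin_centers,
                             value = drift_fit$drift)
  safe_ts <- function(series, s) {
    tryCatch(series_timescale(series, seed = s), error = function(e) NULL)
  }
  list(drift = safe_ts(drift_series, seeds[[1]]),
       alpha = safe_ts(alpha[, c("bin_center_min", "value")], seeds[[2]]))
}

#' Cohort configuration
#'
#' @param n_sessions Number of sessions.
#' @param synth A [synth_config()] shared by all sessions.
#' @param subjects Subject labels cycled over sessions (two-subject cohorts by
#'   default, mirroring a two-animal experiment).
#' @param fidelity `"full"` or `"summary"` (see [simulate_session()]).
#' @param window,step,min_segments Analysis bin geometry.
#' @param sliding,timescales Which optional analyses to run.
#' @param seed Master seed; per-session and per-stage seeds are derived.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_sessions = 20, synth = synth_config(),
                          subjects = c("monkey1", "monkey2"),
                          fidelity = c("full", "summary"),
                          window = 30, step = 6, min_segments = 10,
                          sliding = TRUE, timescales = TRUE, seed = 1) {
  fidelity <- match.arg(fidelity)
  sd_check(n_sessions >= 1, "invalid_parameter", "need at least 1 session")
  validate_synth_config(synth)
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate and analyze a cohort of sessions
#'
#' Sessions are generated and analyzed one at a time (raw waveforms are
#' discarded after analysis), then across-session summaries are assembled:
#' within-session correlation summaries for the headline metric pairs
#' (alpha-pupil, alpha-msrate, alpha-drift, drift-pupil, drift-msrate, plus
#' drift against theta/beta/gamma and alpha against the behavioral metrics),
#' variance-magnitude results, the sliding-frequency scan of median drift-power
#' correlations, and drift/alpha timescales. A stage-count manifest is kept
#' per session; a failing session is recorded and skipped rather than aborting
#' the cohort.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, all summary tables are
#'   written as CSV via [export_results()].
#' @return Object of class `cohort_result`: `sessions` (list of
#'   `session_analysis`), `correlations` (list of `correlation_summary`),
#'   `variance_magnitude`, `freq_scan` (data.frame per left edge),
#'   `timescales` (per-session data.frame), `manifest`, `errors`.
#' @export
run_cohort <- function(config = cohort_config(), out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(config$seed, config$n_sessions)
  analyses <- list()
  errors <- list()
  for (i in seq_len(config$n_sessions)) {
    res <- tryCatch({
      sess_seeds <- derive_seeds(seeds[[i]], 2)
      rec <- simulate_session(config$synth, seed = sess_seeds[[1]],
                              fidelity = config$fidelity)
      rec$session_id <- sprintf("s%02d", i)
      rec$subject_id <- config$subjects[(i - 1) %% length(config$subjects) + 1]
      an <- analyze_session(rec, window = config$window, step = config$step,
                            min_segments = config$min_segments,
                            sliding = config$sliding,
                            timescales = config$timescales,
                            seed = sess_seeds[[2]])
      rm(rec)
      gc(FALSE)
      an
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[sprintf("s%02d", i)]] <- conditionMessage(res)
    } else {
      analyses[[length(analyses) + 1]] <- res
    }
  }
  sd_check(length(analyses) > 0, "empty_output", "every session failed")

  pairs <- list(c("alpha", "pupil"), c("alpha", "msrate"), c("alpha", "drift"),
                c("drift", "pupil"), c("drift", "msrate"),
                c("theta", "drift"), c("beta", "drift"), c("gamma", "drift"),
                c("alpha", "hit_rate"), c("alpha", "fa_rate"),
                c("alpha", "rt"), c("alpha", "sacc_vel"))
  correlations <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "_")
    cs <- tryCatch(within_session_correlations(analyses, pr[1], pr[2]),
                   error = function(e) NULL)
    if (!is.null(cs)) correlations[[key]] <- cs
  }

  vm <- list(
    alpha_pupil = tryCatch(variance_magnitude(analyses, "alpha", "pupil"),
                           error = function(e) NULL),
    alpha_msrate = tryCatch(variance_magnitude(analyses, "alpha", "msrate"),
                            error = function(e) NULL))

  freq_scan <- NULL
  if (config$sliding && config$fidelity == "full") {
    edges <- names(analyses[[1]]$sliding)
    rows <- lapply(edges, function(ed) {
      wrapped <- lapply(analyses, function(a) {
        list(session_id = a$session_id, subject_id = a$subject_id,
             metrics = list(power = a$sliding[[ed]],
                            drift = a$metrics$drift))
      })
      cs <- tryCatch(within_session_correlations(wrapped, "power", "drift"),
                     error = function(e) NULL)
      if (is.null(cs)) return(NULL)
      data.frame(left_edge_hz = as.numeric(ed), median_r = cs$median_r,
                 p = cs$p)
    })
    freq_scan <- do.call(rbind, rows)
  }

  ts_tab <- NULL
  if (config$timescales && config$fidelity == "full") {
    rows <- lapply(analyses, function(a) {
      if (is.null(a$timescale) || is.null(a$timescale$drift) ||
          is.null(a$timescale$alpha)) return(NULL)
      data.frame(session_id = a$session_id, subject_id = a$subject_id,
                 drift_timescale_min = a$timescale$drift$timescale,
                 drift_censored = a$timescale$drift$censored,
                 alpha_timescale_min = a$timescale$alpha$timescale,
                 alpha_censored = a$timescale$alpha$censored)
    })
    ts_tab <- do.call(rbind, rows)
  }

  manifest <- list(
    n_sessions_requested = config$n_sessions,
    n_sessions_analyzed = length(analyses),
    fidelity = config$fidelity,
    seed = config$seed,
    window_min = config$window, step_min = config$step,
    min_segments = config$min_segments,
    package_version = as.character(utils::packageVersion("slowdrift")),
    per_session_counts = lapply(analyses, function(a) {
      c(list(session_id = a$session_id), a$counts)
    }))

  result <- structure(list(sessions = analyses, correlations = correlations,
                           variance_magnitude = vm, freq_scan = freq_scan,
                           timescales = ts_tab, manifest = manifest,
                           errors = errors), class = "cohort_result")
  if (!is.null(out_dir)) export_cohort(result, out_dir)
  result
}

# Write every cohort summary (and per-session binned metrics) as CSV.
export_cohort <- function(result, out_dir) {
  tables <- list()
  for (key in names(result$correlations)) {
    tables[[paste0("correlations_", key)]] <- result$correlations[[key]]$per_session
  }
  summary_rows <- lapply(names(result$correlations), function(key) {
    cs <- result$correlations[[key]]
    data.frame(pair = key, median_r = cs$median_r, p = cs$p,
               n_sessions = cs$n_sessions)
  })
  tables$correlation_summary <- do.call(rbind, summary_rows)
  if (!is.null(result$freq_scan)) tables$freq_scan <- result$freq_scan
  if (!is.null(result$timescales)) tables$timescales <- result$timescales
  for (a in result$sessions) {
    for (nm in names(a$metrics)) {
      m <- a$metrics[[nm]]
      if (is.null(m) || nrow(m) == 0) next
      tables[[paste0("session_", a$session_id, "_", nm)]] <-
        m[, c("bin_center_min", "value")]
    }
  }
  paths <- export_results(tables, out_dir)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
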