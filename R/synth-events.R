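#' Generate the trial/period event table of a session
#'
#' Each trial begins with an initial fixation (prestimulus) period, then
#' alternates 400-ms stimulus periods with fixation periods whose durations are
#' drawn uniformly from `prestimulus_range`. Each stimulus is labeled 45 or 135
#' degrees at random. On each stimulus presentation an orientation change
#' occurs with probability `p_change`; a change trial ends in a hit (saccade
#' within 400 ms) or a miss, and an unchanged stimulus can end the trial with a
#' false alarm. Outcome probabilities can be modulated by the arousal latent
#' (logistic link) through `hit_coupling` / `fa_coupling`. Trials are separated
#' by a short intertrial interval (plus a 1-s timeout after false alarms) and
#' tile the session until the configured duration is reached.
#'
#' @param config A [synth_config()].
#' @param latent Optional `arousal_latent` used to modulate outcome
#'   probabilities; `NULL` leaves them at baseline.
#' @param seed Optional integer seed.
#' @return A data.frame with one row per period: `trial`, `period`
#'   (index within trial), `period_type` ("prestimulus"/"stimulus"), `onset`
#'   and `duration` (seconds), `orientation` (45/135, NA for prestimulus),
#'   `is_initial` (first fixation of a trial), `change`, `change_time`,
#'   `outcome` ("hit"/"miss"/"false_alarm", on the trial-ending stimulus row),
#'   `saccade_time` (hits/false alarms). The session duration in seconds is
#'   attached as attribute `duration_s`.
#' @export
generate_events <- function(config, latent = NULL, seed = NULL) {
  validate_synth_config(config)
  with_seed(seed, {
    dur_s <- config$session_duration * 60
    pre_lo <- config$prestimulus_range[1] / 1000
    pre_hi <- config$prestimulus_range[2] / 1000
    stim_d <- config$stimulus_duration / 1000
    iti <- 1.2
    rows <- vector("list", 4096)
    nrow_used <- 0L
    add_row <- function(row) {
      nrow_used <<- nrow_used + 1L
      if (nrow_used > length(rows)) length(rows) <<- 2L * length(rows)
      rows[[nrow_used]] <<- row
    }
    lat_val <- function(t) {
      if (is.null(latent)) 0 else latent_at(latent, t)
    }
    t <- 0
    trial <- 0L
    while (t + pre_hi + stim_d < dur_s) {
      trial <- trial + 1L
      period <- 0L
      outcome <- NA_character_
      first <- TRUE
      repeat {
        # fixation period
        pre_d <- stats::runif(1, pre_lo, pre_hi)
        if (t + pre_d + stim_d > dur_s) break
        period <- period + 1L
        add_row(list(trial = trial, period = period,
                     period_type = "prestimulus", onset = t, duration = pre_d,
                     orientation = NA_real_, is_initial = first,
                     change = FALSE, change_time = NA_real_,
                     outcome = NA_character_, saccade_time = NA_real_))
        first <- FALSE
        t <- t + pre_d
        # stimulus period
        if (t + stim_d > dur_s) break
        period <- period + 1L
        ori <- sample(c(45, 135), 1)
        lv <- lat_val(t)
        change <- stats::runif(1) < config$p_change
        change_time <- NA_real_
        saccade_time <- NA_real_
        if (change) {
          change_time <- t
          p_hit <- stats::plogis(stats::qlogis(config$p_hit) +
                                   config$hit_coupling * lv)
          if (stats::runif(1) < p_hit) {
            outcome <- "hit"
            saccade_time <- t + draw_reaction_time(1)
          } else {
            outcome <- "miss"
          }
        } else {
          p_fa <- stats::plogis(stats::qlogis(config$p_fa) +
                                  config$fa_coupling * lv)
          if (stats::runif(1) < p_fa) {
            outcome <- "false_alarm"
            saccade_time <- t + draw_reaction_time(1)
          }
        }
        add_row(list(trial = trial, period = period, period_type = "stimulus",
                     onset = t, duration = stim_d, orientation = ori,
                     is_initial = FALSE, change = change,
                     change_time = change_time, outcome = outcome,
                     saccade_time = saccade_time))
        t <- t + stim_d
        if (!is.na(outcome)) break
      }
      t <- t + iti + if (identical(outcome, "false_alarm")) 1 else 0
    }
    events <- data.table::rbindlist(rows[seq_len(nrow_used)])
    events <- as.data.frame(events)
    attr(events, "duration_s") <- dur_s
    events
  })
}

# Saccadic reaction times on rewarded/false-alarm trials: lognormal around
# ~220 ms, truncated below the 400-ms response deadline.
draw_reaction_time <- function(n) {
  rt <- stats::rlnorm(n, meanlog = log(0.22), sdlog = 0.15)
  pmin(pmax(rt, 0.12), 0.39)
}
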