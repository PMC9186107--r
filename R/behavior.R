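#' Binned behavioral outcome rates
#'
#' Hit rate and false-alarm rate per sliding-window bin, on the same bin
#' geometry as every other session metric. Hit rate is hits / (hits + misses)
#' over change trials in the bin; false-alarm rate is false-alarm trials over
#' all completed trials in the bin (the denominator is a package choice; the
#' alternative - saccade-outcome trials only - can be selected with
#' `fa_denominator`). Trials are located in time by the trial-ending stimulus
#' (change time when present). Bins with no qualifying trials are dropped;
#' pairwise bin alignment downstream handles the gaps.
#'
#' @param events Event table (see [generate_events()]).
#' @param duration_min Session duration, minutes (taken from the events
#'   attribute when omitted).
#' @param window,step Bin geometry, minutes.
#' @param fa_denominator `"completed"` (all completed trials, default) or
#'   `"saccade_or_miss"`.
#' @return List with binned series `hit_rate` and `fa_rate`.
#' @export
binned_outcome_rates <- function(events, duration_min = NULL,
                                 window = 30, step = 6,
                                 fa_denominator = c("completed",
                                                    "saccade_or_miss")) {
  fa_denominator <- match.arg(fa_denominator)
  if (is.null(duration_min)) {
    duration_min <- attr(events, "duration_s") / 60
  }
  sd_check(!is.null(duration_min) && is.finite(duration_min),
           "invalid_parameter", "session duration is required")
  done <- events[!is.na(events$outcome), , drop = FALSE]
  sd_check(nrow(done) > 0, "invalid_parameter", "no outcome labels present")
  t_ev <- ifelse(is.na(done$change_time), done$onset, done$change_time)
  is_hit <- done$outcome == "hit"
  is_miss <- done$outcome == "miss"
  is_fa <- done$outcome == "false_alarm"
  bins <- sliding_bins(duration_min, window, step)
  hit_rows <- list()
  fa_rows <- list()
  for (i in seq_len(nrow(bins))) {
    in_bin <- t_ev / 60 >= bins$start_min[i] & t_ev / 60 < bins$end_min[i]
    n_change <- sum(in_bin & (is_hit | is_miss))
    if (n_change > 0) {
      hit_rows[[length(hit_rows) + 1]] <- data.frame(
        bin_center_min = bins$center_min[i],
        value = sum(in_bin & is_hit) / n_change, n = n_change)
    }
    denom <- if (fa_denominator == "completed") {
      sum(in_bin)
    } else {
      sum(in_bin & (is_hit | is_fa | is_miss))
    }
    if (denom > 0) {
      fa_rows[[length(fa_rows) + 1]] <- data.frame(
        bin_center_min = bins$center_min[i],
        value = sum(in_bin & is_fa) / denom, n = denom)
    }
  }
  list(hit_rate = do.call(rbind, hit_rows), fa_rate = do.call(rbind, fa_rows))
}
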