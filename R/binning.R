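#' Sliding-window bin geometry
#'
#' All session metrics (residual band power, pupil, microsaccade rate, slow
#' drift, behavioral rates) are reduced to the same sliding-window time series
#' so that they can be correlated bin-by-bin. Windows are half-open
#' `[t, t + window)` minutes, stepped from the session start; only windows that
#' fit entirely inside the session are formed. With the default 30-min window
#' and 6-min step a 120-min session yields 16 bins; the 1-min-step variant used
#' for timescale estimation yields 91.
#'
#' @param duration_min Session duration in minutes.
#' @param window Window width in minutes (default 30).
#' @param step Step between window starts in minutes (default 6).
#' @return A data.frame with columns `start_min`, `end_min`, `center_min`.
#' @export
sliding_bins <- function(duration_min, window = 30, step = 6) {
  sd_check(is.numeric(duration_min) && duration_min > 0 &&
             is.numeric(window) && window > 0 && is.numeric(step) && step > 0,
           "invalid_parameter", "duration, window and step must be positive")
  sd_check(duration_min >= window, "session_too_short",
           "session (%.1f min) is shorter than the binning window (%.1f min)",
           duration_min, window)
  starts <- seq(0, duration_min - window, by = step)
  data.frame(start_min = starts,
             end_min = starts + window,
             center_min = starts + window / 2)
}

#' Reduce a point series to sliding-window bins
#'
#' @param times_s Event/sample times in seconds from session start.
#' @param values Values associated with `times_s` (same length).
#' @param duration_min Session duration in minutes.
#' @param window,step Bin geometry in minutes (see [sliding_bins()]).
#' @param min_count Bins built from fewer than `min_count` points are dropped.
#' @param fun Summary function applied within each window (default `mean`).
#' @return A data.frame with columns `bin_center_min`, `value`, `n`.
#' @export
bin_series <- function(times_s, values, duration_min, window = 30, step = 6,
                       min_count = 1, fun = mean) {
  stopifnot(length(times_s) == length(values))
  bins <- sliding_bins(duration_min, window, step)
  t_min <- times_s / 60
  out <- lapply(seq_len(nrow(bins)), function(i) {
    in_bin <- t_min >= bins$start_min[i] & t_min < bins$end_min[i]
    n <- sum(in_bin)
    if (n < min_count) return(NULL)
    data.frame(bin_center_min = bins$center_min[i],
               value = fun(values[in_bin]), n = n)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(bin_center_min = numeric(0), value = numeric(0),
                      n = integer(0))
  }
  rownames(out) <- NULL
  out
}

# Align two binned series on their common bin centers (pairwise deletion of
# bins missing from either series).
align_bins <- function(a, b) {
  key_a <- round(a$bin_center_min, 6)
  key_b <- round(b$bin_center_min, 6)
  common <- intersect(key_a, key_b)
  list(x = a$value[match(common, key_a)],
       y = b$value[match(common, key_b)],
       bin_center_min = common)
}
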