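# Timescale estimation by cross-validated Gaussian-kernel smoothing.

#' Cross-validated R-squared curve over smoothing SDs
#'
#' Points are partitioned at random into `n_folds` folds. For each fold and
#' each smoothing SD, every held-out point is predicted as the Gaussian
#' weighted average of the retained points,
#' `sum_j w_j y_j / sum_j w_j` with `w_j = exp(-(t - t_j)^2 / (2 sd^2))`, and
#' R-squared is pooled over all held-out predictions
#' (`1 - SSE / SST`, SST about the global mean). A held-out point whose kernel
#' weights all underflow falls back to its nearest retained neighbor.
#'
#' @param series Binned series (data.frame with `bin_center_min`, `value`) or
#'   a numeric vector of values with `times` supplied separately.
#' @param times Bin centers in minutes (if `series` is a plain vector).
#' @param sd_grid Smoothing SDs in minutes (default 1-90, step 1).
#' @param n_folds Number of CV folds (default 10).
#' @param seed Optional integer seed controlling the fold assignment.
#' @return Object of class `cv_r2_curve`: `sd_grid`, `r2`, `folds`.
#' @export
cv_r2_curve <- function(series, times = NULL, sd_grid = 1:90, n_folds = 10,
                        seed = NULL) {
  if (is.data.frame(series)) {
    times <- series$bin_center_min
    y <- series$value
  } else {
    y <- as.numeric(series)
  }
  n <- length(y)
  sd_check(!is.null(times) && length(times) == n, "invalid_parameter",
           "times and values must have equal length")
  sd_check(n >= 20, "invalid_parameter",
           "need at least 20 points for cross-validation")
  sd_check(stats::var(y) > 0, "degenerate_input", "series variance is zero")
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  d2 <- outer(times, times, "-")^2
  sst <- sum((y - mean(y))^2)
  r2 <- vapply(sd_grid, function(s) {
    w <- exp(-d2 / (2 * s^2))
    sse <- 0
    for (f in seq_len(n_folds)) {
      held <- which(folds == f)
      ret <- which(folds != f)
      wf <- w[held, ret, drop = FALSE]
      denom <- rowSums(wf)
      pred <- as.numeric(wf %*% y[ret]) / denom
      bad <- denom < 1e-300
      if (any(bad)) {
        nearest <- apply(d2[held[bad], ret, drop = FALSE], 1, which.min)
        pred[bad] <- y[ret][nearest]
      }
      sse <- sse + sum((y[held] - pred)^2)
    }
    1 - sse / sst
  }, numeric(1))
  structure(list(sd_grid = sd_grid, r2 = r2, folds = folds),
            class = "cv_r2_curve")
}

#' Timescale from a cross-validated R-squared curve
#'
#' The timescale is the smallest smoothing SD above the R-squared maximum at
#' which R-squared has dropped to 75% of that maximum (larger SDs smooth away
#' progressively faster components, so the decay point above the argmax
#' characterizes how slow the series' recoverable structure is). If the curve
#' never drops below the threshold within the grid the estimate is censored at
#' the grid maximum.
#'
#' @param curve A `cv_r2_curve` (or list with `sd_grid` and `r2`).
#' @param drop_frac Fraction of the maximum defining the drop point (0.75).
#' @return Object of class `timescale_estimate`: `sd_max` (argmax SD),
#'   `r2_max`, `timescale` (min), `censored`.
#' @export
estimate_timescale <- function(curve, drop_frac = 0.75) {
  r2 <- curve$r2
  grid <- curve$sd_grid
  sd_check(all(is.finite(r2)), "invalid_input", "R-squared curve must be finite")
  r2_max <- max(r2)
  sd_check(r2_max > 0, "no_structure",
           "maximum cross-validated R-squared is not positive; the series has no recoverable timescale")
  i_max <- which.max(r2)
  after <- which(grid > grid[i_max] & r2 <= drop_frac * r2_max)
  if (length(after) == 0) {
    ts <- max(grid)
    censored <- TRUE
  } else {
    ts <- grid[min(after)]
    censored <- FALSE
  }
  structure(list(sd_max = grid[i_max], r2_max = r2_max,
                 timescale = ts, censored = censored,
                 sd_grid = grid, r2 = r2),
            class = "timescale_estimate")
}

#' One-call timescale of a binned series
#'
#' @inheritParams cv_r2_curve
#' @param ... Passed to [cv_r2_curve()].
#' @return A `timescale_estimate`.
#' @export
series_timescale <- function(series, times = NULL, ...) {
  estimate_timescale(cv_r2_curve(series, times, ...))
}
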