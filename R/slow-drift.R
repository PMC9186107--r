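# Slow-drift extraction: orientation residualization, sliding-window binning,
# and PCA projection with the majority-positive sign convention.

#' Orientation-residualized spike counts
#'
#' Subtracts, per neuron, the session-mean response to each orientation (45 or
#' 135 degrees) from the individual responses to that orientation, removing
#' stimulus tuning before latent extraction. Counts are taken from the 400-ms
#' window beginning 50 ms after stimulus onset.
#'
#' @param spike_counts Neurons x stimulus-periods matrix.
#' @param orientations Orientation label (45/135) per period.
#' @return Residual matrix of the same shape; per-orientation row means are 0.
#' @export
residual_counts <- function(spike_counts, orientations) {
  spike_counts <- as.matrix(spike_counts)
  sd_check(ncol(spike_counts) == length(orientations), "invalid_parameter",
           "one orientation label per stimulus period is required")
  for (ori in c(45, 135)) {
    sd_check(any(orientations == ori), "invalid_parameter",
             "orientation %d has no stimulus periods", ori)
  }
  resid <- spike_counts
  for (ori in unique(orientations)) {
    cols <- orientations == ori
    resid[, cols] <- spike_counts[, cols] -
      rowMeans(spike_counts[, cols, drop = FALSE])
  }
  resid
}

#' Bin residual counts with the shared sliding-window geometry
#'
#' Same bin geometry as the EEG binning (30-min window, 6-min step by default;
#' 1-min step for the timescale variant), guaranteeing that drift and EEG
#' series of one session share bin centers.
#'
#' @param residuals Neurons x periods residual matrix.
#' @param times_s Stimulus-period onset times, seconds.
#' @param duration_min Session duration, minutes.
#' @param window,step Bin geometry, minutes.
#' @return Bins x neurons matrix with attribute `"bin_centers"` (min).
#' @export
bin_residuals <- function(residuals, times_s, duration_min,
                          window = 30, step = 6) {
  residuals <- as.matrix(residuals)
  stopifnot(ncol(residuals) == length(times_s))
  bins <- sliding_bins(duration_min, window, step)
  t_min <- times_s / 60
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    in_bin <- t_min >= bins$start_min[i] & t_min < bins$end_min[i]
    if (!any(in_bin)) return(NULL)
    list(center = bins$center_min[i],
         value = rowMeans(residuals[, in_bin, drop = FALSE]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, lapply(rows, `[[`, "value"))
  attr(out, "bin_centers") <- vapply(rows, `[[`, numeric(1), "center")
  out
}

#' Slow drift: PC1 projection of binned residual counts
#'
#' Neuron-wise means across bins are removed, the first principal component of
#' the bins x neurons matrix is computed by SVD, and the drift is the
#' projection onto it. Because PCA weights have an arbitrary sign, the drift
#' and weights are jointly flipped whenever a strict majority of neuron
#' weights is negative, establishing the convention that an increase in drift
#' means higher firing in most neurons (even splits: flip so the weight sum is
#' nonnegative; a weight sum of exactly zero is left as computed).
#'
#' @param binned Bins x neurons matrix from [bin_residuals()].
#' @return Object of class `drift_estimate`: `bin_centers` (min), `drift`
#'   (PC1 projection, spike-count units), `weights` (unit norm),
#'   `variance_explained`.
#' @export
compute_drift <- function(binned) {
  binned <- as.matrix(binned)
  sd_check(nrow(binned) >= 2 && ncol(binned) >= 1, "invalid_parameter",
           "need at least 2 bins and 1 neuron")
  centers <- attr(binned, "bin_centers") %||% seq_len(nrow(binned))
  xc <- sweep(binned, 2, colMeans(binned))
  sd_check(sum(xc^2) > 0, "degenerate_input",
           "binned residuals have zero variance")
  sv <- svd(xc)
  w <- sv$v[, 1]
  scores <- xc %*% w
  n_neg <- sum(w < 0)
  n_nonneg <- sum(w >= 0)
  flip <- if (n_neg > n_nonneg) {
    TRUE
  } else if (n_neg == n_nonneg) {
    sum(w) < 0
  } else {
    FALSE
  }
  if (flip) {
    w <- -w
    scores <- -scores
  }
  structure(list(bin_centers = as.numeric(centers),
                 drift = as.numeric(scores),
                 weights = w,
                 variance_explained = sv$d[1]^2 / sum(sv$d^2)),
            class = "drift_estimate")
}

# Convenience: full drift pipeline from a recording.
session_drift <- function(spike_counts, orientations, onsets_s, duration_min,
                          window = 30, step = 6) {
  resid <- residual_counts(spike_counts, orientations)
  binned <- bin_residuals(resid, onsets_s, duration_min, window, step)
  compute_drift(binned)
}
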