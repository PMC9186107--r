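# Session-level statistics: Pearson correlations within sessions, Wilcoxon
# signed-rank across sessions, cross-session null distributions, and
# variance-magnitude analysis.

#' Pearson product-moment correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r` and `p` (t transformation, two-sided).
#' @export
pearson_r <- function(x, y) {
  sd_check(length(x) == length(y) && length(x) >= 3, "invalid_parameter",
           "x and y must have equal length >= 3")
  sd_check(all(is.finite(x)) && all(is.finite(y)), "invalid_parameter",
           "inputs must be finite")
  sd_check(stats::var(x) > 0 && stats::var(y) > 0, "undefined_correlation",
           "correlation undefined for zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Wilcoxon signed-rank test of median zero
#'
#' Two-sided one-sample test. Exact zeros are dropped; ties among the absolute
#' values are mid-ranked. For n <= 25 the exact null distribution of the
#' positive-rank sum is computed by dynamic programming over all 2^n sign
#' assignments; above that a normal approximation with continuity and tie
#' correction is used.
#'
#' @param values Numeric vector (e.g., per-session correlation coefficients).
#' @param exact_max Largest n for the exact branch (default 25).
#' @return List with `p`, statistic `W` (positive-rank sum), `n` (nonzero
#'   values used), `method`.
#' @export
wilcoxon_signed_rank <- function(values, exact_max = 25) {
  v <- values[values != 0]
  if (length(v) == 0) {
    warning("all values are exactly zero; p = 1")
    return(list(p = 1, W = 0, n = 0L, method = "degenerate"))
  }
  sd_check(length(v) >= 5, "insufficient_data",
           "need at least 5 nonzero values")
  n <- length(v)
  rnk <- rank(abs(v), ties.method = "average")
  W <- sum(rnk[v > 0])
  if (n <= exact_max) {
    # exact: DP over doubled ranks (mid-ranks become integers)
    r2 <- as.integer(round(2 * rnk))
    total <- sum(r2)
    dist <- numeric(total + 1) # index k+1 = prob mass at doubled-sum k
    dist[1] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), dist[seq_len(total + 1 - r)])
      dist <- (dist + shifted) / 2
    }
    w2 <- as.integer(round(2 * W))
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rnk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  list(p = p, W = W, n = n, method = method)
}

#' Within-session correlations between two binned metrics
#'
#' For every session, the two series are restricted to their common bins and a
#' Pearson correlation is computed; the across-session distribution of
#' coefficients is summarized by its median (overall and per subject) and
#' tested against a zero median with the Wilcoxon signed-rank test. Sessions
#' with fewer than `min_bins` common bins are excluded with a warning.
#'
#' @param sessions List of session analyses (see [analyze_session()]), each
#'   with `$metrics[[metric]]` binned series and `$session_id`/`$subject_id`.
#' @param metric_a,metric_b Metric names (e.g., `"alpha"`, `"pupil"`,
#'   `"msrate"`, `"drift"`).
#' @param min_bins Minimum number of common bins per session (default 3).
#' @return Object of class `correlation_summary`: `per_session` data.frame
#'   (`session_id`, `subject_id`, `r`, `n_bins`), `median_r`,
#'   `median_r_by_subject`, `p` (Wilcoxon, NA when < 5 sessions), `n_sessions`.
#' @export
within_session_correlations <- function(sessions, metric_a, metric_b,
                                        min_bins = 3) {
  rows <- lapply(sessions, function(s) {
    a <- s$metrics[[metric_a]]
    b <- s$metrics[[metric_b]]
    if (is.null(a) || is.null(b)) return(NULL)
    al <- align_bins(a, b)
    if (length(al$x) < min_bins) {
      warning(sprintf("session %s: only %d common bins; excluded",
                      s$session_id, length(al$x)))
      return(NULL)
    }
    data.frame(session_id = s$session_id, subject_id = s$subject_id,
               r = stats::cor(al$x, al$y), n_bins = length(al$x))
  })
  per_session <- do.call(rbind, rows)
  sd_check(!is.null(per_session) && nrow(per_session) > 0, "empty_output",
           "no session had enough common bins")
  p <- if (nrow(per_session) >= 5) {
    wilcoxon_signed_rank(per_session$r)$p
  } else {
    NA_real_
  }
  structure(list(
    metric_a = metric_a, metric_b = metric_b,
    per_session = per_session,
    median_r = stats::median(per_session$r),
    median_r_by_subject = tapply(per_session$r, per_session$subject_id,
                                 stats::median),
    p = p,
    n_sessions = nrow(per_session)), class = "correlation_summary")
}

#' Cross-session null distribution of correlations
#'
#' Correlating metric A of one session with metric B of a *different* session
#' breaks any within-session coupling while preserving each series' smoothness;
#' the resulting distribution should be centered on zero and provides a
#' reference for the within-session coefficients. Series are truncated from
#' the start to the shorter common length of each ordered pair.
#'
#' @inheritParams within_session_correlations
#' @return Data.frame with `session_a`, `session_b`, `r` for every ordered
#'   pair of distinct sessions.
#' @export
cross_session_null <- function(sessions, metric_a, metric_b, min_bins = 3) {
  sd_check(length(sessions) >= 2, "invalid_parameter",
           "need at least 2 sessions")
  out <- list()
  for (i in seq_along(sessions)) {
    for (j in seq_along(sessions)) {
      if (i == j) next
      a <- sessions[[i]]$metrics[[metric_a]]
      b <- sessions[[j]]$metrics[[metric_b]]
      if (is.null(a) || is.null(b)) next
      m <- min(nrow(a), nrow(b))
      if (m < min_bins) next
      out[[length(out) + 1]] <- data.frame(
        session_a = sessions[[i]]$session_id,
        session_b = sessions[[j]]$session_id,
        r = stats::cor(a$value[seq_len(m)], b$value[seq_len(m)]))
    }
  }
  sd_check(length(out) > 0, "empty_output", "no comparable session pairs")
  do.call(rbind, out)
}

#' Variance-magnitude association between two metrics
#'
#' Tests whether sessions with large fluctuations in metric A also show large
#' fluctuations in metric B: the within-session variance of each binned metric
#' is computed per session, z-scored separately within each subject (so a
#' between-subject variance difference cannot create an artifactual pooled
#' correlation), and the z-scored variances are correlated across sessions.
#'
#' @inheritParams within_session_correlations
#' @return Object of class `variance_magnitude_result`: `per_session`
#'   data.frame (`session_id`, `subject_id`, `var_a`, `var_b`, `z_a`, `z_b`),
#'   `r`, `p`.
#' @export
variance_magnitude <- function(sessions, metric_a, metric_b) {
  rows <- lapply(sessions, function(s) {
    a <- s$metrics[[metric_a]]
    b <- s$metrics[[metric_b]]
    if (is.null(a) || is.null(b)) return(NULL)
    data.frame(session_id = s$session_id, subject_id = s$subject_id,
               var_a = stats::var(a$value), var_b = stats::var(b$value))
  })
  df <- do.call(rbind, rows)
  sd_check(!is.null(df) && nrow(df) >= 3, "invalid_parameter",
           "need at least 3 sessions")
  if (length(unique(df$subject_id)) == 1) {
    warning("single-subject cohort: z-scoring degenerates to a global z-score")
  }
  zscore <- function(x) (x - mean(x)) / stats::sd(x)
  df$z_a <- stats::ave(df$var_a, df$subject_id, FUN = zscore)
  df$z_b <- stats::ave(df$var_b, df$subject_id, FUN = zscore)
  ct <- pearson_r(df$z_a, df$z_b)
  structure(list(per_session = df, r = ct$r, p = ct$p),
            class = "variance_magnitude_result")
}

#' Bootstrap confidence interval for a median correlation
#'
#' Percentile interval from resampling sessions with replacement.
#'
#' @param r Per-session correlation coefficients.
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of resamples (default 10000).
#' @param seed Optional integer seed.
#' @return Numeric `c(lower, upper)`.
#' @export
median_r_ci <- function(r, level = 0.95, n_boot = 10000, seed = NULL) {
  sd_check(length(r) >= 2, "invalid_parameter", "need at least 2 values")
  with_seed(seed, {
    meds <- vapply(seq_len(n_boot), function(i) {
      stats::median(sample(r, length(r), replace = TRUE))
    }, numeric(1))
    unname(stats::quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}
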