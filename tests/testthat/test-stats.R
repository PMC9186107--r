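test_that("pearson_r reproduces hand-computed values", {
  expect_equal(pearson_r(1:4, 2 * (1:4) + 1)$r, 1)
  expect_equal(pearson_r(1:4, -(1:4))$r, -1)
  # cov = 1, sd_x = sd_y = sqrt(5/3): r = 1 / (5/3) = 0.8
  out <- pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(out$r, 0.8)
  expect_equal(out$p, 0.2, tolerance = 1e-10) # t transform, df = 2
  expect_error(pearson_r(1:3, rep(2, 3)), class = "undefined_correlation")
  expect_error(pearson_r(1:2, 1:2), class = "invalid_parameter")
})

brute_wilcoxon_p <- function(v) {
  v <- v[v != 0]
  n <- length(v)
  rnk <- rank(abs(v), ties.method = "average")
  W <- sum(rnk[v > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Ws <- apply(signs, 1, function(s) sum(rnk[as.logical(s)]))
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

test_that("wilcoxon exact branch equals brute-force sign enumeration", {
  # all-positive values are the extreme tail: p = 2 / 2^n
  expect_equal(wilcoxon_signed_rank(rep(0.5, 10))$p, 2 / 2^10)
  # perfectly balanced +/- pairs give p = 1
  expect_equal(wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))$p, 1)
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    v <- sample(c(-3:-1, 1:4), n, replace = TRUE)
    if (i %% 2 == 0) v <- v + rnorm(n, sd = 0.01) # break ties half the time
    expect_equal(wilcoxon_signed_rank(v)$p, brute_wilcoxon_p(v),
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon agrees with the reference implementation and handles edge cases", {
  set.seed(1)
  v <- rnorm(15)
  expect_equal(wilcoxon_signed_rank(v)$p,
               wilcox.test(v, exact = TRUE)$p.value, tolerance = 1e-12)
  # large-n branch: normal approximation with continuity correction
  set.seed(2)
  v2 <- rnorm(40, mean = 0.3)
  expect_equal(wilcoxon_signed_rank(v2)$p,
               wilcox.test(v2, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
  expect_warning(out <- wilcoxon_signed_rank(rep(0, 6)), "zero")
  expect_equal(out$p, 1)
  expect_error(wilcoxon_signed_rank(c(1, 2, 0, 0, 0)),
               class = "insufficient_data")
})

fake_session <- function(id, subject, a, b, centers = seq_along(a)) {
  list(session_id = id, subject_id = subject,
       metrics = list(
         a = data.frame(bin_center_min = centers[seq_along(a)], value = a),
         b = data.frame(bin_center_min = centers[seq_along(b)], value = b)))
}

test_that("within-session correlations align common bins and summarize by subject", {
  set.seed(3)
  sessions <- lapply(1:8, function(i) {
    x <- rnorm(10)
    fake_session(sprintf("s%d", i), if (i <= 4) "m1" else "m2",
                 x, -x + rnorm(10, sd = 0.1))
  })
  cs <- within_session_correlations(sessions, "a", "b")
  expect_equal(cs$n_sessions, 8)
  expect_lt(cs$median_r, -0.9)
  expect_lt(cs$p, 0.05)
  expect_named(cs$median_r_by_subject, c("m1", "m2"))
  # affine rescaling of either metric changes nothing
  sessions2 <- lapply(sessions, function(s) {
    s$metrics$a$value <- 3 * s$metrics$a$value - 7
    s$metrics$b$value <- -2 * s$metrics$b$value + 1
    s
  })
  cs2 <- within_session_correlations(sessions2, "a", "b")
  expect_equal(abs(cs2$per_session$r), abs(cs$per_session$r),
               tolerance = 1e-12)
  # bins present in only one series are dropped pairwise
  s_miss <- sessions
  s_miss[[1]]$metrics$a <- s_miss[[1]]$metrics$a[-c(2, 5), ]
  cs3 <- within_session_correlations(s_miss, "a", "b")
  expect_equal(cs3$per_session$n_bins[1], 8)
  # identical metrics give r = 1 in every session
  s_same <- lapply(sessions, function(s) {
    s$metrics$b <- s$metrics$a
    s
  })
  expect_equal(within_session_correlations(s_same, "a", "b")$per_session$r,
               rep(1, 8), tolerance = 1e-12)
  # sessions with too few common bins are excluded with a warning
  s_short <- c(sessions, list(fake_session("s9", "m2", rnorm(2), rnorm(2))))
  expect_warning(cs4 <- within_session_correlations(s_short, "a", "b"),
                 "common bins")
  expect_equal(cs4$n_sessions, 8)
})

test_that("cross-session nulls pair distinct sessions and center on zero", {
  set.seed(4)
  sessions <- lapply(1:10, function(i) {
    fake_session(sprintf("s%d", i), "m1", rnorm(12), rnorm(12))
  })
  null <- cross_session_null(sessions, "a", "b")
  expect_equal(nrow(null), 10 * 9)
  expect_lt(abs(mean(null$r)), 0.1)
  expect_equal(nrow(cross_session_null(sessions[1:2], "a", "b")), 2)
  # a duplicated session reproduces its own within-session correlation
  dup <- list(sessions[[1]], sessions[[1]])
  nd <- cross_session_null(dup, "a", "b")
  expect_equal(nd$r, rep(cor(sessions[[1]]$metrics$a$value,
                             sessions[[1]]$metrics$b$value), 2))
  expect_error(cross_session_null(sessions[1], "a", "b"),
               class = "invalid_parameter")
})

test_that("variance magnitude detects shared gain and z-scores within subject", {
  set.seed(5)
  base_a <- rnorm(12)
  base_b <- rnorm(12)
  sessions <- lapply(1:12, function(i) {
    g <- runif(1, 0.5, 3) # shared per-session gain scales both variances
    fake_session(sprintf("s%d", i), if (i %% 2) "m1" else "m2",
                 g * base_a, g * base_b)
  })
  vm <- variance_magnitude(sessions, "a", "b")
  expect_gt(vm$r, 0.95)
  for (subj in c("m1", "m2")) {
    z <- vm$per_session$z_a[vm$per_session$subject_id == subj]
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
  one_subj <- lapply(sessions[1:6], function(s) {
    s$subject_id <- "m1"
    s
  })
  expect_warning(variance_magnitude(one_subj, "a", "b"), "single-subject")
})

test_that("bootstrap CI for the median correlation is seeded and sensible", {
  r <- c(-0.5, -0.4, -0.45, -0.3, -0.6, -0.35, -0.2, -0.55)
  ci <- median_r_ci(r, n_boot = 2000, seed = 10)
  expect_identical(ci, median_r_ci(r, n_boot = 2000, seed = 10))
  expect_lt(ci[1], median(r))
  expect_gt(ci[2], median(r))
  expect_gte(ci[1], min(r))
  expect_lte(ci[2], max(r))
})
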