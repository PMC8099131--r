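test_that("event matching equals the exhaustive minimal-cost assignment", {
  # exact and shifted lists
  a <- c(0.3, 0.9, 1.5, 2.1)
  m0 <- match_events(a, a)
  expect_equal(m0$diff, rep(0, 4))
  m1 <- match_events(a, a + 0.01)
  expect_equal(m1$diff, rep(-0.01, 4), tolerance = 1e-12)
  # randomized jittered instances vs brute force
  set.seed(42)
  for (rep_i in 1:15) {
    n <- sample(3:6, 1)
    base <- cumsum(runif(n, 0.5, 0.8))
    b <- base + rnorm(n, 0, 0.05)
    drop_a <- runif(1) < 0.3
    aa <- if (drop_a) base[-sample(n, 1)] else base
    tol <- 0.25
    got <- match_events(aa, b, tol)
    oracle <- brute_match(aa, b, tol)
    expect_equal(nrow(got), oracle$n)
    expect_equal(sum(abs(got$diff)), oracle$cost, tolerance = 1e-9)
  }
})

test_that("difference statistics equal their defining formulas", {
  expect_equal(difference_stats(1:5, 1:5)$mean_abs, 0)
  cs <- difference_stats(1:5 + 2, 1:5)
  expect_equal(cs$mean_diff, 2); expect_equal(cs$sd_diff, 0)
  set.seed(7)
  a <- rnorm(20); b <- rnorm(20)
  ds <- difference_stats(a, b)
  expect_equal(ds$mean_diff, sum(a - b) / 20, tolerance = 1e-12)
  expect_equal(ds$sd_abs, sqrt(sum((abs(a - b) - mean(abs(a - b)))^2) / 19),
               tolerance = 1e-12)
  expect_equal(ds$min_diff, min(a - b))
  expect_equal(ds$max_diff, max(a - b))
})

test_that("correlations hit the degenerate cases exactly", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_true(pearson_r(x, rep(1, 5))$zero_variance)
  expect_equal(icc_c1(x, x)$icc, 1)
  expect_equal(icc_a1(x, x)$icc, 1)
})

test_that("ICCs match an independent ANOVA mean-squares oracle", {
  set.seed(11)
  for (rep_i in 1:20) {
    n <- sample(4:10, 1)
    x <- rnorm(n, 10, 2)
    y <- x + rnorm(n, 0.5, 0.8)   # biased second rater
    ms <- anova_ms(x, y)
    c1 <- icc_c1(x, y); a1 <- icc_a1(x, y)
    expect_equal(c1$icc, (ms$msr - ms$mse) / (ms$msr + ms$mse),
                 tolerance = 1e-10)
    expect_equal(a1$icc,
                 (ms$msr - ms$mse) /
                   (ms$msr + ms$mse + (2 / n) * (ms$msc - ms$mse)),
                 tolerance = 1e-10)
    # agreement penalizes rater bias when MS_C >= MS_E
    if (ms$msc >= ms$mse) expect_lte(a1$icc, c1$icc + 1e-12)
  }
})

test_that("repeated-measures ANOVA matches hand-computed sums of squares", {
  # minimal case, sums of squares by definition
  m <- matrix(c(1, 2, 3, 5, 4, 9), nrow = 2)
  n <- 2; k <- 3
  grand <- mean(m)
  ss_sys <- n * sum((colMeans(m) - grand)^2)
  ss_sub <- k * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_sys - ss_sub
  F_hand <- (ss_sys / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  res <- rm_anova_bonferroni(m)
  expect_equal(res$F, F_hand, tolerance = 1e-10)
  expect_equal(res$df, c(k - 1, (n - 1) * (k - 1)))

  # identical systems: no effect
  ident <- matrix(rep(rnorm(6), 3), ncol = 3)
  res0 <- rm_anova_bonferroni(ident)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  expect_true(all(res0$posthoc$p_adj == 1))

  # a single offset system is flagged by exactly its two comparisons
  set.seed(21)
  base <- rnorm(60, 0.6, 0.08)
  m3 <- cbind(A = base + rnorm(60, 0, 0.01),
              B = base + rnorm(60, 0, 0.01),
              C = base + 0.05 + rnorm(60, 0, 0.01))
  res3 <- rm_anova_bonferroni(m3)
  expect_gt(res3$F, 10)
  ph <- res3$posthoc
  expect_gt(ph$p_adj[ph$pair == "A v B"], 0.05)
  expect_lt(ph$p_adj[ph$pair == "A v C"], 0.05)
  expect_lt(ph$p_adj[ph$pair == "B v C"], 0.05)
})

test_that("lag-zero cross-correlation of shifted sinusoids equals cos(phase)", {
  t <- 2 * pi * (0:999) / 1000
  expect_equal(xcorr_lag0(sin(t), sin(t)), 1)
  expect_equal(xcorr_lag0(sin(t), -sin(t)), -1)
  for (phi in c(0.3, 1.1, 2.0, 2.9))
    expect_equal(xcorr_lag0(sin(t), sin(t + phi)), cos(phi),
                 tolerance = 1e-6)
})

test_that("MAE and walkway binning follow their definitions", {
  a <- matrix(1:12, 3); b <- a + 3
  expect_equal(mae_curves(a, b), 3)
  expect_equal(mae_curves(a, a), 0)
  expect_equal(as.character(bin_by_walkway(c(-0.7, 0, 0.6))),
               c("Start", "Middle", "End"))
})

test_that("a run compared with itself shows perfect agreement", {
  run <- default_run()
  rep <- compare_runs(run, run)
  for (e in rep$events) expect_equal(e$mean_abs, 0)
  for (p in rep$spatiotemporal) {
    expect_equal(p$mean_abs, 0)
    if (!is.null(p$r)) {
      expect_equal(p$r, 1, tolerance = 1e-9)
      expect_equal(p$icc_c1, 1, tolerance = 1e-9)
      expect_equal(p$icc_a1, 1, tolerance = 1e-9)
    }
  }
  for (a in rep$angles) {
    expect_equal(a$mae_deg, 0)
    expect_equal(a$xcorr_lag0, 1, tolerance = 1e-12)
  }
  expect_equal(rep$gait_speed$diff, 0)
})

test_that("pose and mocap runs of the same bout agree at the reported scale", {
  rep <- compare_runs(mocap_run(), default_run())
  expect_lt(abs(rep$spatiotemporal$step_time$mean_abs), 0.02)
  expect_lt(abs(rep$spatiotemporal$step_length$mean_abs), 0.01)
  for (a in rep$angles) {
    expect_lt(a$mae_deg, 1)
    expect_gt(a$xcorr_lag0, 0.99)
  }
})
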