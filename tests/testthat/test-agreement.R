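pair_from_diffs <- function(d, crit = 10) {
  paired_sample(seq_along(d), 1, device = crit + d, criterion = rep(crit, length(d)))
}

pair_diffs_oracle <- function(p) p$device - p$criterion

test_that("bias and limits of agreement have their closed forms", {
  p0 <- pair_from_diffs(rep(0, 6))
  ba0 <- mean_bias_loa(p0)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  p1 <- pair_from_diffs(c(-1, 1))
  ba1 <- mean_bias_loa(p1)
  expect_equal(ba1$bias, 0)
  expect_equal(ba1$sd_diff, sqrt(2), tolerance = 1e-12)
  expect_equal(ba1$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba1$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)

  expect_error(mean_bias_loa(pair_from_diffs(1)), "at least 2")
})

test_that("LoA width equals twice the multiplier times the SD", {
  for (s in 1:5) {
    p <- random_paired_sample(40, seed = 100 + s)
    ba <- mean_bias_loa(p)
    expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sd(pair_diffs_oracle(p)),
                 tolerance = 1e-9)
    expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  }
})

test_that("MAE and RMSE match hand values and satisfy their ordering", {
  p <- pair_from_diffs(c(3, -4))
  expect_equal(mae(p), 3.5)
  expect_equal(rmse(p), sqrt(12.5), tolerance = 1e-12)

  same <- paired_sample(1:4, 1, device = c(1, 2, 3, 4), criterion = c(1, 2, 3, 4))
  expect_equal(mae(same), 0)
  expect_equal(rmse(same), 0)

  for (s in 1:5) {
    p <- random_paired_sample(30, seed = 200 + s)
    expect_gte(rmse(p), mae(p))
    expect_gte(rmse(p), abs(mean_bias_loa(p)$bias))
  }
  # equality iff all |d| equal
  eq <- pair_from_diffs(c(2, -2, 2))
  expect_equal(rmse(eq), mae(eq), tolerance = 1e-12)
  neq <- pair_from_diffs(c(1, -3))
  expect_gt(rmse(neq), mae(neq))
})

test_that("first-trial mode keeps one trial per participant", {
  p <- paired_sample(
    participant_id = c(1, 1, 1, 2, 2, 3, 3, 3),
    trial_id = c(2, 1, 3, 1, 2, 3, 1, 2),
    device = 1:8, criterion = rep(0, 8)
  )
  q <- strideval:::filter_loa_mode(p, "first_trial")
  expect_equal(nrow(q), 3)
  expect_equal(sort(q$device), c(2, 4, 7))  # earliest trial of each participant
  ba <- mean_bias_loa(p, mode = "first_trial")
  expect_equal(ba$n, 3)
})

test_that("Spearman magnitude bands use the printed half-open intervals", {
  crit <- 1:5
  # permutations engineered to exact rank-correlation values
  expect_equal(spearman_with_magnitude(
    paired_sample(1:5, 1, c(1, 3, 5, 2, 4), crit))$rho, 0.5)
  expect_equal(spearman_with_magnitude(
    paired_sample(1:5, 1, c(1, 3, 5, 2, 4), crit))$magnitude, "large")
  expect_equal(spearman_with_magnitude(
    paired_sample(1:5, 1, c(1, 2, 3, 5, 4), crit))$rho, 0.9)
  expect_equal(spearman_with_magnitude(
    paired_sample(1:5, 1, c(1, 2, 3, 5, 4), crit))$magnitude, "nearly perfect")
  expect_equal(spearman_with_magnitude(
    paired_sample(1:5, 1, c(2, 5, 3, 1, 4), crit))$rho, 0)
  expect_equal(spearman_with_magnitude(
    paired_sample(1:5, 1, c(2, 5, 3, 1, 4), crit))$magnitude, "trivial")

  mono <- paired_sample(1:6, 1, device = exp(1:6), criterion = 1:6)
  expect_equal(spearman_with_magnitude(mono)$rho, 1)

  degen <- paired_sample(1:4, 1, device = rep(2, 4), criterion = 1:4)
  expect_true(spearman_with_magnitude(degen)$flagged)
})

test_that("log Bland-Altman is exact for a pure multiplicative offset", {
  crit <- withr::with_seed(5, runif(50, 2, 8))
  p <- paired_sample(1:50, 1, device = 1.05 * crit, criterion = crit)
  lb <- log_bland_altman(p)
  expect_equal(lb$percent_bias, 5, tolerance = 1e-9)
  expect_equal(lb$percent_loa_high - lb$percent_loa_low, 0, tolerance = 1e-9)
  expect_equal(lb$n_excluded_nonpositive, 0)

  ident <- paired_sample(1:10, 1, device = crit[1:10], criterion = crit[1:10])
  lbi <- log_bland_altman(ident)
  expect_equal(c(lbi$percent_bias, lbi$percent_loa_low, lbi$percent_loa_high),
               c(0, 0, 0), tolerance = 1e-12)
})

test_that("non-positive pairs are excluded and counted", {
  p <- paired_sample(1:5, 1,
                     device = c(2, 3, -1, 4, 0),
                     criterion = c(2, 3, 2, 4, 2))
  lb <- log_bland_altman(p)
  expect_equal(lb$n_excluded_nonpositive, 2)
  expect_equal(lb$n, 3)
  all_bad <- paired_sample(1:3, 1, device = c(-1, -2, 0), criterion = c(1, 1, 1))
  expect_error(log_bland_altman(all_bad), "positive")
})

test_that("log-ratio bias recovers a known median ratio", {
  n <- 1e4
  withr::with_seed(909, {
    crit <- runif(n, 5, 9)
    dev <- 0.93 * crit * exp(rnorm(n, 0, 0.04))
  })
  p <- paired_sample(rep(1:20, length.out = n), 1, dev, crit)
  lb <- log_bland_altman(p)
  expect_equal(lb$percent_bias, -7.0, tolerance = 0.3)
  expect_lt(lb$percent_loa_low, lb$percent_bias)
  expect_gt(lb$percent_loa_high, lb$percent_bias)
})

test_that("log and linear bias agree to first order for small errors", {
  withr::with_seed(11, {
    crit <- runif(500, 5, 10)
    dev <- crit * (1 + runif(500, -0.03, 0.03)) + 0.02
  })
  p <- paired_sample(1:500, 1, dev, crit)
  ba <- mean_bias_loa(p)
  lb <- log_bland_altman(p)
  rel_bias_pct <- 100 * ba$bias / mean((p$device + p$criterion) / 2)
  expect_lt(abs(lb$percent_bias - rel_bias_pct), 0.5)
})

test_that("heteroscedasticity screen flags proportional error and passes null", {
  m <- seq(1, 10, length.out = 60)
  s <- rep(c(1, -1), 30)
  p <- paired_sample(1:60, 1, device = m + m * s * 0.2, criterion = m - m * s * 0.2)
  h <- heteroscedasticity_check(p)
  expect_equal(h$rho, 1, tolerance = 1e-9)
  expect_equal(h$verdict, "detected")

  const <- pair_from_diffs(rep(0.5, 10))
  expect_true(heteroscedasticity_check(const)$flagged)

  verdicts <- vapply(1:100, function(s) {
    withr::with_seed(4000 + s, {
      crit <- runif(1000, 5, 10)
      dev <- crit + rnorm(1000, 0, 0.3)
    })
    heteroscedasticity_check(paired_sample(1:1000, 1, dev, crit))$verdict
  }, character(1))
  expect_gte(mean(verdicts == "none_detected"), 0.90)
})

test_that("the KS screen behaves on clear cases", {
  x <- withr::with_seed(6, rnorm(500))
  kn <- ks_normality(x)
  expect_true(kn$normal)
  ke <- ks_normality(withr::with_seed(7, rexp(200)))
  expect_false(ke$normal)
  kc <- ks_normality(rep(1, 10))
  expect_true(kc$flagged)
  expect_false(kc$normal)
  expect_error(ks_normality(c(1, 2)), "at least 5")
  # uncorrected variant exists and is more conservative here
  ku <- ks_normality(x, lilliefors = FALSE)
  expect_true(ku$normal)
})

test_that("report rows satisfy the structural invariants", {
  samples <- list(
    a = random_paired_sample(60, seed = 1),
    b = random_paired_sample(60, seed = 2),
    c = random_paired_sample(60, seed = 3)
  )
  rep6 <- build_report(samples)
  expect_equal(nrow(rep6), 6)  # 3 variables x 2 modes
  expect_true(all(rep6$rmse >= rep6$mae))
  expect_true(all(rep6$rmse >= abs(rep6$bias) - 1e-12))
  expect_true(all(rep6$loa_low <= rep6$bias & rep6$bias <= rep6$loa_high))
})

test_that("Bland-Altman plots carry the reference lines", {
  p <- random_paired_sample(50, seed = 9)
  g <- plot_bland_altman(p)
  expect_s3_class(g, "ggplot")
  built <- ggplot2::ggplot_build(g)
  yint <- unlist(lapply(built$data[-1], function(d) d$yintercept))
  ba <- mean_bias_loa(p)
  expect_true(any(abs(yint - ba$bias) < 1e-9))
  expect_true(any(abs(yint - ba$loa_low) < 1e-9))
})
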