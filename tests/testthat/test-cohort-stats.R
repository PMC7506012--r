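# Descriptives with normality routing, two-group tests, correlation,
# propensity matching, reproducibility metrics and sample size.

test_that("describe routes by Shapiro-Wilk normality", {
  set.seed(31)
  norm <- rnorm(200)
  expect_equal(describe(norm)$route, "mean_sd")
  lnorm <- exp(rnorm(200))
  expect_equal(describe(lnorm)$route, "median_iqr")
  b <- describe(c(rep(1, 16), rep(0, 4)), kind = "binary")
  expect_equal(b$text, "16 (80%)")
  expect_warning(describe(rep(3, 10)), "constant")
  expect_error(describe(c(1, 2)), "n >= 3")
})

test_that("group comparison picks t, Mann-Whitney, chi-square or Fisher", {
  set.seed(320)
  x <- rnorm(30, 5); y <- rnorm(30, 5)
  r <- compare_groups(x, y)
  expect_equal(r$test, "t")
  r2 <- compare_groups(exp(rnorm(250)), exp(rnorm(250, 0.3)))
  expect_equal(r2$test, "wilcoxon")
  # identical constant groups route to the rank test with p = 1
  r3 <- compare_groups(rep(2, 10), rep(2, 10))
  expect_equal(r3$test, "wilcoxon")
  expect_equal(r3$p_value, 1)
  # published 2x2 row: 16/20 vs 13/20 -> uncorrected chi-square p = 0.29
  r4 <- compare_groups(c(rep(1, 16), rep(0, 4)), c(rep(1, 13), rep(0, 7)),
                       kind = "binary")
  expect_equal(r4$test, "chisq")
  expect_equal(round(r4$p_value, 2), 0.29)
  # small expected counts route to Fisher
  r5 <- compare_groups(c(rep(1, 2), rep(0, 8)), c(rep(1, 1), rep(0, 9)),
                       kind = "binary")
  expect_equal(r5$test, "fisher")
})

test_that("correlation routes Pearson/Spearman and recovers rho", {
  x <- 1:20
  expect_equal(correlate(x, x)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  set.seed(33)
  n <- 5000
  z <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, 0.54, 0.54, 1), 2))
  r <- correlate(z[, 1], z[, 2])
  expect_equal(r$method, "pearson")
  expect_lt(abs(r$r - 0.54), 0.03)
  sk <- exp(z[, 1])
  expect_equal(correlate(sk, z[, 2])$method, "spearman")
  expect_error(correlate(rep(1, 10), 1:10), "constant")
})

test_that("propensity matching is greedy, calipered and balance-improving", {
  n <- 40
  df <- data.frame(age = rep(c(60, 65, 70, 75), 10),
                   bmi = rep(c(22, 24), 20))
  tr <- rep(c(TRUE, FALSE), each = 20)
  set.seed(34)
  m <- propensity_match(df, tr, c("age", "bmi"), caliper = 0.5)
  expect_equal(nrow(m$pairs), 20)
  expect_true(all(m$pairs$distance <= 0.5))
  expect_true(all(tr[m$pairs$treated]))
  expect_true(all(!tr[m$pairs$control]))
  expect_false(any(duplicated(m$pairs$control)))
  # identical covariate rows match at distance zero
  expect_true(all(m$pairs$distance < 1e-12))
  # caliper 0 with distinct scores -> no matches
  df2 <- data.frame(x = c(rnorm(10, 2), rnorm(10, -2)))
  tr2 <- rep(c(TRUE, FALSE), each = 10)
  m2 <- propensity_match(df2, tr2, "x", caliper = 0)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$n_unmatched_treated, 10)
  # confounded cohort: matching improves every covariate's balance
  set.seed(35)
  nn <- 300
  age <- rnorm(nn, 65, 8)
  bmi <- rnorm(nn, 24, 3)
  p <- plogis(-14 + 0.18 * age + 0.1 * bmi)
  grp <- runif(nn) < p
  dat <- data.frame(age = age, bmi = bmi)
  pre <- standardized_differences(dat, grp, c("age", "bmi"))
  mm <- propensity_match(dat, grp, c("age", "bmi"), caliper = 0.1)
  keep <- c(mm$pairs$treated, mm$pairs$control)
  post <- standardized_differences(dat, grp, c("age", "bmi"), subset = keep)
  expect_true(all(post < pre))
  expect_error(propensity_match(dat, rep(TRUE, nn), "age"), "non-empty")
})

test_that("Bland-Altman bias and limits follow their definitions", {
  a <- c(1, 2, 3, 4)
  expect_equal(bland_altman(a, a), list(bias = 0, sd_diff = 0,
                                        loa_low = 0, loa_high = 0))
  r <- bland_altman(a, a - 2)
  expect_equal(r$bias, 2)
  expect_equal(r$sd_diff, 0)
  set.seed(36)
  x <- rnorm(10000, 30, 4)
  o1 <- x + rnorm(10000, 0.48, 1.5 / sqrt(2))
  o2 <- x + rnorm(10000, 0, 1.5 / sqrt(2))
  ba <- bland_altman(o1, o2)
  expect_lt(abs(ba$bias - 0.48), 0.05)
  expect_lt(abs((ba$loa_high - ba$loa_low) / 2 - 1.96 * 1.5), 0.1)
  # antisymmetry of the bias, identical limit half-width
  ba2 <- bland_altman(o2, o1)
  expect_equal(ba2$bias, -ba$bias)
  expect_equal(ba2$loa_high - ba2$loa_low, ba$loa_high - ba$loa_low)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("within-subject CV is scale-invariant and consistent", {
  a <- c(10, 12, 14); b <- c(10, 12, 14)
  expect_equal(cv_reproducibility(a, b), 0)
  set.seed(37)
  x <- rnorm(20000, 30, 4)
  o1 <- x + rnorm(20000, 0, 1)
  o2 <- x + rnorm(20000, 0, 1)
  cv <- cv_reproducibility(o1, o2)
  expect_lt(abs(cv - 1 / 30 * 100), 0.15)
  expect_equal(cv_reproducibility(3.3 * o1, 3.3 * o2), cv, tolerance = 1e-12)
  expect_error(cv_reproducibility(c(-5, -6), c(-5, -6)), "grand mean")
})

test_that("ICC(2,1) matches agreement limits and variance components", {
  a <- rnorm(50, 20, 5)
  expect_equal(icc(a, a)$icc, 1)
  set.seed(38)
  subj <- rnorm(2000, 30, 4.5)
  e1 <- subj + rnorm(2000, 0, 0.9)
  e2 <- subj + rnorm(2000, 0, 0.9)
  r <- icc(e1, e2)
  target <- 4.5^2 / (4.5^2 + 0.9^2)
  expect_lt(abs(r$icc - target), 0.01)
  expect_true(r$ci_lower < r$icc && r$icc < r$ci_upper)
  # shuffling one reading destroys agreement
  r0 <- suppressWarnings(icc(e1, sample(e2)))
  expect_lt(abs(r0$icc), 0.1)
  expect_error(icc(1:4, 1:4), "n >= 5")
})

test_that("t-test sample size uses the exact noncentral-t solution", {
  expect_equal(sample_size_ttest(5, 5, 0.80, 0.05), 17)
  # the normal approximation would give 2*(1.96+0.8416)^2 = 15.7 -> 16
  approx_n <- ceiling(2 * (qnorm(0.975) + qnorm(0.80))^2)
  expect_equal(approx_n, 16)
  expect_gt(sample_size_ttest(5, 5, 0.80, 0.05), approx_n)
  expect_equal(sample_size_ttest(1e6, 1, 0.8, 0.05), 2)
  # cross-check against the base-R power solver over a grid
  for (delta in c(2, 5, 8)) for (sd in c(4, 6)) {
    mine <- sample_size_ttest(delta, sd, 0.80, 0.05)
    ref <- ceiling(stats::power.t.test(delta = delta, sd = sd, power = 0.80,
                                       sig.level = 0.05)$n)
    expect_true(abs(mine - ref) <= 1)
    # and the returned n really attains the power while n-1 does not
    pw <- function(n) {
      df <- 2 * (n - 1)
      ncp <- delta / (sd * sqrt(2 / n))
      tc <- qt(0.975, df)
      1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
    }
    expect_gte(pw(mine), 0.80)
    if (mine > 2) expect_lt(pw(mine - 1), 0.80)
  }
  # monotonicity: non-increasing in delta, non-decreasing in sd and power
  ns_delta <- vapply(c(2, 4, 6, 8), sample_size_ttest, numeric(1),
                     sd = 5, power = 0.8, alpha = 0.05)
  expect_true(all(diff(ns_delta) <= 0))
  ns_sd <- vapply(c(3, 5, 7), function(s)
    sample_size_ttest(5, s, 0.8, 0.05), numeric(1))
  expect_true(all(diff(ns_sd) >= 0))
  ns_pow <- vapply(c(0.7, 0.8, 0.9), function(p)
    sample_size_ttest(5, 5, p, 0.05), numeric(1))
  expect_true(all(diff(ns_pow) >= 0))
  expect_error(sample_size_ttest(5, 5, 0.04, 0.05), "power must exceed")
  expect_error(sample_size_ttest(-1, 5), "positive")
})
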