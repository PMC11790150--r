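test_that("adjusted Fisher-Pearson skewness matches brute-force evaluation", {
  # hand evaluation on {1,2,9}: g1 = m3/m2^1.5 = 0.66553,
  # G1 = g1 * sqrt(n(n-1))/(n-2) = 1.63006
  rep3 <- skewness_report(c(1, 2, 9))
  expect_equal(rep3$skewness, 1.63006, tolerance = 1e-4)
  expect_equal(rep3$se_skewness, sqrt(6 * 3 * 2 / (1 * 4 * 6)))
  # exact symmetry -> zero skewness
  expect_equal(skewness_report(rep(c(-1, 0, 1), 10))$skewness, 0)
})

test_that("skewness standard error reproduces the large-sample formula", {
  se <- skewness_report(seq_len(10000))$se_skewness
  expect_equal(se, 0.02449, tolerance = 1e-4)
  expect_equal(round(se, 3), 0.024)
})

test_that("skewness z score carries the sign of the skewness", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(50) + sample(c(-1, 1), 1) * rexp(50)
    rep <- skewness_report(x)
    expect_gt(rep$se_skewness, 0)
    expect_identical(sign(rep$z_score), sign(rep$skewness))
  }
  expect_error(skewness_report(rep(2, 10)), class = "strawsim_domain_error")
  expect_error(skewness_report(c(1, 2)), class = "strawsim_domain_error")
})

test_that("one-sample K-S statistic is tiny for quantile-aligned samples", {
  n <- 400
  x <- qnorm((seq_len(n) - 0.5) / n)
  res <- ks_one_sample(x, pnorm)
  expect_lte(res$statistic, 0.5 / n + 1e-12)
  expect_gt(res$p_value, 0.999)
})

test_that("one-sample K-S holds its nominal type-I error", {
  set.seed(19)
  rejections <- vapply(seq_len(400), function(i) {
    ks_one_sample(rnorm(1000), pnorm)$p_value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("two-sample K-S separates different laws and accepts identical ones", {
  x <- rnorm(100)
  same <- ks_two_sample(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(23)
  apart <- ks_two_sample(rnorm(1000), rnorm(1000, mean = 2))
  expect_lt(apart$p_value, 1e-6)
  expect_error(ks_two_sample(numeric(0), x), class = "strawsim_domain_error")
})

test_that("normal fit recovers moments and is translation equivariant", {
  set.seed(29)
  x <- rnorm(5000, 3, 2)
  f <- fit_normal(x)
  expect_equal(f$mean, mean(x))
  expect_equal(f$sd, sd(x))
  expect_gte(f$ks_stat, 0)
  expect_lte(f$ks_stat, 1)
  f_shift <- fit_normal(x + 7)
  expect_equal(f_shift$mean, f$mean + 7)
  expect_equal(f_shift$sd, f$sd)
  expect_equal(f_shift$ks_stat, f$ks_stat, tolerance = 1e-10)
})

test_that("shifted-lognormal fit recovers the canonical lognormal", {
  set.seed(37)
  x <- exp(rnorm(1e5))
  f <- fit_lognormal3(x)
  expect_lt(abs(f$s - 1), 0.05)
  expect_lt(abs(f$loc), 0.05)
  expect_lt(abs(f$scale - 1), 0.05)
  expect_lt(f$loc, min(x))
})

test_that("shifted-lognormal fit recovers moments in the small-shape regime", {
  # generating parameters of the near-normal regime; raw parameters are
  # near-unidentifiable there, so recovery is asserted on moments
  s <- 0.0411; loc <- -91.0223; scale <- 105.2339
  set.seed(41)
  x <- loc + scale * exp(s * rnorm(1e5))
  f <- fit_lognormal3(x)
  fit_mean <- f$loc + f$scale * exp(f$s^2 / 2)
  fit_sd <- f$scale * sqrt((exp(f$s^2) - 1) * exp(f$s^2))
  true_mean <- loc + scale * exp(s^2 / 2)
  true_sd <- scale * sqrt((exp(s^2) - 1) * exp(s^2))
  expect_lt(abs(fit_mean - true_mean) / true_mean, 0.01)
  expect_lt(abs(fit_sd - true_sd) / true_sd, 0.05)
})

test_that("lognormal likelihood at the optimum beats moment-based starts", {
  set.seed(43)
  samples <- list(exp(rnorm(2000)),
                  run_cohort(small_config(seed = 44, n_flowers = 3000L))$records$weight)
  for (x in samples) {
    f <- fit_lognormal3(x)
    loc0 <- min(x) - 0.01 * diff(range(x))
    y0 <- log(x - loc0)
    ll0 <- sum(dlnorm(x - loc0, mean(y0), sd(y0), log = TRUE))
    expect_gte(f$log_likelihood, ll0)
    expect_lt(f$loc, min(x))
    expect_gt(f$s, 0)
  }
})

test_that("Q-Q points sit on the identity line for affine quantile input", {
  n <- 100
  x <- 5 + 2 * qnorm((seq_len(n) - 0.5) / n)
  qq <- qq_points(x)
  expect_lt(max(abs(qq$theoretical - qq$sample)), 1e-8)
  # normal data correlates near-perfectly with its theoretical quantiles
  set.seed(47)
  qq2 <- qq_points(rnorm(5000))
  expect_gt(cor(qq2$theoretical, qq2$sample), 0.99)
})

test_that("Q-Q upper tail rises above the line for right-skewed data", {
  set.seed(53)
  qq <- qq_points(exp(rnorm(5000)))
  top <- tail(order(qq$theoretical), 50)
  expect_true(all(qq$sample[top] > qq$theoretical[top]))
})

test_that("pooled chi-square accepts samples drawn from the tested pmf", {
  probs <- dbinom(0:20, 20, 0.3)
  set.seed(59)
  x <- sample(0:20, 5e4, replace = TRUE, prob = probs)
  res <- chisq_pmf_test(x, probs)
  expect_gt(res$p_value, 0.001)
  expect_gte(res$df, 1)
  # and rejects a clearly wrong pmf
  wrong <- dbinom(0:20, 20, 0.5)
  expect_lt(chisq_pmf_test(x, wrong)$p_value, 1e-10)
  expect_error(chisq_pmf_test(c(-1, 2), probs), class = "strawsim_domain_error")
})

test_that("Freedman-Diaconis edges cover the sample", {
  set.seed(61)
  x <- rnorm(1000)
  edges <- fd_bin_edges(x)
  expect_lte(edges[1], min(x))
  expect_gte(edges[length(edges)], max(x))
  expect_true(all(diff(edges) > 0))
})
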