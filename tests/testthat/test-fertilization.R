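test_that("stigma receptivity decays with flower age", {
  fm <- fertilization_model()
  expect_equal(stigma_receptivity(1, fm), exp(-0.01), tolerance = 1e-10)
  expect_equal(stigma_receptivity(5, fm), 0.0375, tolerance = 1e-3)
  r <- stigma_receptivity(1:10, fm)
  expect_true(all(diff(r) < 0))
  expect_true(all(r > 0 & r <= 1))
  # vanishing decay coefficient leaves the stigma fully receptive
  nodecay <- fertilization_model(decay_coeff = 1e-15)
  expect_equal(stigma_receptivity(1:5, nodecay), rep(1, 5), tolerance = 1e-9)
  expect_error(stigma_receptivity(0, fm), class = "strawsim_domain_error")
})

test_that("fertilization probability is compatibility times receptivity", {
  fm <- fertilization_model()
  expect_equal(fertilization_prob(1, fm), 0.79204, tolerance = 1e-4)
  expect_equal(fertilization_prob(3, fm), 0.4747, tolerance = 1e-3)
  expect_identical(fertilization_prob(1, fertilization_model(compatibility = 0)), 0)
  expect_true(all(fertilization_prob(1:5, fm) <= stigma_receptivity(1:5, fm)))
  # strictly decreasing in day, strictly increasing in compatibility
  expect_true(all(diff(fertilization_prob(1:8, fm)) < 0))
  probs_by_c <- vapply(seq(0.1, 1, by = 0.1),
                       function(c) fertilization_prob(2, fertilization_model(compatibility = c)),
                       numeric(1))
  expect_true(all(diff(probs_by_c) > 0))
})

test_that("binomial fertilization respects its bounds and mean", {
  expect_identical(sample_fertilized(0, 0.8), 0L)
  expect_identical(sample_fertilized(100, 1.0), 100L)
  set.seed(11)
  draws <- sample_fertilized(rep(100L, 1e5), 0.79204)
  expect_true(all(draws <= 100))
  se <- sqrt(100 * 0.79204 * (1 - 0.79204) / 1e5)
  expect_lt(abs(mean(draws) - 79.204), 4 * se)
  expect_error(sample_fertilized(10, 1.2), class = "strawsim_domain_error")
  expect_error(sample_fertilized(-5, 0.5), class = "strawsim_domain_error")
})

test_that("achene accumulation sums the daily fertilized counts", {
  expect_identical(accumulate_achenes(c(60, 55, 40, 15, 1)), 171)
  expect_identical(accumulate_achenes(rep(0, 5)), 0)
  expect_error(accumulate_achenes(numeric(0)), class = "strawsim_domain_error")
  expect_error(accumulate_achenes(c(3, -1)), class = "strawsim_domain_error")
})

test_that("Monte Carlo achene totals match the closed-form expectation", {
  # E[Z_sum] = grains * lambda * c * sum_n exp(-0.01 n^3.6) ~ 246.29
  es <- expected_summaries(default_config())
  expect_equal(es$mean_zsum, 25 * 4.5 * 0.8 * sum(exp(-0.01 * (1:5)^3.6)))
  expect_equal(es$mean_zsum, 246.29, tolerance = 1e-4)
  res <- run_cohort(default_config(seed = 3))
  se <- sqrt(es$var_zsum / 10000)
  expect_lt(abs(mean(res$records$z_sum) - es$mean_zsum), 4 * se)
})

test_that("daily fertilized grains never exceed daily pollen", {
  for (s in 1:3) {
    res <- run_cohort(small_config(seed = s, n_flowers = 500L))
    z <- as.matrix(res$records[paste0("z", 1:5)])
    y <- as.matrix(res$records[paste0("y", 1:5)])
    expect_true(all(z <= y))
    expect_true(all(z >= 0))
  }
})

test_that("convolution pmf reproduces closed-form moments exactly", {
  vm <- tiny_visit()
  fm <- fertilization_model()
  pmf <- exact_zsum_pmf(vm, fm)
  expect_gte(sum(pmf), 1 - 1e-8)
  mom <- pmf_moments(pmf)
  es <- expected_summaries(simulation_config(visit = vm, fert = fm))
  expect_equal(mom$mean, es$mean_zsum, tolerance = 1e-8)
  expect_equal(mom$var, es$var_zsum, tolerance = 1e-8)
})

test_that("convolution pmf degenerates correctly", {
  # visits almost surely zero -> no fertilization possible
  pmf0 <- exact_zsum_pmf(visit_model(lambda_visits = 1e-12, grains_per_visit = 2))
  expect_equal(pmf0[1], 1, tolerance = 1e-9)
  # fully self-incompatible -> point mass at zero achenes
  pmfc <- exact_zsum_pmf(tiny_visit(), fertilization_model(compatibility = 0))
  expect_equal(pmfc[1], 1, tolerance = 1e-12)
  # intractable support is refused with guidance
  expect_error(exact_zsum_pmf(visit_model(), max_support = 100L),
               "support too large", class = "strawsim_domain_error")
})
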