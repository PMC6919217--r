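test_that("generation is deterministic given the seed and leaves RNG state alone", {
  p <- synthetic_params(n = 500, seed = 99)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(synthetic_params(n = 500, seed = 100))))

  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_cohort(p)); after <- runif(1)
  expect_identical(before, after)
})

test_that("parameter validation rejects degenerate models", {
  expect_error(synthetic_params(n = 0), class = "icusurv_parameter_error")
  expect_error(synthetic_params(los_sigma = 0), class = "icusurv_parameter_error")
  expect_error(synthetic_params(los_cap_days = -1), class = "icusurv_parameter_error")
  expect_error(synthetic_params(beta0 = Inf), class = "icusurv_parameter_error")
})

test_that("with no LOS or age effect, survival is flat in length of stay", {
  p <- synthetic_params(n = 40000, beta_los = 0, beta_age = 0, beta0 = -2, seed = 5)
  cohort <- generate_cohort(p)
  truth <- 1 - plogis(-2)
  curve <- estimate_conditional_survival(cohort, min_at_risk = 200)
  # empirical survival near the constant truth at every reported day
  expect_true(all(abs(curve$cs - truth) < 0.05))
  oracle <- analytic_conditional_survival(p, days = 0:10)
  expect_equal(oracle$true_cs, rep(truth, 11), tolerance = 1e-8)
})

test_that("analytic oracle handles a point-mass LOS with constant death risk", {
  # LOS concentrated at 3 days, pi identically 0.2
  p <- synthetic_params(los_mu = log(3), los_sigma = 1e-6, beta_los = 0,
                        beta_age = 0, beta0 = log(0.2 / 0.8))
  oracle <- analytic_conditional_survival(p, days = 0:3)
  expect_equal(oracle$true_cs, rep(0.8, 4), tolerance = 1e-7)
  # conditioning far beyond the point mass is degenerate
  expect_error(analytic_conditional_survival(p, days = 40),
               class = "icusurv_domain_error")
})

test_that("analytic oracle agrees with a large Monte-Carlo estimate", {
  p <- synthetic_params(n = 1, seed = 1)
  days <- c(0, 1, 3, 5, 8, 10, 15)
  oracle <- analytic_conditional_survival(p, days)

  set.seed(314)
  n <- 5e5
  f_min <- pnorm((p$age_min - p$age_mean) / p$age_sd)
  age <- p$age_mean + p$age_sd * qnorm(f_min + runif(n) * (1 - f_min))
  los <- rlnorm(n, p$los_mu, p$los_sigma)
  pi_death <- plogis(p$beta0 + p$beta_los * pmin(los, p$los_cap_days) +
                       p$beta_age * (age >= 75))
  survived <- runif(n) > pi_death
  for (i in seq_along(days)) {
    sel <- los >= days[i]
    mc <- mean(survived[sel])
    se <- sqrt(mc * (1 - mc) / sum(sel))
    expect_lt(abs(mc - oracle$true_cs[i]), 3 * se + 1e-9)
  }
})

test_that("oracle curve declines to the cap then plateaus, in [0, 1]", {
  p <- synthetic_params()
  oracle <- analytic_conditional_survival(p, days = 0:20)
  expect_true(all(oracle$true_cs >= 0 & oracle$true_cs <= 1))
  declining <- oracle$true_cs[oracle$day <= p$los_cap_days]
  expect_true(all(diff(declining) < 0))
  plateau <- oracle$true_cs[oracle$day >= p$los_cap_days]
  expect_equal(diff(plateau), rep(0, length(plateau) - 1), tolerance = 1e-7)
})

test_that("the elderly stratum's true survival is below the younger stratum's", {
  p <- synthetic_params(beta_age = 1.0)
  days <- 0:15
  young <- analytic_conditional_survival(p, days, stratum = "young")
  old <- analytic_conditional_survival(p, days, stratum = "old")
  expect_true(all(old$true_cs < young$true_cs))
  # mixture lies between the strata
  mix <- analytic_conditional_survival(p, days, stratum = "all")
  expect_true(all(mix$true_cs < young$true_cs & mix$true_cs > old$true_cs))
})

test_that("generated cohorts match the documented preset conditions", {
  cohort <- generate_cohort(synthetic_params(n = 30000, seed = 8))
  s <- summarize_cohort(cohort)
  expect_equal(s$median_los, 2, tolerance = 0.1)
  expect_equal(s$iqr_los_lower, 1, tolerance = 0.1)
  expect_equal(s$iqr_los_upper, 4, tolerance = 0.15)
  expect_equal(s$median_age, 64.04, tolerance = 0.01)  # truncated-normal median ~64.04
  expect_equal(s$pct_survived, 87.9, tolerance = 0.8)  # oracle day-0 value 87.87
  expect_true(all(cohort$age_years >= 18))
  expect_true(all(cohort$icu_los_days >= 0))
})

test_that("estimator recovers the analytic curve within binomial sampling error", {
  params <- synthetic_params(n = 50000, seed = 6)
  cohort <- generate_cohort(params)
  curve <- estimate_conditional_survival(cohort)
  oracle <- analytic_conditional_survival(params, curve$day)
  err <- abs(curve$cs - oracle$true_cs)
  se <- sqrt(oracle$true_cs * (1 - oracle$true_cs) / curve$n_at_risk)
  # everywhere within 3.5 binomial SEs; tight absolute error where the
  # at-risk set is still large
  expect_true(all(err <= 3.5 * se))
  expect_true(all(err[curve$n_at_risk >= 20000] <= 0.01))
})
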