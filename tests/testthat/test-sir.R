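test_that("prior draws follow the scenario priors", {
  set.seed(5)
  n <- 1e5
  rc <- sample_parameter_priors(scenario_spec("RC"), n)
  se_unif <- (0.118 / sqrt(12)) / sqrt(n)
  expect_lt(abs(mean(rc$r_max) - 0.059), 3 * se_unif)
  expect_true(all(rc$r_max >= 0 & rc$r_max <= 0.118))
  expect_true(all(rc$theta >= 0 & rc$theta <= 1))
  expect_true(all(rc$n_recent >= 500 & rc$n_recent <= 40000))

  d7 <- sample_parameter_priors(scenario_spec("D-7"), n)
  expect_true(all(d7$r_max <= 0.118))
  inside <- mean(d7$r_max >= 0.05 & d7$r_max <= 0.114)
  expect_equal(inside, 0.95, tolerance = 0.02)
  expect_equal(mean(d7$r_max), 0.086, tolerance = 0.01)
})

test_that("SIR resampling is multinomial in the weights", {
  set.seed(6)
  # equal weights resample approximately uniformly
  idx <- sir_resample(rep(1, 20), 2e4)
  expect_gt(stats::chisq.test(tabulate(idx, 20))$p.value, 0.001)
  # a single positive weight always wins
  expect_true(all(sir_resample(c(0, 0, 7, 0), 50) == 3))
  # 1:3 odds
  idx2 <- sir_resample(c(1, 3), 1e5)
  p2 <- mean(idx2 == 2)
  expect_lt(abs(p2 - 0.75), 3 * sqrt(0.75 * 0.25 / 1e5))
  expect_error(sir_resample(c(0, 0), 5), "feasible")
})

test_that("weight diagnostics", {
  expect_equal(sir_diagnostics(rep(2, 7))$ess, 7)
  one <- sir_diagnostics(c(0, 5, 0))
  expect_equal(one$ess, 1)
  expect_equal(one$max_weight_share, 1)
  expect_equal(sir_diagnostics(c(1, 1, 2))$ess, 16 / 6)
  expect_error(sir_diagnostics(numeric(0)), "empty")
})

test_that("marginal likelihood estimator", {
  expect_equal(log_marginal_estimate(rep(log(0.3), 50)), log(0.3))
  ll <- log(c(0.1, 0.4, 0.2))
  expect_equal(log_marginal_estimate(ll), log(mean(exp(ll))))
  expect_identical(log_marginal_estimate(rep(-Inf, 10)), -Inf)
  # identical draws and weights across two "scenarios" give equal marginals
  expect_equal(log_marginal_estimate(ll), log_marginal_estimate(rev(ll)))
})

test_that("evaluate_draws completes draws and rejects infeasible ones", {
  spec <- scenario_spec("RC")
  set.seed(31)
  draws <- sample_parameter_priors(spec, 200)
  ev <- evaluate_draws(spec, draws)
  expect_true(all(ev$feasible))
  expect_true(all(ev$K >= ev$n_recent))
  # round trip at the recent year for every draw
  expect_lt(max(abs(ev$N_2008 / ev$n_recent - 1)), 1e-6)
  expect_true(all(ev$n_min > 0 & ev$n_min <= ev$K))
  expect_true(all(ev$status_2030 <= 1 + 1e-9))

  # posterior-median-like draw: K within the published interval
  d1 <- tibble::tibble(r_max = 0.088, theta = 0.5, n_recent = 14264,
                       premodern_factor = 1.71, modern_factor = 1.0185,
                       early_modern_factor = 1.0185)
  ev1 <- evaluate_draws(spec, d1)
  expect_gt(ev1$K, 22821)
  expect_lt(ev1$K, 33578)
})

test_that("zero-catch toy: likelihood reduces to a single lognormal term", {
  spec <- scenario_spec("D-2") # no indices; absolute data only
  obs <- observation_set(spec)
  obs$absolute <- obs$absolute[obs$absolute$year == 2008, ]
  d <- tibble::tibble(r_max = 0.05, theta = 0.5, n_recent = 14264,
                      premodern_factor = 1, modern_factor = 1,
                      early_modern_factor = 1)
  ev <- evaluate_draws(spec, d, observations = obs, catches = zero_catches())
  expect_equal(ev$K, 14264, tolerance = 1e-8)
  sig <- lognormal_sigma(0.084)
  expect_equal(ev$loglik, -log(sig) - 0.5 * log(2 * pi), tolerance = 1e-6)

  # an estimate no trajectory can reach makes the draw infeasible
  d_bad <- d
  d_bad$r_max <- 0
  d_bad$n_recent <- 39000
  ev_bad <- evaluate_draws(spec, d_bad, observations = obs,
                           catches = list(periods = whale_catch_periods(),
                                          modern = whale_modern_catches()))
  expect_true(ev_bad$feasible) # reachable with large K; now make it impossible
  heavy <- zero_catches()
  heavy$modern$core <- 1e9
  ev_imp <- evaluate_draws(spec, d_bad, observations = obs, catches = heavy)
  expect_false(ev_imp$feasible)
  expect_identical(ev_imp$loglik, -Inf)
})

test_that("marginal likelihood agrees with quadrature on a zero-catch toy", {
  # With no catches K = n_recent and the only data point is the 2008
  # estimate, so the marginal likelihood is a 1-D integral over the
  # n_recent prior; r_max and theta integrate out trivially.
  spec <- scenario_spec("D-2")
  obs <- observation_set(spec)
  obs$absolute <- obs$absolute[obs$absolute$year == 2008, ]
  sig <- lognormal_sigma(0.084)
  dens <- function(nr) {
    stats::dnorm(log(14264), log(nr), sig) / (40000 - 500)
  }
  truth <- log(stats::integrate(dens, 500, 40000, rel.tol = 1e-10)$value)

  set.seed(88)
  draws <- sample_parameter_priors(spec, 4e4)
  ev <- evaluate_draws(spec, draws, observations = obs,
                       catches = zero_catches())
  got <- log_marginal_estimate(ev$loglik)
  expect_equal(got, truth, tolerance = 0.01)
})

test_that("fit_scenario returns a coherent posterior object", {
  set.seed(9)
  fit <- fit_scenario("RC", n_prior = 4000, n_out = 500)
  expect_s3_class(fit, "sir_fit")
  expect_identical(nrow(fit$posterior), 500L)
  expect_true(all(fit$posterior$feasible))
  expect_lte(fit$diagnostics$ess, 4000)
  expect_true(is.finite(fit$log_marginal))
  g <- glance(fit)
  expect_identical(g$scenario, "RC")
  expect_identical(g$n_prior, 4000)
})
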