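test_that("the annual step matches hand evaluation and its fixed points", {
  expect_equal(logistic_step(27000, 27000, 0.088, 2.39), 27000)
  expect_equal(logistic_step(10000, 27000, 0.088, 2.39), 10797.97, tolerance = 1e-5)
  expect_lt(logistic_step(500, 27000, 0.088, 2.39, removal = 600), 1)
  expect_error(logistic_step(-5, 27000, 0.088, 2.39), "positive")
})

test_that("projection preserves equilibrium and flags crashes", {
  no_catch <- tibble::tibble(year = 1830:1972, removal = 0)
  traj <- project_population(12345, 0.1, 2.39, no_catch)
  expect_true(attr(traj, "valid"))
  expect_equal(traj$abundance, rep(12345, nrow(traj)))

  crash <- tibble::tibble(year = 1830:1972,
                          removal = ifelse(1830:1972 < 1840, 3000, 0))
  bad <- project_population(10000, 0.02, 2.39, crash)
  expect_false(attr(bad, "valid"))

  # strictly increasing after catches end, while below K
  rc_rem <- assemble_removals(scenario_spec("RC"), 0.5, unit_loss())
  tr <- project_population(27000, 0.09, 2.39, rc_rem)
  post <- tr$abundance[tr$year >= 1973]
  expect_true(all(diff(post[post < 27000]) > 0))
})

test_that("solve_carrying_capacity inverts the projection", {
  no_catch <- tibble::tibble(year = 1830:1972, removal = 0)
  expect_equal(solve_carrying_capacity(14264, 2008, 0.088, 2.39, no_catch),
               14264, tolerance = 1e-9)

  rem <- assemble_removals(scenario_spec("RC"), 0.5, unit_loss())
  K <- solve_carrying_capacity(14264, 2008, 0.088, 2.39, rem)
  # grid-search oracle at 0.1-whale resolution around the solution
  grid <- seq(K - 5, K + 5, by = 0.1)
  reach <- vapply(grid, function(k) {
    tr <- project_population(k, 0.088, 2.39, rem, end_year = 2008)
    if (!attr(tr, "valid")) -Inf else tr$abundance[tr$year == 2008]
  }, numeric(1))
  K_grid <- grid[which.min(abs(reach - 14264))]
  expect_lt(abs(K - K_grid), 0.1)

  # round trip: the solved K reproduces n_recent
  tr <- project_population(K, 0.088, 2.39, rem, end_year = 2008)
  expect_lt(abs(tr$abundance[tr$year == 2008] / 14264 - 1), 1e-6)

  # infeasible: zero growth cannot reach an abundance that exceeds any
  # attainable value under heavy removals, even after bracket expansion
  heavy <- tibble::tibble(year = 1830:1972, removal = 1e6)
  expect_true(is.na(solve_carrying_capacity(4e4, 2008, 0, 2.39, heavy,
                                            k_upper = 1e5)))
})

test_that("recent abundance is monotone in K (bisection precondition)", {
  rem <- assemble_removals(scenario_spec("RC"), 0.5, unit_loss())
  for (r in c(0.02, 0.09)) {
    Ks <- seq(25000, 80000, length.out = 12)
    vals <- vapply(Ks, function(k) {
      tr <- project_population(k, r, 2.39, rem, end_year = 2008)
      if (!attr(tr, "valid")) -Inf else tr$abundance[tr$year == 2008]
    }, numeric(1))
    # crashed (invalid) trajectories occupy a low-K prefix; above it the
    # recent abundance is strictly increasing in K
    fin <- is.finite(vals)
    expect_true(all(diff(which(fin)) == 1))
    expect_true(all(diff(vals[fin]) > 0))
  }
})

test_that("MSYL fraction matches the production-curve argmax", {
  expect_equal(round(msyl_fraction(2.39), 2), 0.60)
  expect_equal(round(msyl_fraction(5.04), 2), 0.70)
  expect_equal(round(msyl_fraction(11.22), 2), 0.80)
  expect_equal(msyl_fraction(1), 0.5)
  for (z in c(1, 2.39, 5.04, 11.22)) {
    opt <- stats::optimize(function(x) x * (1 - x^z), c(0, 1),
                           maximum = TRUE, tol = 1e-10)
    expect_equal(msyl_fraction(z), opt$maximum, tolerance = 1e-6)
  }
  expect_error(msyl_fraction(0), "positive")
})

test_that("trajectory statistics summarize depletion and status", {
  no_catch <- tibble::tibble(year = 1830:1972, removal = 0)
  flat <- project_population(27193, 0.09, 2.39, no_catch)
  s <- trajectory_stats(flat, 27193)
  expect_equal(s$max_depletion, 1)
  expect_equal(s$status_2019, 1)

  rem <- assemble_removals(scenario_spec("RC"), 0.5, unit_loss())
  tr <- project_population(27193, 0.09, 2.39, rem)
  s2 <- trajectory_stats(tr, 27193)
  expect_equal(s2$n_min, min(tr$abundance))
  expect_equal(s2$year_min, tr$year[which.min(tr$abundance)])
  expect_true(s2$year_min >= 1904 && s2$year_min <= 1975)
  expect_equal(s2$max_depletion, s2$n_min / 27193)

  # a trajectory bottoming at 440 of K = 27193 is 1.6% depletion
  expect_equal(round(440 / 27193, 4), 0.0162)

  bad <- project_population(5000, 0.01, 2.39,
                            tibble::tibble(year = 1830:1972, removal = 900))
  expect_error(trajectory_stats(bad, 5000), "invalid")
})
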