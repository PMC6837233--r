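test_that("period totals are spread uniformly and include the pelagic component", {
  ann <- annualize_periods()
  expect_identical(ann$year, 1830:1972)
  expect_equal(ann$premodern_min[ann$year %in% 1830:1839], rep(120, 10))
  # 1894: single-year period, min 120 plus 48 pelagic whales
  expect_equal(ann$premodern_min[ann$year == 1894], 168)
  expect_equal(ann$premodern_max[ann$year == 1894], 448)
  expect_equal(sum(ann$premodern_max), 34965)
  expect_equal(sum(ann$premodern_min), 11738)
  expect_true(all(ann$premodern_min <= ann$premodern_max))
  expect_true(all(ann$premodern_min[ann$year > 1924] == 0))

  bad <- tibble::tibble(start_year = c(1830L, 1835L), end_year = c(1839L, 1841L),
                        brazil_min = c(1, 1), brazil_max = c(2, 2),
                        pelagic = c(0, 0))
  expect_error(annualize_periods(bad), "overlapping")
})

test_that("theta interpolation is exact at the endpoints and linear between", {
  ann <- annualize_periods()
  expect_equal(interpolate_premodern(0, ann)$catch, ann$premodern_min)
  expect_equal(interpolate_premodern(1, ann)$catch, ann$premodern_max)
  mid <- interpolate_premodern(0.5, ann)
  expect_equal(mid$catch[mid$year == 1830], 260)
  expect_error(interpolate_premodern(1.2, ann), "\\[0, 1\\]")
  expect_error(interpolate_premodern(-0.1, ann), "\\[0, 1\\]")
  # monotone in theta, year-wise
  thetas <- seq(0, 1, by = 0.25)
  series <- sapply(thetas, function(th) interpolate_premodern(th, ann)$catch)
  expect_true(all(diff(t(series)) >= 0))
})

test_that("loss-rate draws follow the era priors", {
  set.seed(101)
  none <- sample_loss_rates(5, "none")
  expect_equal(unname(as.matrix(none)), matrix(1, 5, 3))

  n <- 1e5
  both <- sample_loss_rates(n, "both_eras")
  expect_lt(abs(mean(both$premodern_factor) - 1.71), 3 * 0.073 / sqrt(n))
  expect_lt(abs(mean(both$modern_factor) - 1.0185), 3 * 0.0028 / sqrt(n))
  # outside C-4 the early-modern years share the modern-era factor
  expect_identical(both$early_modern_factor, both$modern_factor)

  mo <- sample_loss_rates(n, "modern_only")
  expect_true(all(mo$premodern_factor == 1))

  c4 <- sample_loss_rates(n, "C4_split")
  p_gt <- mean(c4$early_modern_factor > 1.15)
  expect_lt(abs(p_gt - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  expect_lte(max(c4$early_modern_factor), 1.30)
  expect_true(all(c4$early_modern_factor >= 1))

  expect_error(sample_loss_rates(5, "bogus"), "slr_mode")
})

test_that("removal series assembly matches the printed totals and allocations", {
  rc <- scenario_spec("RC")
  rem <- assemble_removals(rc, theta = 1, unit_loss())
  expect_equal(sum(rem$removal), 34965 + 31170) # 66135

  # excluded pre-modern component zeroes all removals before 1904
  c2 <- assemble_removals(scenario_spec("C-2"), theta = 0.7,
                          tibble::tibble(premodern_factor = 1.71,
                                         modern_factor = 1.0185,
                                         early_modern_factor = 1.0185))
  expect_true(all(c2$removal[c2$year < 1904] == 0))

  # C-5 differs from RC only in years with nonzero Falkland catches
  loss <- tibble::tibble(premodern_factor = 1.5, modern_factor = 1.02,
                         early_modern_factor = 1.02)
  r_rc <- assemble_removals(rc, 0.3, loss)
  r_c5 <- assemble_removals(scenario_spec("C-5"), 0.3, loss)
  falk <- whale_modern_catches()
  diff <- r_c5$removal - r_rc$removal
  expect_equal(diff[match(falk$year, r_rc$year)], falk$falkland * 1.02)
  expect_true(all(diff[!r_rc$year %in% falk$year[falk$falkland > 0]] == 0))

  # fringe exceeds core by 677 before correction
  r_c6 <- assemble_removals(scenario_spec("C-6"), 0.3, unit_loss())
  r_rc1 <- assemble_removals(rc, 0.3, unit_loss())
  expect_equal(sum(r_c6$removal) - sum(r_rc1$removal), 677)

  # monotone in theta and in each loss factor, year-wise
  r_lo <- assemble_removals(rc, 0.2, unit_loss())
  r_hi <- assemble_removals(rc, 0.8, unit_loss())
  expect_true(all(r_hi$removal >= r_lo$removal))
  bigger <- tibble::tibble(premodern_factor = 2, modern_factor = 1.1,
                           early_modern_factor = 1.1)
  expect_true(all(assemble_removals(rc, 0.2, bigger)$removal >= r_lo$removal))

  # C-4: the early factor applies only to modern catches in 1904-1918
  c4loss <- tibble::tibble(premodern_factor = 1, modern_factor = 1,
                           early_modern_factor = 1.2)
  r_c4 <- assemble_removals(scenario_spec("C-4"), 0, c4loss)
  r_base <- assemble_removals(rc, 0, unit_loss())
  mod <- whale_modern_catches()
  delta <- r_c4$removal - r_base$removal
  in_window <- r_c4$year >= 1904 & r_c4$year <= 1918
  expect_equal(delta[in_window],
               0.2 * mod$core[mod$year >= 1904 & mod$year <= 1918])
  expect_true(all(delta[!in_window] == 0))
})
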