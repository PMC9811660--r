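test_that("gamma2_from_distance follows the Solomon-Bloembergen form", {
  # hand evaluation: K/r^6 * (4 tau_c + 3 tau_c / (1 + (wH tau_c)^2))
  # at r = 11 A the 4 tau_c term dominates ((wH tau_c)^2 ~ 4e4)
  expect_equal(gamma2_from_distance(11), 1110.905, tolerance = 1e-4)

  # r^-6 scaling identity and large-r limit
  r <- c(5, 8, 11, 17, 23)
  expect_equal(gamma2_from_distance(2 * r), gamma2_from_distance(r) / 64)
  expect_lt(gamma2_from_distance(1e6), 1e-20)

  # strictly decreasing in r
  g <- gamma2_from_distance(seq(4, 40, by = 0.5))
  expect_true(all(diff(g) < 0))

  expect_error(gamma2_from_distance(0), "positive")
  expect_error(gamma2_from_distance(-3), "positive")
})

test_that("the fast-tumbling spectral-density term is negligible at defaults", {
  # with (wH tau_c)^2 >> 1 dropping 3 tau_c/(1 + wH^2 tau_c^2) changes
  # gamma2 by well under 0.01%
  p <- spin_params()
  full <- gamma2_from_distance(15, p)
  simple <- p$k_const / 15^6 * 4 * p$tau_c
  expect_lt(abs(full - simple) / full, 1e-4)
})

test_that("ratio_from_gamma2 maps rates to intensity ratios in (0, 1]", {
  expect_identical(ratio_from_gamma2(0), 1)
  # full-occupancy predictions at the two printed bound-state distances
  expect_equal(ratio_from_gamma2(gamma2_from_distance(11.0)), 3e-6,
               tolerance = 0.5)
  expect_equal(ratio_from_gamma2(gamma2_from_distance(10.6)), 2e-7,
               tolerance = 0.5)
  g <- 10^seq(-3, 4, length.out = 40)
  ratios <- ratio_from_gamma2(g)
  expect_true(all(ratios > 0 & ratios <= 1))
  expect_true(all(diff(ratios) < 0))
  expect_error(ratio_from_gamma2(-1), "non-negative")
})

test_that("predicted_pre composes fast exchange correctly", {
  # printed sensitivity statements
  expect_lte(predicted_pre(5, 1e-4), 0.8)
  expect_equal(predicted_pre(5, 1e-4), 0.77, tolerance = 0.01)
  expect_lte(predicted_pre(10, 0.10), 0.2)
  expect_lte(predicted_pre(5, 1e-3), 0.2)

  # p = 0 is always 1 regardless of distance
  expect_equal(predicted_pre(c(3, 11, 40), 0), rep(1, 3))

  # joint monotonicity: non-decreasing in r, non-increasing in p
  r_grid <- seq(5, 35, by = 2.5)
  p_grid <- c(1e-4, 1e-3, 1e-2, 0.1, 0.5, 1)
  m <- outer(r_grid, p_grid, function(r, p) predicted_pre(r, p))
  expect_true(all(apply(m, 2, function(col) all(diff(col) >= 0))))
  expect_true(all(apply(m, 1, function(row) all(diff(row) <= 0))))

  expect_error(predicted_pre(10, 1.2), "\\[0, 1\\]")
  expect_error(predicted_pre(10, -0.1), "\\[0, 1\\]")
})

test_that("gamma2_from_ratio inverts the forward model", {
  # frozen values from the independent bisection oracle
  expect_equal(gamma2_from_ratio(0.89), bisect_gamma2(0.89),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(as.numeric(gamma2_from_ratio(0.89)), 5.4688, tolerance = 1e-4)
  expect_equal(as.numeric(gamma2_from_ratio(0.77)), 12.5587, tolerance = 1e-4)

  # round trip over a wide ratio grid to 1e-9 relative
  x <- 10^seq(-10, -0.01, length.out = 50)
  back <- ratio_from_gamma2(as.numeric(gamma2_from_ratio(x)))
  expect_equal(back, x, tolerance = 1e-9)

  # clipping contract for noise ratios >= 1
  g <- gamma2_from_ratio(c(0.5, 1.0, 1.2))
  expect_equal(as.numeric(g)[2:3], c(0, 0))
  expect_identical(attr(g, "clipped"), c(FALSE, TRUE, TRUE))

  expect_error(gamma2_from_ratio(0), "positive")
  expect_error(gamma2_from_ratio(-0.2), "positive")
})

test_that("population_from_ratio reproduces the worked inversions", {
  expect_equal(population_from_ratio(0.89, 11.6), 0.007, tolerance = 0.05)
  expect_equal(population_from_ratio(0.77, 10.6), 0.009, tolerance = 0.05)
  expect_equal(population_from_ratio(1.0, 12), 0)
  # clipped to [0, 1] even for extreme attenuation at long distance
  expect_lte(population_from_ratio(1e-8, 40), 1)
})

test_that("kd and population round-trip through 1:1 mass action", {
  # direct arithmetic: p = 0.5 at 20/110 uM -> (110 - 10) * 10 / 10 uM
  expect_equal(kd_from_population(0.5), 1.0e-4, tolerance = 1e-12)
  expect_equal(population_from_kd(1.0e-4), 0.5, tolerance = 1e-9)

  # the worked-case populations land on the published millimolar KDs
  expect_equal(kd_from_population(0.007), 16e-3, tolerance = 0.02)
  expect_equal(kd_from_population(0.009), 12e-3, tolerance = 0.05)
  expect_equal(population_from_kd(16e-3), 0.007, tolerance = 0.05)

  # round trip over a population grid
  for (p in 10^seq(-5, -0.05, length.out = 25)) {
    expect_equal(population_from_kd(kd_from_population(p)), p,
                 tolerance = 1e-9)
  }

  # weak-binding limit and error contracts
  expect_lt(population_from_kd(100), 1e-5)
  expect_message(expect_identical(kd_from_population(0), Inf), "unbounded")
  tight <- binding_context(labeled_total = 200e-6, partner_total = 110e-6)
  expect_error(kd_from_population(0.9, tight), "infeasible")
})

test_that("distance_at_ratio solves the footprint boundary", {
  r04 <- distance_at_ratio(0.4, 1)
  expect_lte(r04, 19)
  expect_equal(r04, 18.54, tolerance = 1e-3)
  expect_equal(predicted_pre(r04, 1), 0.4, tolerance = 1e-6)

  # boundary consistent with detection at 5 A / 0.1% population
  expect_gte(distance_at_ratio(0.2, 0.001), 5)

  # monotone limit: targets near 1 push the distance out
  expect_gt(distance_at_ratio(0.999, 1), distance_at_ratio(0.5, 1))

  expect_error(distance_at_ratio(1.0, 1), "between 0 and 1")
  expect_error(distance_at_ratio(0.4, 0), "\\(0, 1\\]")
})

test_that("spin_params and binding_context validate and derive fields", {
  sp <- spin_params()
  expect_equal(sp$R2_dia, pi * 25)
  expect_equal(sp$omega_H, 2 * pi * 8e8)
  expect_error(spin_params(tau_c = -1), "positive")
  expect_error(spin_params(linewidth_dia = 0), "positive")
  expect_error(binding_context(labeled_total = 0), "positive")
})
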