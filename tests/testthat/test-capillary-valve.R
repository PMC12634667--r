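# Reduced two-phase burst-valve simulator: invasion dynamics, bisection,
# nondimensionalization, and agreement with the Young-Laplace oracles.

test_that("nondimensional pressure is p * D_h / gamma", {
  expect_equal(nondimensional_pressure(0, 3.2, 0.072), 0)
  expect_equal(nondimensional_pressure(0.072 / 3.2e-6, 3.2, 0.072), 1)
  expect_equal(nondimensional_pressure(4050, 3.2, 0.072), 0.18)
  expect_error(nondimensional_pressure(1, 3.2, 0), "gamma")
})

test_that("invasion outcomes bracket the capillary threshold", {
  fl <- fixture_fluids()
  dom <- valve_domain(fixture_straight_fenestra(), dx = 1)
  lower <- quasistatic_burst_bounds(fixture_straight_fenestra(), fl)["lower"]

  pinned <- simulate_invasion(dom, 0.5 * lower, fl)
  expect_equal(pinned$outcome, "pinned")
  burst <- simulate_invasion(dom, 3 * lower, fl)
  expect_equal(burst$outcome, "burst")
  # monotone interface advance: fenestra fill never decreases
  expect_true(all(diff(burst$trace$fenestra_fill) >= 0))
  expect_true(all(burst$phi >= 0 & burst$phi <= 1))
  # zero applied pressure pins against any capillary resistance
  expect_equal(simulate_invasion(dom, 0, fl)$outcome, "pinned")
})

test_that("zero surface tension bursts at any positive pressure", {
  fl0 <- fluid_properties(surface_tension = 0)
  dom <- valve_domain(fixture_straight_fenestra(), dx = 1)
  expect_equal(simulate_invasion(dom, 1, fl0, t_max = Inf)$outcome, "burst")
  br <- find_burst_pressure(dom, fl0)
  expect_equal(br$burst_pressure, 0)
  expect_equal(br$p_star, 0)
})

test_that("unresolved pores raise a resolution error", {
  expect_error(valve_domain(fixture_straight_fenestra(), dx = 2),
               "resolution")
})

test_that("bisection brackets are validated", {
  fl <- fixture_fluids()
  dom <- valve_domain(fixture_straight_fenestra(), dx = 1)
  expect_error(find_burst_pressure(dom, fl, p_lo = 3e4), "lower bound")
  expect_error(find_burst_pressure(dom, fl, p_hi = 10), "upper bound")
})

test_that("straight-fenestra burst pressure sits within Young-Laplace bounds", {
  fl <- fixture_fluids()
  fen <- fixture_straight_fenestra()
  bounds <- quasistatic_burst_bounds(fen, fl)
  br <- find_burst_pressure(valve_domain(fen, dx = 1), fl, tol = 40)
  # transit resistance (lower) and semicircular cap (upper), with a small
  # margin for the discrete interface
  expect_gte(br$burst_pressure, bounds["lower"] * 0.9)
  expect_lte(br$burst_pressure, bounds["upper"] * 1.1)
  # emergent value should track the analytic transit threshold closely
  expect_equal(br$burst_pressure, unname(bounds["lower"]), tolerance = 0.1)
})

test_that("pillar fenestra bursts above the straight fenestra at equal D_h", {
  fl <- fixture_fluids()
  fs <- fixture_straight_fenestra()
  fp <- fixture_pillar_fenestra()
  expect_equal(fs$hydraulic_diameter, fp$hydraulic_diameter)
  for (dx in c(1.25, 1)) {
    bs <- find_burst_pressure(valve_domain(fs, dx = dx), fl, tol = 60)
    bp <- find_burst_pressure(valve_domain(fp, dx = dx), fl, tol = 60)
    expect_gt(bp$burst_pressure, bs$burst_pressure)
  }
  # the sliding-arc oracle for the converging-diverging pore
  sl <- quasistatic_burst_bounds(fp, fl)["sliding_max"]
  bp1 <- find_burst_pressure(valve_domain(fp, dx = 1), fl, tol = 40)
  expect_equal(bp1$burst_pressure, unname(sl), tolerance = 0.08)
})

test_that("burst pressure scales linearly with surface tension", {
  fen <- fixture_straight_fenestra()
  b1 <- find_burst_pressure(valve_domain(fen, dx = 1),
                            fluid_properties(surface_tension = 0.036),
                            tol = 20)
  b2 <- find_burst_pressure(valve_domain(fen, dx = 1),
                            fluid_properties(surface_tension = 0.072),
                            tol = 40)
  expect_equal(b2$burst_pressure / b1$burst_pressure, 2, tolerance = 0.03)
  # p* is invariant under the gamma rescaling
  expect_equal(b1$p_star, b2$p_star, tolerance = 0.03)
})

test_that("burst pressure is grid-stable between the two finest levels", {
  fl <- fixture_fluids()
  for (fen in list(fixture_straight_fenestra(), fixture_pillar_fenestra())) {
    b_coarse <- find_burst_pressure(valve_domain(fen, dx = 1), fl, tol = 40)
    b_fine <- find_burst_pressure(valve_domain(fen, dx = 0.5), fl, tol = 40)
    expect_lt(abs(b_fine$burst_pressure - b_coarse$burst_pressure) /
                b_fine$burst_pressure, 0.10)
  }
})
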