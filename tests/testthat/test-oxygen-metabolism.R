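# Michaelis-Menten oxygen reaction-diffusion: trivial limits, the 1d slab
# closed form, conservation, monotonicity and grid convergence.

test_that("zero consumption gives a uniform field at the boundary value", {
  sol <- solve_oxygen_steady(fixture_small_domain("V1"),
                             oxygen_parameters(socr = 0))
  expect_equal(range(sol$c_vec), c(0.21, 0.21), tolerance = 1e-10)
  expect_equal(sol$B, 0, tolerance = 1e-18)
  expect_equal(tissue_ocr(sol), sol$B)
  m <- min_oxygen(sol)
  expect_equal(as.numeric(m), 0.21, tolerance = 1e-10)
  expect_true(attr(m, "viable"))
})

test_that("zeroth-order 1d slab matches the parabolic closed form", {
  # a long thin box with no roof exchange approximates a 1d slab across x
  # with both faces at c_s; in the non-depleted limit (c >> k_m) the profile
  # is parabolic with c_min = c_s - R0 a^2 / (2D)
  lx <- 200; a <- um_to_m(lx) / 2
  dom <- tissue_domain("custom", dims = c(lx, 4000, 50),
                       n = c(40, 64, 10))
  socr <- 2e-17
  par <- oxygen_parameters(socr = socr, k_pdms = 0, km = 1e-6)
  sol <- solve_oxygen_steady(dom, par)
  r0 <- socr * par$cell_density
  expected_min <- par$c_side - r0 * a^2 / (2 * par$diffusivity)
  expect_equal(sol$c_min, expected_min, tolerance = 0.02)
  expect_equal(as.numeric(min_oxygen(sol)), sol$c_min)
  # non-depleted conservation identity: B -> sOCR rho_c V
  expect_equal(sol$B, socr * par$cell_density *
                 um3_to_m3(dom$volume_um3), tolerance = 0.01)
})

test_that("surface-flux OCR equals volume-integrated consumption within 1%", {
  for (g in c("V1", "V3")) {
    for (socr in c(4.67e-17, 1.5e-16)) {
      sol <- solve_oxygen_steady(fixture_small_domain(g),
                                 oxygen_parameters(socr = socr))
      expect_lt(abs(sol$B - sol$consumed) / sol$B, 0.01)
    }
  }
})

test_that("maximum principle: concentrations stay within [0, boundary]", {
  sol <- solve_oxygen_steady(fixture_small_domain("V3"),
                             oxygen_parameters(socr = 3e-16))
  expect_gte(sol$c_min, 0)
  expect_lte(sol$c_max, 0.21 + 1e-12)
})

test_that("increasing sOCR depletes oxygen and raises tissue OCR", {
  socrs <- c(2e-17, 4.67e-17, 1e-16)
  sols <- lapply(socrs, function(s)
    solve_oxygen_steady(fixture_small_domain("V1"),
                        oxygen_parameters(socr = s)))
  cmins <- vapply(sols, function(s) s$c_min, 0)
  bs <- vapply(sols, function(s) s$B, 0)
  expect_true(all(diff(cmins) < 0))
  expect_true(all(diff(bs) > 0))
})

test_that("a larger tissue consumes more at equal sOCR", {
  p <- oxygen_parameters()
  b1 <- solve_oxygen_steady(fixture_small_domain("V1"), p)$B
  b2 <- solve_oxygen_steady(fixture_small_domain("V2"), p)$B
  b3 <- solve_oxygen_steady(fixture_small_domain("V3"), p)$B
  expect_gt(b2, b1)
  expect_gt(b3, b2)
})

test_that("tissue OCR converges under grid refinement on V1", {
  p <- oxygen_parameters()
  b_coarse <- solve_oxygen_steady(tissue_domain("V1", n = c(16, 40, 12)), p)$B
  b_fine <- solve_oxygen_steady(tissue_domain("V1", n = c(32, 80, 24)), p)$B
  expect_lt(abs(b_fine - b_coarse) / b_fine, 0.01)
})

test_that("domain and parameter validation", {
  expect_error(tissue_domain("custom"), "dims")
  expect_error(tissue_domain("V1", n = c(12, 30, 6)), "10 cells")
  expect_error(oxygen_parameters(km = 0.3), "km")
  expect_error(oxygen_parameters(diffusivity = -1), "diffusivity")
  d <- tissue_domain("V2")
  expect_equal(d$dims, c(243.8, 621.6, 124.7))
})
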