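# Barrier geometry: hydraulic diameter, pillar layouts, porosity and porous
# volume.

test_that("hydraulic diameter matches the rectangular-duct formula", {
  expect_equal(hydraulic_diameter(4, 4), 4)   # square duct: D_h = side
  expect_equal(hydraulic_diameter(2, 2), 2)
  # invert 2hw/(h+w) = 3.2 at h = 2: w = 8, the printed fenestra geometry
  w <- 3.2 * 2 / (2 * 2 - 3.2)
  expect_equal(w, 8)
  expect_equal(hydraulic_diameter(2, w), 3.2)
  expect_error(hydraulic_diameter(0, 5), "positive")
  expect_error(hydraulic_diameter(5, -1), "positive")
})

test_that("pillar layouts satisfy the gap convention exactly", {
  lay <- build_pillar_layout(8, 8, 708)
  expect_equal(lay$pillar_diameter, (708 - 9 * 8) / 8)   # 79.5
  expect_equal(lay$pillar_diameter, 79.5)
  lay2 <- build_pillar_layout(8, 2, 708)
  expect_equal(lay2$pillar_diameter, 86.25)
  # centres equally spaced, layout fills the region under end_gaps
  expect_equal(diff(lay$centers),
               rep(lay$pillar_diameter + lay$pore_size, 7))
  expect_equal(max(lay$centers) + lay$pillar_diameter / 2 + lay$pore_size,
               708)
  # degenerate single pillar spanning the region
  lay1 <- build_pillar_layout(1, 0, 100)
  expect_equal(lay1$pillar_diameter, 100)
  expect_equal(lay1$centers, 50)
  # infeasible geometry
  expect_error(build_pillar_layout(8, 100, 708), "infeasible")
})

test_that("porosity follows the plan-area closed form and its limits", {
  lay <- build_pillar_layout(8, 8, 708)
  expect_equal(porosity(lay), 1 - 8 * pi * 39.75^2 / (125 * 708),
               tolerance = 1e-12)
  expect_equal(porosity(lay), 0.551, tolerance = 1e-3)
  # porosity is monotone in pore size at fixed n and region
  pores <- c(2, 4, 6, 8, 10)
  ps <- vapply(pores, function(p)
    porosity(build_pillar_layout(8, p, 708)), 0)
  expect_true(all(diff(ps) > 0))
  # shrinking pillars toward points drives porosity to 1
  tiny <- build_pillar_layout(8, 78, 708)   # 0.75 um pillars
  expect_gt(porosity(tiny), 0.9999)
})

test_that("Monte-Carlo area integration agrees with closed-form porosity", {
  lay <- build_pillar_layout(8, 8, 708)
  expect_equal(porosity_mc(lay, n = 1e6), porosity(lay), tolerance = 5e-3)
  lay2 <- build_pillar_layout(8, 2, 708)
  expect_equal(porosity_mc(lay2, n = 1e6), porosity(lay2), tolerance = 5e-3)
})

test_that("porous volume is exactly linear in height", {
  base <- build_pillar_layout(8, 8, 708, height = 2)
  doubled <- build_pillar_layout(8, 8, 708, height = 4)
  expect_equal(porous_volume(doubled), 2 * porous_volume(base))
  expect_equal(porous_volume(build_pillar_layout(8, 8, 708, height = 1)) * 7,
               porous_volume(build_pillar_layout(8, 8, 708, height = 7)))
  heights <- c(0.5, 1, 2, 5, 10)
  ratio <- vapply(heights, function(h)
    porous_volume(build_pillar_layout(8, 8, 708, height = h)) / h, 0)
  expect_equal(ratio, rep(ratio[1], length(heights)))
})

test_that("fenestra and device constructors validate and derive D_h", {
  fs <- fixture_straight_fenestra()
  expect_equal(fs$hydraulic_diameter, 3.2)
  fp <- fixture_pillar_fenestra()
  expect_equal(fp$hydraulic_diameter, 3.2)   # throat gap 8 um at 2 um height
  expect_error(fenestra_geometry("pillar_array", 2, 8), "pillar_layout")
  dev <- device_geometry()
  expect_equal(dev$chamber_width, 300)
  expect_equal(dev$channel_width, 100)
  expect_error(fluid_properties(contact_angle = 190), "contact_angle")
  expect_error(fluid_properties(surface_tension = -1), "surface_tension")
})

test_that("layout export table carries one row per pillar", {
  lay <- build_pillar_layout(8, 8, 708)
  tab <- layout_table(lay)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$diameter_um, rep(79.5, 8))
  expect_equal(tab$center_along_um, lay$centers)
})
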