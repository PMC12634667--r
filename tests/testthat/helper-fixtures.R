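# Shared fixtures: small, cheap objects reused across test files.

fixture_fluids <- function(...) fluid_properties(...)

fixture_straight_fenestra <- function(height = 2, width = 8) {
  fenestra_geometry("straight_channel", height = height,
                    width_or_layout = width)
}

fixture_pillar_fenestra <- function(pore = 8, height = 2) {
  fenestra_geometry("pillar_array", height = height,
                    width_or_layout = build_pillar_layout(8, pore, 708,
                                                          height = height))
}

# small oxygen grids, fast enough for per-test solves
fixture_small_domain <- function(geometry = "V1") {
  n <- switch(geometry,
              V1 = c(12, 30, 10),
              V2 = c(12, 30, 12),
              V3 = c(14, 40, 12))
  tissue_domain(geometry, n = n)
}

# Monte-Carlo plan-area porosity oracle: fraction of random points in the
# barrier region that fall outside every pillar
porosity_mc <- function(layout, n = 1e6, seed = 99) {
  set.seed(seed)
  x <- runif(n, 0, layout$region_length)
  y <- runif(n, 0, layout$region_width)
  r <- layout$pillar_diameter / 2
  inside <- rep(FALSE, n)
  for (cx in layout$centers) {
    inside <- inside | ((x - cx)^2 + (y - layout$region_width / 2)^2 <= r^2)
  }
  1 - mean(inside)
}
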