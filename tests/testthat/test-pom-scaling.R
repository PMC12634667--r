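# Population of models and finite-size scaling collapse.

test_that("sOCR sampling hits the printed moments and is reproducible", {
  d <- socr_distribution()
  s <- sample_socr(d, 1e5, seed = 3)
  expect_true(all(s > 0))
  expect_equal(mean(s), 4.67e-17, tolerance = 0.02)
  expect_equal(sd(s) / mean(s), 0.69, tolerance = 0.03)
  expect_identical(s, sample_socr(d, 1e5, seed = 3))
  expect_false(identical(s[1], sample_socr(d, 1, seed = 4)[1]))
  # cv = 0 collapses to the mean
  s0 <- sample_socr(socr_distribution(cv = 0), 10, seed = 1)
  expect_equal(s0, rep(4.67e-17, 10))
  # truncation is honoured
  dtr <- socr_distribution(truncation = c(2e-17, 1e-16))
  str <- sample_socr(dtr, 5000, seed = 5)
  expect_true(all(str >= 2e-17 & str <= 1e-16))
  expect_error(socr_distribution(mean = -1), "mean")
})

test_that("empirical pdf integrates to one and matches known densities", {
  set.seed(10)
  u <- runif(5000)
  pdf_u <- empirical_pdf(u, n_bins = 25)
  dx <- diff(pdf_u$x[1:2])
  expect_equal(sum(pdf_u$density * dx), 1, tolerance = 0.01)
  expect_true(all(abs(pdf_u$density - 1) < 0.2))
  ln <- rlnorm(20000, 0, 0.5)
  pdf_ln <- empirical_pdf(ln, n_bins = 60)
  ref <- dlnorm(pdf_ln$x, 0, 0.5)
  expect_lt(mean(abs(pdf_ln$density - ref)), 0.05)
  expect_error(empirical_pdf(runif(10)), "50 samples")
})

test_that("collapse recovers known exponents from generative ensembles", {
  masses <- c(1.56e9, 3.12e9, 6.7e9)
  for (d0 in c(0.6, 0.75, 1.0)) {
    syn <- synth_scaling_distributions(d0, masses, n = 2000, seed = 21,
                                       common_x = FALSE)
    cr <- collapse_distributions(syn$samples, syn$masses, seed = 8)
    expect_equal(cr$delta, d0, tolerance = 0.05)
    expect_equal(cr$alpha, cr$delta)
  }
})

test_that("exact proportionality to mass is recovered as isometric scaling", {
  masses <- c(1, 2.3, 5.1) * 1e9
  set.seed(4)
  x <- rlnorm(3000, 0, 0.5)
  samples <- lapply(masses, function(m) m * x * exp(rnorm(3000, 0, 0.03)))
  cr <- collapse_distributions(samples, masses, seed = 2)
  expect_equal(cr$delta, 1, tolerance = 0.05)
})

test_that("collapse optimum is locally identifiable and matches a grid scan", {
  syn <- synth_scaling_distributions(0.75, c(1e9, 2.2e9, 4.8e9),
                                     n = 1500, seed = 31, common_x = FALSE)
  cr <- collapse_distributions(syn$samples, syn$masses, seed = 9)
  prof <- collapse_profile(syn$samples, syn$masses,
                           deltas = seq(0.5, 1.1, by = 0.001))
  d_grid <- prof$delta[which.min(prof$distance)]
  expect_lt(abs(cr$delta - d_grid), 0.0015)   # within one grid step
  at <- function(d) prof$distance[which.min(abs(prof$delta - d))]
  expect_gt(at(cr$delta + 0.2), cr$distance)
  expect_gt(at(cr$delta - 0.2), cr$distance)
})

test_that("delta is invariant to a common multiplicative factor on masses", {
  syn <- synth_scaling_distributions(0.8, c(1.2e9, 2.5e9, 5.5e9),
                                     n = 1500, seed = 41, common_x = FALSE)
  c1 <- collapse_distributions(syn$samples, syn$masses, seed = 3)
  c2 <- collapse_distributions(syn$samples, syn$masses * 7.3e-15, seed = 3)
  expect_equal(c1$delta, c2$delta, tolerance = 0.02)
})

test_that("degenerate collapses are flagged", {
  set.seed(6)
  x <- rlnorm(1000, 0, 0.4)
  expect_warning(
    cr <- collapse_distributions(list(x, x * 1.001), c(2e9, 2e9), seed = 1),
    "degenerate")
  expect_true(cr$degenerate)
})

test_that("PoM propagates sOCR variability with common random numbers", {
  geoms <- list(V1 = fixture_small_domain("V1"),
                V2 = fixture_small_domain("V2"))
  pom <- run_pom(geoms, socr_distribution(), n = 40, seed = 13)
  expect_equal(dim(pom$B), c(40L, 2L))
  expect_equal(length(pom$failures), 0)
  expect_true(all(pom$B > 0))
  # common draws: per-draw B are strongly rank-correlated across geometries
  expect_gt(cor(pom$B[, 1], pom$B[, 2], method = "spearman"), 0.999)
  # larger tissue consumes more for every shared draw
  expect_true(all(pom$B[, 2] > pom$B[, 1]))
  # masses use volume x cell density by default
  expect_equal(unname(pom$masses),
               c(243.8 * 621.6 * 62.35, 243.8 * 621.6 * 124.7) *
                 1e-18 * 1.95e14,
               tolerance = 1e-6)
  # reproducibility
  pom2 <- run_pom(geoms, socr_distribution(), n = 40, seed = 13)
  expect_identical(pom$B, pom2$B)
})

test_that("deterministic single-model PoM equals the direct solve", {
  geom <- list(V1 = fixture_small_domain("V1"))
  pom <- run_pom(geom, socr_distribution(cv = 0), n = 2, seed = 1)
  direct <- solve_oxygen_steady(fixture_small_domain("V1"),
                                oxygen_parameters(socr = 4.67e-17))
  expect_equal(unname(pom$B[1, 1]), direct$B, tolerance = 1e-8)
  expect_equal(unname(pom$B[2, 1]), direct$B, tolerance = 1e-8)
})

test_that("non-depleted PoM inherits the sOCR cv (linear regime)", {
  # a small sparse tissue stays far from depletion, so B ~ sOCR rho V and
  # cv(B) ~ cv(sOCR)
  geom <- list(tiny = tissue_domain("custom", dims = c(60, 120, 50),
                                    n = c(10, 16, 10)))
  pom <- run_pom(geom, socr_distribution(), n = 150, seed = 17)
  cvb <- sd(pom$B[, 1]) / mean(pom$B[, 1])
  draws_cv <- sd(pom$draws) / mean(pom$draws)
  expect_equal(cvb, draws_cv, tolerance = 0.02)
  # and B is proportional to the draw
  expect_gt(cor(pom$B[, 1], pom$draws), 0.9999)
})
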