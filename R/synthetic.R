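# Synthetic-data generators: every statistical input the analysis assumes,
# reproducible from a seed, with ground truth attached.

#' Specification for the synthetic generators
#'
#' Defaults are the printed study statistics: single-cell OCR mean 4.67e-17
#' mol/s (cv 0.69); tissue volume mean 1.91e7 um^3 (cv 0.33); cell density
#' mean 1.95e14 cells/m^3 (cv 0.26); cell count mean 3685 (cv 0.40, implied
#' by volume x density); per-dimension means 243.8 x 621.6 x 124.7 um.
#'
#' @param seed Default seed for generators that are not given one.
#' @param socr_mean,socr_cv Single-cell OCR moments (mol/s).
#' @param volume_mean,volume_cv Tissue volume moments (um^3).
#' @param density_mean,density_cv Cell density moments (cells/m^3).
#' @param dim_means Mean box dimensions (um).
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(seed = 1L,
                           socr_mean = 4.67e-17, socr_cv = 0.69,
                           volume_mean = 1.91e7, volume_cv = 0.33,
                           density_mean = 1.95e14, density_cv = 0.26,
                           dim_means = c(243.8, 621.6, 124.7)) {
  for (nm in c("socr_mean", "volume_mean", "density_mean")) {
    stopifnot_positive(get(nm), nm)
  }
  stopifnot(all(c(socr_cv, volume_cv, density_cv) >= 0),
            length(dim_means) == 3, all(dim_means > 0))
  structure(list(
    seed = seed, socr_mean = socr_mean, socr_cv = socr_cv,
    volume_mean = volume_mean, volume_cv = volume_cv,
    density_mean = density_mean, density_cv = density_cv,
    dim_means = dim_means
  ), class = "synthetic_spec")
}

.rlnorm_mcv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

#' Synthetic ensemble of tissue geometries
#'
#' Draws tissue volume and cell density as independent lognormals matched to
#' the printed moments and derives the cell count as their product, so each
#' sample's density is exactly count/volume and the ensemble mean density
#' matches the printed value. Box dimensions are the mean aspect ratio
#' rescaled isotropically to the sampled volume.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param n Ensemble size.
#' @param seed Seed (defaults to the spec's).
#' @return Data frame with dimensions (um), volume (um^3), cell count and
#'   density (cells/m^3); the spec is attached as attribute
#'   \code{"ground_truth"}.
#' @export
synth_geometry_ensemble <- function(spec, n, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  n <- as.integer(n)
  vol <- .rlnorm_mcv(n, spec$volume_mean, spec$volume_cv)
  den <- .rlnorm_mcv(n, spec$density_mean, spec$density_cv)
  count <- um3_to_m3(vol) * den
  scale <- (vol / prod(spec$dim_means))^(1 / 3)
  out <- data.frame(
    lx = spec$dim_means[1] * scale,
    ly = spec$dim_means[2] * scale,
    lz = spec$dim_means[3] * scale,
    volume_um3 = vol,
    cell_count = count,
    density_per_m3 = den
  )
  attr(out, "ground_truth") <- spec
  out
}

#' Synthetic scaling ensembles with a known exponent
#'
#' Generates per-mass samples that satisfy the finite-size scaling form
#' exactly: \eqn{B = m^{\delta_0} X} with X drawn from a fixed base
#' distribution, which implies \eqn{p(B) = B^{-1} F(B/m^{\delta_0})} with
#' \eqn{F(u) = u\,p_X(u)}. Used for end-to-end recovery tests of the
#' collapse.
#'
#' @param delta0 Ground-truth exponent.
#' @param masses Vector of distinct masses.
#' @param n Samples per mass.
#' @param seed Seed.
#' @param base \code{"lognormal"} (default) base distribution X, or a
#'   function(n) returning positive draws.
#' @param sdlog Log-sd of the lognormal base.
#' @param common_x Reuse the same X draws across masses (default TRUE,
#'   mirroring common random numbers in the PoM).
#' @return List with \code{samples} (list per mass), \code{masses} and
#'   \code{delta0}.
#' @export
synth_scaling_distributions <- function(delta0, masses, n = 2000,
                                        seed = 1L, base = "lognormal",
                                        sdlog = 0.6, common_x = TRUE) {
  stopifnot(is.finite(delta0), length(masses) >= 1, all(masses > 0))
  if (length(masses) > 1 && any(duplicated(masses))) {
    stop("'masses' must be distinct", call. = FALSE)
  }
  set.seed(as.integer(seed))
  drawx <- if (is.function(base)) base else
    function(m) stats::rlnorm(m, 0, sdlog)
  x0 <- drawx(n)
  samples <- lapply(masses, function(m) {
    x <- if (common_x) x0 else drawx(n)
    m^delta0 * x
  })
  list(samples = samples, masses = masses, delta0 = delta0, seed = seed)
}

#' Synthetic chamber concentration trace
#'
#' Saturating exponential \eqn{c(t) = c_0 (1 - e^{-kt})}, optionally with
#' additive Gaussian noise, wrapped as a \code{concentration_trace} so the
#' permeability and equilibration estimators can be exercised against closed
#' forms: \eqn{P = k V_{ch}/A_b} and \eqn{t_{eq}(0.95) = \ln(20)/k}.
#'
#' @param k Rate constant (1/h).
#' @param c0 Inlet concentration (nM).
#' @param t_grid Sample times (h).
#' @param noise Additive noise sd (fraction of c0).
#' @param chamber_volume,barrier_area Geometry used by the permeability
#'   estimator (m^3, m^2).
#' @param seed Seed for the noise.
#' @return A \code{concentration_trace} with attribute
#'   \code{"ground_truth"} carrying k and the closed-form targets.
#' @export
synth_concentration_trace <- function(k, c0 = 7.46,
                                      t_grid = seq(0, 60, by = 0.05),
                                      noise = 0,
                                      chamber_volume = 3.1e-11,
                                      barrier_area = 2.1e-7,
                                      seed = 1L) {
  stopifnot_positive(k, "k")
  cfrac <- 1 - exp(-k * t_grid)
  if (noise > 0) {
    set.seed(as.integer(seed))
    cfrac <- pmin(pmax(cfrac + stats::rnorm(length(t_grid), 0, noise), 0), 1)
  }
  out <- structure(list(
    trace = data.frame(t_hours = t_grid, c_over_c0 = cfrac),
    c0 = nM_to_molm3(c0),
    chamber_volume = chamber_volume,
    barrier_area = barrier_area,
    barrier_area_convention = "synthetic",
    config = NULL
  ), class = "concentration_trace")
  attr(out, "ground_truth") <- list(
    k_per_h = k,
    permeability_cm_s = (k / 3600) * chamber_volume / barrier_area * 100,
    t_eq_95_h = log(20) / k)
  out
}

#' Write a generated table with a JSON ground-truth sidecar
#'
#' @param x A data frame (or object with a \code{trace} data frame).
#' @param path CSV output path; the sidecar is written next to it as
#'   \code{<path>.truth.json}.
#' @return Invisibly, the two paths.
#' @export
write_synthetic <- function(x, path) {
  df <- if (is.data.frame(x)) x else x$trace
  utils::write.csv(df, path, row.names = FALSE)
  truth <- attr(x, "ground_truth")
  sidecar <- paste0(path, ".truth.json")
  jsonlite::write_json(
    if (is.null(truth)) list() else truth,
    sidecar, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(path, sidecar))
}
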