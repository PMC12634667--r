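# Finite-size scaling collapse of tissue-OCR distributions.
#
# Model: p(B | <m>, beta) = B^(-beta) F(B / <m>^delta). Rescaling each
# geometry's distribution as y = p(B) B^beta against x = B / <m>^delta
# should put all geometries on one master curve F at the right delta. The
# collapse distance follows the probability-contiguity construction: on
# log-log axes, the sum over ordered pairs of curves of the integrated
# absolute difference on their overlap, normalized by the overlap length.
# With beta = 1 the rescaled curve y = p(B) B is exactly the density of
# log B, so the collapse reduces to horizontally aligning log-densities
# shifted by delta * log<m>.

# log-log rescaled curve for one geometry: X = ln B - delta ln<m>,
# Y = ln(p(B) B^beta) = ln f(lnB) + (beta - 1) lnB, with f the log-space KDE
.collapse_curves <- function(samples, beta) {
  lapply(samples, function(s) {
    s <- s[is.finite(s) & s > 0]
    d <- stats::density(log(s), n = 512)
    keep <- d$y > max(d$y) * 1e-3
    list(lx = d$x[keep],
         ly = log(d$y[keep]) + (beta - 1) * d$x[keep])
  })
}

# overlap-normalized pairwise distance at a given delta; curves are shifted
# by delta * ln<m> and compared on a common abscissa by linear interpolation
.collapse_distance <- function(curves, log_m, delta, n_grid = 200L) {
  ng <- length(curves)
  total <- 0
  npairs <- 0L
  for (i in seq_len(ng - 1L)) {
    for (j in (i + 1L):ng) {
      xi <- curves[[i]]$lx - delta * log_m[i]
      xj <- curves[[j]]$lx - delta * log_m[j]
      lo <- max(min(xi), min(xj))
      hi <- min(max(xi), max(xj))
      if (hi <= lo) {
        # no overlap: penalize by the gap so the optimizer is guided back
        total <- total + 100 * (lo - hi)
        npairs <- npairs + 1L
        next
      }
      xs <- seq(lo, hi, length.out = n_grid)
      yi <- stats::approx(xi, curves[[i]]$ly, xs)$y
      yj <- stats::approx(xj, curves[[j]]$ly, xs)$y
      total <- total + mean(abs(yi - yj))
      npairs <- npairs + 1L
    }
  }
  # the distance is symmetric, so the sum over ordered pairs is twice the
  # sum over unordered pairs
  2 * total
}

# minimal differential evolution (rand/1/bin) for the 1-d collapse problem;
# deterministic under the supplied seed
.de_optimize <- function(fn, lower, upper, np = 20L, f = 0.8, cr = 0.9,
                         iters = 60L, seed = 1L, tol = 1e-7) {
  set.seed(as.integer(seed))
  pop <- stats::runif(np, lower, upper)
  val <- vapply(pop, fn, 0)
  trace <- data.frame(iter = 0L, best = pop[which.min(val)],
                      value = min(val))
  for (it in seq_len(iters)) {
    for (k in seq_len(np)) {
      abc <- sample(setdiff(seq_len(np), k), 3L)
      mutant <- pop[abc[1]] + f * (pop[abc[2]] - pop[abc[3]])
      mutant <- min(max(mutant, lower), upper)
      trial <- if (stats::runif(1) < cr) mutant else pop[k]
      tv <- fn(trial)
      if (tv <= val[k]) { pop[k] <- trial; val[k] <- tv }
    }
    trace <- rbind(trace, data.frame(iter = it, best = pop[which.min(val)],
                                     value = min(val)))
    if (diff(range(pop)) < tol) break
  }
  b <- which.min(val)
  list(par = pop[b], value = val[b], trace = trace)
}

#' Finite-size scaling collapse of per-geometry distributions
#'
#' Estimates the scaling exponent \eqn{\delta} (reported in the field as the
#' allometric exponent \eqn{\alpha}) that best collapses the tissue-OCR
#' distributions of differently sized tissues onto one master curve, by
#' minimizing the probability-contiguity distance with differential
#' evolution over a bracket of candidate exponents.
#'
#' @param samples A list of numeric vectors (tissue OCR per geometry), or a
#'   \code{\link{run_pom}} result.
#' @param masses Mean mass per geometry (any common unit); taken from the
#'   PoM result if one is supplied.
#' @param beta Normalization exponent (fixed to 1 by convention).
#' @param delta_bounds Search bracket for the exponent.
#' @param seed Seed for the optimizer.
#' @param np,iters Differential-evolution population size and generations.
#' @return An object of class \code{collapse_result}: \code{delta},
#'   \code{alpha} (synonym), \code{beta}, the collapse \code{distance}, the
#'   optimizer trace, the master-curve table at the optimum, and a
#'   \code{degenerate} flag (identical masses collapse for any exponent).
#' @export
collapse_distributions <- function(samples, masses = NULL, beta = 1,
                                   delta_bounds = c(0.3, 1.5), seed = 1L,
                                   np = 20L, iters = 60L) {
  if (inherits(samples, "pom_result")) {
    if (is.null(masses)) masses <- samples$masses
    ok <- stats::complete.cases(samples$B)
    samples <- lapply(seq_len(ncol(samples$B)),
                      function(j) samples$B[ok, j])
  }
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(masses) || length(masses) != length(samples)) {
    stop("'masses' must give one mean mass per geometry", call. = FALSE)
  }
  stopifnot(all(masses > 0), all(is.finite(delta_bounds)),
            delta_bounds[1] < delta_bounds[2])

  curves <- .collapse_curves(samples, beta)
  log_m <- log(masses)
  degenerate <- stats::sd(log_m) < 1e-12
  if (degenerate) {
    warning("degenerate collapse: all masses equal; ",
            "distance is independent of the exponent")
  }

  fn <- function(d) .collapse_distance(curves, log_m, d)
  opt <- .de_optimize(fn, delta_bounds[1], delta_bounds[2],
                      np = np, iters = iters, seed = seed)

  xopt <- opt$par
  master <- do.call(rbind, lapply(seq_along(curves), function(i) {
    data.frame(geometry = i,
               x = curves[[i]]$lx - xopt * log_m[i],
               y = curves[[i]]$ly)
  }))

  structure(list(
    delta = xopt, alpha = xopt, beta = beta,
    distance = opt$value, degenerate = degenerate,
    optimizer = opt$trace, master_curve = master,
    delta_bounds = delta_bounds, seed = seed,
    n_geometries = length(curves), masses = masses
  ), class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf(
    "collapse_result: delta (alpha) = %.4f, beta = %g, distance = %.4g (%d geometries)\n",
    x$delta, x$beta, x$distance, x$n_geometries))
  invisible(x)
}

#' Collapse-distance profile over a grid of exponents
#'
#' Dense scan of the collapse objective, used as the independent oracle for
#' the differential-evolution optimum and for local identifiability checks.
#'
#' @param samples,masses,beta As in \code{\link{collapse_distributions}}.
#' @param deltas Vector of candidate exponents.
#' @return Data frame with \code{delta} and \code{distance}.
#' @export
collapse_profile <- function(samples, masses = NULL, beta = 1,
                             deltas = seq(0.3, 1.5, by = 0.001)) {
  if (inherits(samples, "pom_result")) {
    if (is.null(masses)) masses <- samples$masses
    ok <- stats::complete.cases(samples$B)
    samples <- lapply(seq_len(ncol(samples$B)),
                      function(j) samples$B[ok, j])
  }
  curves <- .collapse_curves(samples, beta)
  log_m <- log(masses)
  data.frame(delta = deltas,
             distance = vapply(deltas, function(d)
               .collapse_distance(curves, log_m, d), 0))
}
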