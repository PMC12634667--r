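# Steady Michaelis-Menten oxygen reaction-diffusion in the boxed microtissue.
#
# The tissue is a rectangular box; oxygen diffuses with diffusivity D and is
# consumed at the Michaelis-Menten rate
#   R = -sOCR * rho_c * c / (k_m + c).
# Side walls see the media oxygen concentration (Dirichlet), the glass floor
# is no-flux, and the PDMS roof passes oxygen with a lumped mass-transfer
# coefficient (Robin). Discretization: cell-centred finite volumes on a
# structured grid; the saturable sink is lagged (Picard) as a linear
# coefficient rho_c * sOCR / (k_m + c_old), which keeps the operator an
# M-matrix and the iterates positive.

#' Boxed tissue domain
#'
#' The three printed microtissue geometries: V1 (243.8 x 621.6 x 62.35 um),
#' V2 (V1 with doubled height) and V3 (288 x 950 x 124.7 um), or a custom
#' box.
#'
#' @param geometry \code{"V1"}, \code{"V2"}, \code{"V3"} or \code{"custom"}.
#' @param dims Box edge lengths c(Lx, Ly, Lz) in um (for \code{"custom"}).
#' @param n Grid cells per direction, c(nx, ny, nz); \code{NULL} picks a
#'   resolution with at least 10 cells across the smallest edge.
#' @return An object of class \code{tissue_domain}.
#' @export
tissue_domain <- function(geometry = c("V1", "V2", "V3", "custom"),
                          dims = NULL, n = NULL) {
  geometry <- match.arg(geometry)
  presets <- list(V1 = c(243.8, 621.6, 62.35),
                  V2 = c(243.8, 621.6, 124.7),
                  V3 = c(288, 950, 124.7))
  if (geometry == "custom") {
    if (is.null(dims) || length(dims) != 3 || any(dims <= 0)) {
      stop("custom geometry needs dims = c(Lx, Ly, Lz) > 0", call. = FALSE)
    }
  } else {
    dims <- presets[[geometry]]
  }
  if (is.null(n)) {
    h <- min(dims) / 10
    n <- pmax(4L, as.integer(round(dims / h)))
    n <- pmin(n, c(64L, 128L, 64L))
  }
  n <- as.integer(n)
  if (length(n) != 3 || any(n < 4)) {
    stop("grid must have at least 4 cells per direction", call. = FALSE)
  }
  if (n[3] < 10) {
    stop("grid must resolve the smallest (z) dimension with >= 10 cells",
         call. = FALSE)
  }
  structure(list(
    geometry = geometry, dims = dims, n = n,
    volume_um3 = prod(dims)
  ), class = "tissue_domain")
}

#' @export
print.tissue_domain <- function(x, ...) {
  cat(sprintf("tissue_domain %s: %.4g x %.4g x %.4g um (%d x %d x %d cells)\n",
              x$geometry, x$dims[1], x$dims[2], x$dims[3],
              x$n[1], x$n[2], x$n[3]))
  invisible(x)
}

#' Oxygen transport and consumption parameters
#'
#' Defaults are the printed study values: Michaelis constant 6.9e-3 mol/m^3,
#' cell density 1.95e14 cells/m^3, media-side oxygen 0.21 mol/m^3, critical
#' (viability) concentration 0.04 mol/m^3. Tissue oxygen diffusivity is not
#' printed; the default 2e-9 m^2/s is a typical cardiac-tissue literature
#' value and the acceptance analyses sweep the band [1-3]e-9 m^2/s. The PDMS
#' roof coefficient defaults to D_PDMS / t_PDMS with D_PDMS = 3.4e-9 m^2/s
#' across a 2 mm slab.
#'
#' @param socr Single-cell oxygen consumption rate (mol/s per cell).
#' @param diffusivity Oxygen diffusivity in tissue (m^2/s).
#' @param km Michaelis constant (mol/m^3).
#' @param cell_density Cells per m^3.
#' @param c_side Side-wall (media) oxygen concentration (mol/m^3).
#' @param c_critical Viability threshold (mol/m^3).
#' @param k_pdms PDMS roof mass-transfer coefficient (m/s).
#' @param c_ambient Ambient oxygen above the PDMS (mol/m^3).
#' @return An object of class \code{oxygen_parameters}.
#' @export
oxygen_parameters <- function(socr = 4.67e-17, diffusivity = 2e-9,
                              km = 6.9e-3, cell_density = 1.95e14,
                              c_side = 0.21, c_critical = 0.04,
                              k_pdms = 3.4e-9 / 2e-3, c_ambient = 0.21) {
  if (!is.numeric(socr) || socr < 0) stop("'socr' must be >= 0", call. = FALSE)
  stopifnot_positive(diffusivity, "diffusivity")
  stopifnot_positive(km, "km")
  stopifnot_positive(cell_density, "cell_density")
  stopifnot_positive(c_side, "c_side")
  stopifnot_positive(c_critical, "c_critical")
  if (km >= c_side) stop("'km' must be below 'c_side'", call. = FALSE)
  if (!is.numeric(k_pdms) || k_pdms < 0) {
    stop("'k_pdms' must be >= 0", call. = FALSE)
  }
  structure(list(
    socr = socr, diffusivity = diffusivity, km = km,
    cell_density = cell_density, c_side = c_side,
    c_critical = c_critical, k_pdms = k_pdms, c_ambient = c_ambient
  ), class = "oxygen_parameters")
}

# assemble the constant part of the FV operator; returns a list with the
# Laplacian triplets, boundary rhs, and face bookkeeping for flux integrals
.oxygen_operator <- function(domain, params) {
  n <- domain$n
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  hx <- um_to_m(domain$dims[1]) / nx
  hy <- um_to_m(domain$dims[2]) / ny
  hz <- um_to_m(domain$dims[3]) / nz
  N <- nx * ny * nz
  D <- params$diffusivity
  idx <- function(i, j, k) ((k - 1L) * ny + (j - 1L)) * nx + i

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_acc <- numeric(N)
  rhs <- numeric(N)

  add_int <- function(a, b, cond) {
    ii <<- c(ii, a, b); jj <<- c(jj, b, a)
    vv <<- c(vv, -cond, -cond)
    diag_acc[a] <<- diag_acc[a] + cond
    diag_acc[b] <<- diag_acc[b] + cond
  }

  ij <- expand.grid(j = seq_len(ny), k = seq_len(nz))
  # x-interior faces
  for (i in seq_len(nx - 1L)) {
    a <- idx(i, ij$j, ij$k); b <- idx(i + 1L, ij$j, ij$k)
    add_int(a, b, rep(D * hy * hz / hx, nrow(ij)))
  }
  ik <- expand.grid(i = seq_len(nx), k = seq_len(nz))
  for (j in seq_len(ny - 1L)) {
    a <- idx(ik$i, j, ik$k); b <- idx(ik$i, j + 1L, ik$k)
    add_int(a, b, rep(D * hx * hz / hy, nrow(ik)))
  }
  ijk <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  for (k in seq_len(nz - 1L)) {
    a <- idx(ijk$i, ijk$j, k); b <- idx(ijk$i, ijk$j, k + 1L)
    add_int(a, b, rep(D * hx * hy / hz, nrow(ijk)))
  }

  # Dirichlet side walls (x and y faces): ghost at half-spacing
  side <- list()
  a <- idx(rep(1L, nrow(ij)), ij$j, ij$k)
  side$xlo <- list(cells = a, cond = rep(2 * D * hy * hz / hx, nrow(ij)))
  a <- idx(rep(nx, nrow(ij)), ij$j, ij$k)
  side$xhi <- list(cells = a, cond = rep(2 * D * hy * hz / hx, nrow(ij)))
  a <- idx(ik$i, rep(1L, nrow(ik)), ik$k)
  side$ylo <- list(cells = a, cond = rep(2 * D * hx * hz / hy, nrow(ik)))
  a <- idx(ik$i, rep(ny, nrow(ik)), ik$k)
  side$yhi <- list(cells = a, cond = rep(2 * D * hx * hz / hy, nrow(ik)))
  for (s in side) {
    diag_acc[s$cells] <- diag_acc[s$cells] + s$cond
    rhs[s$cells] <- rhs[s$cells] + s$cond * params$c_side
  }

  # PDMS roof (z top): Robin with effective coefficient folding in the half
  # cell of tissue
  a <- idx(ijk$i, ijk$j, rep(nz, nrow(ijk)))
  keff <- params$k_pdms / (1 + params$k_pdms * hz / (2 * D))
  top_cond <- rep(keff * hx * hy, nrow(ijk))
  diag_acc[a] <- diag_acc[a] + top_cond
  rhs[a] <- rhs[a] + top_cond * params$c_ambient
  top <- list(cells = a, cond = top_cond)
  # floor (z bottom): no-flux, nothing to add

  A0 <- Matrix::forceSymmetric(Matrix::sparseMatrix(
    i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
    x = c(vv, diag_acc), dims = c(N, N)))

  list(A0 = A0, rhs = rhs, side = side, top = top, N = N,
       h = c(hx, hy, hz), cell_volume = hx * hy * hz)
}

#' Solve the steady oxygen field in a tissue box
#'
#' Picard iteration on the Michaelis-Menten sink about the linearized
#' coefficient \eqn{\rho_c\,sOCR/(k_m + c)}, with damping, down to a relative
#' nonlinear residual below \code{tol}.
#'
#' @param domain A \code{\link{tissue_domain}}.
#' @param params An \code{\link{oxygen_parameters}}.
#' @param tol Relative nonlinear residual target.
#' @param max_iter Iteration cap.
#' @param damping Picard damping factor in (0, 1].
#' @param init Optional initial concentration field (vector of length
#'   prod(n)), e.g. a previous solution for warm starts.
#' @param operator Optional precomputed operator from a previous solve on
#'   the same domain/params (reused across a population of models).
#' @return An object of class \code{oxygen_solution}: the concentration
#'   array \code{c} (mol/m^3), \code{c_min}, tissue OCR \code{B} (mol/s),
#'   the volume-integrated consumption, convergence diagnostics and the
#'   domain/params.
#' @export
solve_oxygen_steady <- function(domain, params, tol = 1e-8,
                                max_iter = 150L, damping = 0.7,
                                init = NULL, operator = NULL) {
  stopifnot(inherits(domain, "tissue_domain"),
            inherits(params, "oxygen_parameters"))
  op <- operator %||% .oxygen_operator(domain, params)
  N <- op$N
  vol <- op$cell_volume
  rr <- params$cell_density * params$socr      # max volumetric rate (mol/m^3/s)

  cvec <- if (is.null(init)) rep(params$c_side, N) else pmax(init, 0)
  res_hist <- numeric(0)
  rhs_norm <- max(sqrt(sum(op$rhs^2)), 1e-300)
  coef_fun <- function(cv) rr / (params$km + cv) * vol

  # Picard with a frozen diagonal shift: factor A0 + s I once and iterate by
  # backsolves, moving the difference (coef(c) - s) c to the right-hand
  # side; the shift is refreshed if convergence stalls. The factor is cached
  # on the operator and reused across nearby solves (population runs walk
  # through sorted sOCR draws, so consecutive shifts are close).
  conv <- FALSE
  it <- 0L
  shift <- mean(coef_fun(cvec))
  if (!is.null(op$chol) && is.finite(op$chol_shift) && op$chol_shift > 0 &&
      abs(shift - op$chol_shift) < 0.5 * (shift + op$chol_shift) / 2) {
    chol <- op$chol
    shift <- op$chol_shift
  } else {
    chol <- Matrix::Cholesky(op$A0 + Matrix::Diagonal(N, rep(shift, N)),
                             LDL = FALSE, super = TRUE)
    op$chol <- chol; op$chol_shift <- shift
  }
  refactors <- 0L
  while (it < max_iter) {
    it <- it + 1L
    coef <- coef_fun(cvec)
    b <- op$rhs + (shift - coef) * cvec
    cnew <- pmax(as.numeric(Matrix::solve(chol, b)), 0)
    cvec_next <- damping * cnew + (1 - damping) * cvec
    sink <- rr * cvec_next / (params$km + cvec_next) * vol
    res <- as.numeric(op$A0 %*% cvec_next) + sink - op$rhs
    rel <- sqrt(sum(res^2)) / rhs_norm
    res_hist <- c(res_hist, rel)
    cvec <- cvec_next
    if (rel < tol) { conv <- TRUE; break }
    stalled <- length(res_hist) >= 4 &&
      rel > 0.5 * res_hist[length(res_hist) - 3]
    if (stalled) {
      refactors <- refactors + 1L
      if (refactors <= 2L) {
        # refresh the frozen shift
        shift <- mean(coef_fun(cvec))
        chol <- Matrix::Cholesky(op$A0 + Matrix::Diagonal(N, rep(shift, N)),
                                 LDL = FALSE, super = TRUE)
        op$chol <- chol; op$chol_shift <- shift
      } else {
        # strongly depleted cases: fall back to fully re-linearized,
        # progressively damped Picard (exact diagonal each iteration)
        damping <- max(0.3, damping * 0.7)
        while (it < max_iter && !conv) {
          it <- it + 1L
          coef <- coef_fun(cvec)
          Af <- op$A0 + Matrix::Diagonal(N, coef)
          cnew <- pmax(as.numeric(Matrix::solve(Af, op$rhs)), 0)
          cvec_next <- damping * cnew + (1 - damping) * cvec
          sink <- rr * cvec_next / (params$km + cvec_next) * vol
          res <- as.numeric(op$A0 %*% cvec_next) + sink - op$rhs
          rel <- sqrt(sum(res^2)) / rhs_norm
          res_hist <- c(res_hist, rel)
          cvec <- cvec_next
          if (rel < tol) conv <- TRUE
          if (length(res_hist) >= 6 &&
              rel > 0.9 * res_hist[length(res_hist) - 5]) {
            damping <- max(0.2, damping * 0.7)
          }
        }
        break
      }
    }
  }
  if (!conv) {
    stop(sprintf(
      "solver error: Picard iteration not converged (residuals %s)",
      paste(signif(utils::tail(res_hist, 3), 3), collapse = ", ")),
      call. = FALSE)
  }

  # tissue OCR as the surface integral of inward oxygen flux
  B <- 0
  for (s in op$side) {
    B <- B + sum(s$cond * (params$c_side - cvec[s$cells]))
  }
  B <- B + sum(op$top$cond * (params$c_ambient - cvec[op$top$cells]))
  consumed <- sum(rr * cvec / (params$km + cvec)) * vol

  structure(list(
    c = array(cvec, dim = domain$n), c_vec = cvec,
    c_min = min(cvec), c_max = max(cvec),
    B = B, consumed = consumed,
    iterations = it, residuals = res_hist,
    domain = domain, params = params, operator = op
  ), class = "oxygen_solution")
}

#' @export
print.oxygen_solution <- function(x, ...) {
  cat(sprintf(
    "oxygen_solution (%s): c_min = %.4g mol/m3, B = %.4g mol/s (%d iterations)\n",
    x$domain$geometry, x$c_min, x$B, x$iterations))
  invisible(x)
}

#' Tissue oxygen consumption rate (surface-flux integral)
#'
#' The tissue OCR \eqn{B} is the surface integral of the inward oxygen flux
#' over all boundaries of the converged steady solution; by the divergence
#' theorem it equals the volume-integrated Michaelis-Menten consumption, and
#' the discrete solver preserves that identity to the nonlinear tolerance.
#'
#' @param solution A converged \code{\link{oxygen_solution}}.
#' @return Tissue OCR (mol/s).
#' @export
tissue_ocr <- function(solution) {
  stopifnot(inherits(solution, "oxygen_solution"))
  solution$B
}

#' Minimum oxygen concentration, with viability flag
#'
#' @param solution An \code{\link{oxygen_solution}}.
#' @return The global minimum concentration (mol/m^3), with attribute
#'   \code{viable} indicating whether it stays above the critical
#'   concentration.
#' @export
min_oxygen <- function(solution) {
  stopifnot(inherits(solution, "oxygen_solution"))
  structure(solution$c_min,
            viable = solution$c_min >= solution$params$c_critical)
}
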