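# Reduced quasi-static two-phase invasion simulator.
#
# The air-water interface is a liquid indicator field on the plan-view grid.
# At a given applied pressure the interface advances into any open frontier
# cell whose local capillary entry pressure is below the applied pressure;
# advance is monotone, so a sweep that fills nothing is a genuinely pinned
# state. The entry pressure is the Young-Laplace pressure of the in-plane
# meniscus spanning the local pore: for a meniscus anchored on walls a span s
# apart whose tangents diverge by the half-angle phi,
#   p_entry = 2 * gamma * (-cos(theta_a + phi)) / s,
# with theta_a the effective advancing contact angle and theta_a + phi capped
# at 180 degrees (semicircular cap). Span and divergence angle are read from
# the domain's precomputed geometry fields. The out-of-plane (gap-wise)
# capillary term is excluded by default; see the methods vignette.

.shift <- function(m, di, dj) {
  nx <- nrow(m); nj <- ncol(m)
  i <- pmin(pmax(seq_len(nx) + di, 1L), nx)
  j <- pmin(pmax(seq_len(nj) + dj, 1L), nj)
  m[i, j]
}

# per-cell capillary entry pressure (Pa)
.entry_pressure <- function(domain, fluids, out_of_plane) {
  gamma <- fluids$surface_tension
  theta_a <- deg_to_rad(fluids$contact_angle_adv)
  theta_eff <- pmin(pmax(theta_a + domain$wall_angle, 0), pi)
  resist <- 2 * gamma * (-cos(theta_eff)) / um_to_m(domain$span)
  if (out_of_plane == "static") {
    theta_c <- deg_to_rad(fluids$contact_angle)
    resist <- resist - 2 * gamma * cos(theta_c) / um_to_m(domain$depth)
  }
  resist[is.na(resist)] <- Inf   # solid cells never fill
  resist
}

#' Simulate quasi-static liquid invasion of a fenestra at fixed pressure
#'
#' Advances the air-water interface from the inlet chamber across the fenestra
#' under a constant applied pressure. The interface invades any frontier cell
#' whose capillary entry pressure is below the applied pressure; the run ends
#' with outcome \code{"burst"} when liquid crosses the fenestra exit into the
#' outlet region, or \code{"pinned"} when a full sweep advances nothing (or
#' \code{t_max} elapses).
#'
#' @param domain A \code{\link{valve_domain}}.
#' @param applied_pressure Applied pressure at the liquid inlet (Pa).
#' @param fluids A \code{\link{fluid_properties}}.
#' @param t_max Cap on simulated time (s).
#' @param out_of_plane \code{"none"} (default; flat gap-wise front) or
#'   \code{"static"} (adds the equilibrium gap-wise term
#'   \eqn{-2\gamma\cos\theta_c/d(x)}; retained for sensitivity analysis).
#' @param max_sweeps Safety cap on interface-update sweeps.
#' @return An object of class \code{two_phase_state}: the final liquid
#'   indicator field \code{phi}, \code{outcome}, elapsed \code{time} (s), and
#'   a trace of fenestra liquid volume fraction against time.
#' @export
simulate_invasion <- function(domain, applied_pressure, fluids,
                              t_max = 10, out_of_plane = c("none", "static"),
                              max_sweeps = 5000L) {
  stopifnot(inherits(domain, "valve_domain"),
            inherits(fluids, "fluid_properties"))
  out_of_plane <- match.arg(out_of_plane)
  if (!is.numeric(applied_pressure) || applied_pressure < 0) {
    stop("'applied_pressure' must be >= 0", call. = FALSE)
  }
  resist <- .entry_pressure(domain, fluids, out_of_plane)
  solid <- domain$solid

  phi <- matrix(0, domain$nx, domain$ny)
  phi[domain$xc < domain$x_fen[1], ] <- 1   # inlet chamber pre-filled
  phi[solid] <- 0

  fen <- domain$fen_cols
  fen_open <- sum(!solid[fen, ])
  burst_col <- max(fen) + 1L
  d_fen_m <- um_to_m(domain$fenestra$height)
  l_fen_m <- um_to_m(diff(domain$x_fen))

  time <- 0
  trace_t <- 0
  trace_f <- sum(phi[fen, ]) / fen_open
  outcome <- "pinned"
  sweep <- 0L

  repeat {
    sweep <- sweep + 1L
    liquid <- phi >= 0.5
    nb <- .shift(liquid, 1L, 0L) | .shift(liquid, -1L, 0L) |
          .shift(liquid, 0L, 1L) | .shift(liquid, 0L, -1L)
    frontier <- nb & !liquid & !solid
    fill <- frontier & (applied_pressure > resist)

    if (!any(fill)) { outcome <- "pinned"; break }

    excess <- max(applied_pressure - resist[fill])
    v <- excess * d_fen_m^2 / (12 * fluids$viscosity * l_fen_m)
    dt <- if (v > 0) um_to_m(domain$dx) / v else t_max
    time <- time + dt
    phi[fill] <- 1

    trace_t <- c(trace_t, time)
    trace_f <- c(trace_f, sum(phi[fen, ]) / fen_open)

    if (burst_col <= domain$nx && any(phi[burst_col:domain$nx, ] >= 0.5)) {
      outcome <- "burst"; break
    }
    if (time > t_max || sweep >= max_sweeps) { outcome <- "pinned"; break }
  }

  structure(list(
    phi = phi, outcome = outcome, time = time,
    applied_pressure = applied_pressure,
    trace = data.frame(time_s = trace_t, fenestra_fill = trace_f),
    sweeps = sweep, out_of_plane = out_of_plane
  ), class = "two_phase_state")
}

#' @export
print.two_phase_state <- function(x, ...) {
  cat(sprintf("two_phase_state: %s at %.4g Pa after %d sweeps (t = %.3g s)\n",
              x$outcome, x$applied_pressure, x$sweeps, x$time))
  invisible(x)
}

#' Resolve the burst pressure of a fenestra by bisection
#'
#' Brackets the burst pressure between a pinned and a bursting applied
#' pressure and bisects until the bracket is narrower than \code{tol}. The
#' result carries the nondimensional burst pressure
#' \eqn{p^* = \Delta p_b D_h / \gamma_{lv}}.
#'
#' @param domain A \code{\link{valve_domain}}.
#' @param fluids A \code{\link{fluid_properties}}.
#' @param p_lo,p_hi Initial bracket (Pa). Defaults: 0 and \eqn{4\gamma/D_h}.
#' @param tol Bisection tolerance (Pa). Default 2\% of the initial bracket
#'   width; pass a tighter value when the resolved pressure itself is the
#'   quantity of interest.
#' @param ... Passed to \code{\link{simulate_invasion}}.
#' @return An object of class \code{burst_result} with fields
#'   \code{burst_pressure} (Pa), \code{p_star}, \code{outcome} and the
#'   bisection \code{history}.
#' @export
find_burst_pressure <- function(domain, fluids, p_lo = 0, p_hi = NULL,
                                tol = NULL, ...) {
  stopifnot(inherits(domain, "valve_domain"),
            inherits(fluids, "fluid_properties"))
  dh_m <- um_to_m(domain$fenestra$hydraulic_diameter)

  if (fluids$surface_tension == 0) {
    # no capillary resistance: any positive pressure bursts
    return(structure(list(
      burst_pressure = 0, p_star = 0, outcome = "burst",
      bracket = c(0, 0), tol = 0,
      history = data.frame(pressure = numeric(0), outcome = character(0)),
      domain = domain$fenestra$kind), class = "burst_result"))
  }

  if (is.null(p_hi)) p_hi <- 4 * fluids$surface_tension / dh_m
  if (is.null(tol)) tol <- 0.02 * (p_hi - p_lo)
  stopifnot(p_hi > p_lo, tol > 0)

  history <- data.frame(pressure = numeric(0), outcome = character(0))
  run <- function(p) {
    st <- simulate_invasion(domain, p, fluids, ...)
    history <<- rbind(history,
                      data.frame(pressure = p, outcome = st$outcome))
    st$outcome
  }

  if (run(p_lo) != "pinned") {
    stop("bracketing error: lower bound already bursts", call. = FALSE)
  }
  if (run(p_hi) != "burst") {
    stop("bracketing error: upper bound does not burst", call. = FALSE)
  }
  lo <- p_lo; hi <- p_hi
  while ((hi - lo) > tol) {
    mid <- (lo + hi) / 2
    if (run(mid) == "burst") hi <- mid else lo <- mid
  }
  p_b <- (lo + hi) / 2
  structure(list(
    burst_pressure = p_b,
    p_star = nondimensional_pressure(p_b, domain$fenestra$hydraulic_diameter,
                                     fluids$surface_tension),
    outcome = "burst", bracket = c(lo, hi), tol = tol,
    history = history, domain = domain$fenestra$kind
  ), class = "burst_result")
}

#' @export
print.burst_result <- function(x, ...) {
  cat(sprintf("burst_result (%s): dp_b = %.4g Pa, p* = %.3g\n",
              x$domain, x$burst_pressure, x$p_star))
  invisible(x)
}

#' Nondimensional pressure
#'
#' \eqn{p^* = p D_h / \gamma_{lv}}, the burst-valve nondimensionalization.
#'
#' @param p Pressure (Pa).
#' @param d_h Hydraulic diameter (um).
#' @param gamma Surface tension (N/m).
#' @return Dimensionless pressure.
#' @examples
#' nondimensional_pressure(4050, 3.2, 0.072)  # 0.18
#' @export
nondimensional_pressure <- function(p, d_h, gamma) {
  if (!is.numeric(gamma) || gamma <= 0) {
    stop("'gamma' must be > 0", call. = FALSE)
  }
  stopifnot_positive(d_h, "d_h")
  p * um_to_m(d_h) / gamma
}

#' Young-Laplace bounds on the quasi-static burst pressure
#'
#' Closed-form oracle for the grid simulator. For a straight slot of width
#' \eqn{w} the transit resistance of an advancing meniscus at the effective
#' advancing angle \eqn{\theta_a} is \eqn{2\gamma(-\cos\theta_a)/w} and the
#' semicircular-cap bound is \eqn{2\gamma/w}. For a pillar pore the contact
#' lines slide around the pillar surfaces; an arc anchored at sliding angle
#' \eqn{\varphi} resists \eqn{2\gamma(-\cos(\theta_a+\varphi))/s(\varphi)}
#' with span \eqn{s(\varphi) = g + d_p(1-\cos\varphi)}, and the quasi-static
#' burst pressure is the maximum of that resistance over \eqn{\varphi}.
#'
#' @param fenestra A \code{\link{fenestra_geometry}}.
#' @param fluids A \code{\link{fluid_properties}}.
#' @return Named numeric vector with \code{lower} (transit resistance at the
#'   throat), \code{upper} (semicircular cap at the throat) and
#'   \code{sliding_max} (pillar fenestrae only, else \code{NA}).
#' @export
quasistatic_burst_bounds <- function(fenestra, fluids) {
  stopifnot(inherits(fenestra, "fenestra_geometry"),
            inherits(fluids, "fluid_properties"))
  gamma <- fluids$surface_tension
  th <- deg_to_rad(fluids$contact_angle_adv)
  w <- um_to_m(fenestra$width)
  lower <- 2 * gamma * max(0, -cos(th)) / w
  upper <- 2 * gamma / w
  sliding <- NA_real_
  if (fenestra$kind == "pillar_array") {
    dp <- um_to_m(fenestra$layout$pillar_diameter)
    phis <- seq(0, pi - th, length.out = 2000)
    span <- w + dp * (1 - cos(phis))
    sliding <- max(2 * gamma * (-cos(th + phis)) / span)
  }
  c(lower = lower, upper = upper, sliding_max = sliding)
}
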