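# Computational domain for the burst-valve simulator: a plan-view grid of the
# single-fenestra model (inlet chamber -> fenestra -> outlet region), with a
# solid mask describing either a straight microchannel or a pillar-array pore.

#' Build the plan-view domain for the single-fenestra burst model
#'
#' The domain reproduces the single-fenestra burst geometry: an inlet chamber
#' (150 x 200 um footprint, 20 um deep), a fenestra of given length whose
#' depth is the fenestra height, and an outlet region. For a
#' \code{straight_channel} fenestra the strip is solid except for a slot of
#' the fenestra width; for a \code{pillar_array} fenestra the strip carries a
#' channel one pillar pitch wide, constricted mid-length by two opposing
#' half-pillars whose surface gap is the pore size, i.e. a
#' converging-diverging pore.
#'
#' @param fenestra A \code{\link{fenestra_geometry}}.
#' @param dx Grid spacing (um). Default resolves the pore with 8 cells.
#' @param inlet_length,outlet_length,width Plan dimensions of the inlet
#'   chamber, outlet region and domain width (um).
#' @param inlet_depth,outlet_depth Out-of-plane depths (um) used for the
#'   optional static out-of-plane capillary term and the nominal velocity
#'   scale.
#' @return An object of class \code{valve_domain}: grids, solid mask, depth
#'   map and region labels.
#' @export
valve_domain <- function(fenestra, dx = NULL,
                         inlet_length = 150, outlet_length = 75,
                         width = 200, inlet_depth = 20, outlet_depth = 20) {
  stopifnot(inherits(fenestra, "fenestra_geometry"))
  pore <- fenestra$width
  if (is.null(dx)) dx <- pore / 8
  if (pore / dx < 6) {
    stop(sprintf(
      "resolution error: pore of %g um needs >= 6 cells, got %.1f at dx = %g",
      pore, pore / dx, dx), call. = FALSE)
  }

  lx <- inlet_length + fenestra$length + outlet_length
  nx <- as.integer(round(lx / dx))
  ny <- as.integer(round(width / dx))
  xc <- (seq_len(nx) - 0.5) * dx          # cell centres
  yc <- (seq_len(ny) - 0.5) * dx
  x0 <- inlet_length                       # fenestra entrance
  x1 <- inlet_length + fenestra$length     # fenestra exit

  in_fen <- xc >= x0 & xc < x1
  solid <- matrix(FALSE, nx, ny)
  depth <- matrix(inlet_depth, nx, ny)
  depth[xc >= x1, ] <- outlet_depth
  depth[in_fen, ] <- fenestra$height

  ymid <- width / 2
  if (fenestra$kind == "straight_channel") {
    open_half <- fenestra$width / 2
    wall <- outer(in_fen, abs(yc - ymid) > open_half, `&`)
    solid[wall] <- TRUE
  } else {
    lay <- fenestra$layout
    pitch <- lay$pillar_diameter + lay$pore_size
    open_half <- pitch / 2
    wall <- outer(in_fen, abs(yc - ymid) > open_half, `&`)
    solid[wall] <- TRUE
    # two opposing half-pillars centred on the channel walls at mid-length
    r <- lay$pillar_diameter / 2
    px <- (x0 + x1) / 2
    for (py in c(ymid - open_half, ymid + open_half)) {
      d2 <- outer((xc - px)^2, (yc - py)^2, `+`)
      solid[d2 <= r^2] <- TRUE
    }
  }

  # solid frame on the lateral walls; inlet column is the liquid reservoir,
  # outlet column stays open
  solid[, 1] <- TRUE
  solid[, ny] <- TRUE

  geo <- .span_fields(solid, dx)

  structure(list(
    fenestra = fenestra, dx = dx, nx = nx, ny = ny, xc = xc, yc = yc,
    x_fen = c(x0, x1), width = width,
    inlet_depth = inlet_depth, outlet_depth = outlet_depth,
    solid = solid, depth = depth,
    span = geo$span, wall_angle = geo$wall_angle,
    inlet_cells = which(!solid[1, ]),
    outlet_col = nx,
    fen_cols = which(xc >= x0 & xc < x1)
  ), class = "valve_domain")
}

# Per-cell meniscus span and wall divergence angle, assuming advance along +x.
# The span of the meniscus through an open cell is the length of the
# contiguous open run it belongs to along y; the wall divergence half-angle
# follows from the upstream one-sided widening rate of the run,
# tan(phi) = (dW/dx)/2. The raw run widths are staircase-quantized where
# walls are oblique or curved, which would alias into spurious angle spikes,
# so the span profile seen by each cell is averaged over a ~2 um window along
# x (within open columns) before differencing. Upstream differencing
# deliberately leaves the exit plane of a constriction free of the Gibbs
# corner penalty: reaching the outlet-adjacent plane is the burst criterion,
# and the capillary landscape beyond it is outside the depth-averaged
# description.
.span_fields <- function(solid, dx) {
  nx <- nrow(solid); ny <- ncol(solid)
  span <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) {
    r <- rle(!solid[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      if (r$values[j]) span[i, starts[j]:ends[j]] <- r$lengths[j] * dx
    }
  }

  # x-window average of span over open columns at the same y; columns whose
  # span differs from the cell's own by more than a factor of two are
  # excluded, so the window never averages across an abrupt region change
  # (e.g. the fenestra exit) - only the staircase noise of oblique walls
  hw <- max(2L, as.integer(ceiling(3 / dx)))
  acc <- matrix(0, nx, ny)
  cnt <- matrix(0, nx, ny)
  open <- !is.na(span)
  sp0 <- span; sp0[!open] <- 0
  for (k in -hw:hw) {
    spk <- .shift(sp0, k, 0L)
    ok <- .shift(open, k, 0L) & spk <= 2 * sp0 & spk >= 0.5 * sp0
    acc <- acc + ifelse(ok, spk, 0)
    cnt <- cnt + ok
  }
  span_sm <- matrix(NA_real_, nx, ny)
  span_sm[open] <- acc[open] / pmax(cnt[open], 1)

  wall_angle <- matrix(0, nx, ny)
  for (i in 2:nx) {
    here <- open[i, ] & open[i - 1L, ]
    if (!any(here)) next
    dw <- span_sm[i, ] - span_sm[i - 1L, ]
    wall_angle[i, here] <- atan(dw[here] / (2 * dx))
  }
  list(span = span_sm, wall_angle = wall_angle)
}

#' @export
print.valve_domain <- function(x, ...) {
  cat(sprintf(
    "valve_domain: %s fenestra, %d x %d cells at dx = %g um (%.0f x %.0f um)\n",
    x$fenestra$kind, x$nx, x$ny, x$dx, x$nx * x$dx, x$ny * x$dx))
  invisible(x)
}
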