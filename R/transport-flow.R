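# Depth-averaged (Hele-Shaw) flow across the MPS device.
#
# The device is a plan-view domain with region-dependent depth: 150 um deep
# media channels and cell chamber, and a shallow (2-10 um) barrier strip
# perforated by pillar pores. Lubrication theory turns the Stokes problem
# into a variable-conductance Poisson equation for pressure,
#   div( (d^3 / 12 mu) grad p ) = 0,
# with inflow at the media-channel inlets, reference pressure at the
# outlets, and no-flux elsewhere. Depth-averaged velocity is
# u = -(d^2 / 12 mu) grad p.

#' Transport configuration for the MPS device
#'
#' Bundles the device geometry, solute properties and the perfusion rate.
#'
#' @param device A \code{\link{device_geometry}}, or \code{NULL} with
#'   \code{layout = "duct"}.
#' @param diffusivity Solute diffusivity (cm^2/s); default albumin,
#'   9.3e-7.
#' @param c0 Inlet concentration (nM); default 7.46.
#' @param flow_rate Media perfusion rate (uL/h), split over the two media
#'   channels (all of it through the single duct for \code{layout = "duct"}).
#' @param viscosity,density Media properties (Pa s, kg/m^3).
#' @param peclet_length Characteristic length for the Peclet number (um);
#'   default the 300 um chamber width.
#' @param dx_channel,dx_barrier,dy Grid spacings (um): across channels and
#'   chamber, across the barrier strip, and along the device.
#' @param layout \code{"device"} (full chamber + channels + barriers) or
#'   \code{"duct"} (an isolated straight media channel, used to verify the
#'   discrete operator against plug flow).
#' @param perfusion Channel plumbing. \code{"loop"} (default): the two media
#'   channels are segments of one serpentine path - media enters the first
#'   channel, turns around past the chamber end through a connecting segment,
#'   and leaves through the second channel (one inlet, one outlet, as the
#'   device is operated), so the chamber sees a sustained cross-barrier
#'   pressure difference and both channels carry the perfused medium.
#'   \code{"single"}: one channel perfused, the other held at reference
#'   pressure. \code{"both"}: symmetric parallel perfusion.
#' @param link_length Length of the serpentine connecting segment (um), used
#'   for \code{perfusion = "loop"}.
#' @return An object of class \code{transport_config}.
#' @export
transport_config <- function(device = device_geometry(),
                             diffusivity = 9.3e-7, c0 = 7.46,
                             flow_rate = 20,
                             viscosity = 1e-3, density = 1000,
                             peclet_length = 300,
                             dx_channel = 5, dx_barrier = 3.125, dy = 2,
                             layout = c("device", "duct"),
                             perfusion = c("loop", "single", "both"),
                             link_length = 650) {
  layout <- match.arg(layout)
  perfusion <- match.arg(perfusion)
  stopifnot_positive(link_length, "link_length")
  stopifnot_positive(diffusivity, "diffusivity")
  if (!is.numeric(flow_rate) || flow_rate < 0) {
    stop("'flow_rate' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(c0) || c0 < 0) stop("'c0' must be >= 0", call. = FALSE)
  if (layout == "device") stopifnot(inherits(device, "device_geometry"))
  structure(list(
    device = device, diffusivity = diffusivity, c0 = c0,
    flow_rate = flow_rate, viscosity = viscosity, density = density,
    peclet_length = peclet_length,
    dx_channel = dx_channel, dx_barrier = dx_barrier, dy = dy,
    layout = layout, perfusion = perfusion, link_length = link_length
  ), class = "transport_config")
}

# tensor-product grid with region-dependent depth and solid mask
.flow_grid <- function(config) {
  dev <- config$device
  if (config$layout == "duct") {
    wx <- dev$channel_width %||% 100
    ly <- dev$chamber_length %||% 708
    nxs <- max(6L, round(wx / config$dx_channel))
    xf <- seq(0, wx, length.out = nxs + 1)
    region <- rep("channel", nxs)
    depth_ref <- c(channel = dev$channel_height %||% 150)
  } else {
    bw <- dev$barrier$length        # barrier strip width in flow direction
    widths <- c(dev$channel_width, bw, dev$chamber_width, bw,
                dev$channel_width)
    kinds <- c("channel", "barrier", "chamber", "barrier", "channel")
    steps <- c(config$dx_channel, config$dx_barrier, config$dx_channel,
               config$dx_barrier, config$dx_channel)
    xf <- 0; region <- character(0)
    for (k in seq_along(widths)) {
      n <- max(4L, round(widths[k] / steps[k]))
      xf <- c(xf, utils::tail(xf, 1) + seq_len(n) * widths[k] / n)
      region <- c(region, rep(kinds[k], n))
    }
    ly <- dev$chamber_length
    depth_ref <- c(channel = dev$channel_height,
                   barrier = dev$barrier$height,
                   chamber = dev$chamber_height)
  }
  nx <- length(xf) - 1L
  xc <- (xf[-1] + xf[-(nx + 1)]) / 2
  dxv <- diff(xf)
  ny <- max(6L, round(ly / config$dy))
  yf <- seq(0, ly, length.out = ny + 1)
  yc <- (yf[-1] + yf[-(ny + 1)]) / 2
  dyv <- diff(yf)

  depth <- matrix(depth_ref[region], nx, ny)
  solid <- matrix(FALSE, nx, ny)

  if (config$layout == "device" &&
      dev$barrier$kind == "pillar_array") {
    lay <- dev$barrier$layout
    r <- lay$pillar_diameter / 2
    bcols <- which(region == "barrier")
    # two barrier strips; pillar rows run along y at each strip centre
    strip_id <- cumsum(c(1, diff(bcols) > 1))
    for (s in unique(strip_id)) {
      cols <- bcols[strip_id == s]
      x0 <- xf[min(cols)]; x1 <- xf[max(cols) + 1]
      xpc <- (x0 + x1) / 2
      for (cy in lay$centers) {
        ix <- cols[abs(xc[cols] - xpc) <= r]
        if (!length(ix)) next
        d2 <- outer((xc[ix] - xpc)^2, (yc - cy)^2, `+`)
        blk <- d2 <= r^2
        solid[ix, ][blk] <- TRUE
      }
    }
  }
  if (config$layout == "device" && isTRUE(dev$chamber_pillars)) {
    ccols <- which(region == "chamber")
    xpc <- mean(range(xc[ccols]))
    rp <- dev$chamber_pillar_diameter / 2
    cys <- dev$chamber_length / 2 +
      dev$chamber_pillar_spacing * c(-1, 0, 1)
    for (cy in cys) {
      ix <- ccols[abs(xc[ccols] - xpc) <= rp]
      d2 <- outer((xc[ix] - xpc)^2, (yc - cy)^2, `+`)
      blk <- d2 <= rp^2
      solid[ix, ][blk] <- TRUE
    }
  }

  chan <- which(region == "channel")
  blocks <- cumsum(c(1, diff(chan) > 1))
  list(nx = nx, ny = ny, xc = xc, yc = yc, dxv = dxv, dyv = dyv,
       region = region, depth = depth, solid = solid,
       channel_cols = chan,
       channel_a_cols = chan[blocks == 1],
       channel_b_cols = chan[blocks == max(blocks)],
       chamber_cols = which(region == "chamber"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve the steady depth-averaged flow in the device
#'
#' Sets up and solves the variable-conductance pressure Poisson problem with
#' the configured perfusion rate injected at the media-channel inlets
#' (y = 0), reference pressure at the media-channel outlets (y = L), no-slip
#' solids and no-flux walls, then reconstructs the depth-averaged velocity
#' field.
#'
#' @param config A \code{\link{transport_config}}.
#' @return An object of class \code{flow_solution}: pressure (Pa),
#'   cell-centred velocity components and speed (um/s), face fluxes (m^3/s),
#'   the grid, the chamber volume-averaged speed \code{vbar} (um/s) and the
#'   Peclet number at the configured characteristic length.
#' @export
solve_flow <- function(config) {
  stopifnot(inherits(config, "transport_config"))
  g <- .flow_grid(config)
  mu <- config$viscosity
  nx <- g$nx; ny <- g$ny
  n <- nx * ny
  idx <- function(i, j) (j - 1L) * nx + i

  dm <- um_to_m(g$depth)
  Tc <- dm^3 / (12 * mu)              # transmissivity (m^3/(Pa s) per m width)
  Tc[g$solid] <- 0
  dxm <- um_to_m(g$dxv); dym <- um_to_m(g$dyv)

  harm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_acc <- numeric(n)
  rhs <- numeric(n)

  add_face <- function(ia, ja, ib, jb, cond) {
    a <- idx(ia, ja); b <- idx(ib, jb)
    keep <- cond > 0
    ii <<- c(ii, a[keep], b[keep]); jj <<- c(jj, b[keep], a[keep])
    vv <<- c(vv, -cond[keep], -cond[keep])
    diag_acc[a[keep]] <<- diag_acc[a[keep]] + cond[keep]
    diag_acc[b[keep]] <<- diag_acc[b[keep]] + cond[keep]
    invisible(NULL)
  }

  # x-direction faces
  for (i in seq_len(nx - 1L)) {
    cond <- harm(Tc[i, ], Tc[i + 1L, ]) * dym /
      ((g$dxv[i] + g$dxv[i + 1L]) / 2 * 1e-6)
    add_face(rep(i, ny), seq_len(ny), rep(i + 1L, ny), seq_len(ny), cond)
  }
  # y-direction faces
  for (j in seq_len(ny - 1L)) {
    cond <- harm(Tc[, j], Tc[, j + 1L]) * dxm /
      ((g$dyv[j] + g$dyv[j + 1L]) / 2 * 1e-6)
    add_face(seq_len(nx), rep(j, nx), seq_len(nx), rep(j + 1L, nx), cond)
  }

  # perfusion plumbing: influx at the inlet (y = 0) of the perfused
  # channel(s), reference pressure p = 0 at the outlet port(s), and for the
  # serpentine loop a lumped connecting segment joining the far ends of the
  # two channels
  mode <- if (config$layout == "duct") "duct" else config$perfusion
  qin <- ulh_to_m3s(config$flow_rate)
  ch <- switch(mode,
               duct = g$channel_cols,
               both = g$channel_cols,
               g$channel_a_cols)
  ch <- ch[!g$solid[ch, 1L]]
  w <- dxm[ch]
  rhs[idx(ch, rep(1L, length(ch)))] <- qin * w / sum(w)

  link_pairs <- NULL
  if (mode == "loop") {
    # serpentine: outlet is the second channel's near port (y = 0)
    chb <- g$channel_b_cols
    out_faces <- cbind(col = chb, row = rep(1L, length(chb)))
    # connecting segment: mirror-pair the far-end (y = L) cells of the two
    # channels and split the lumped conductance over the pairs
    na <- length(g$channel_a_cols)
    pa <- g$channel_a_cols
    pb <- rev(g$channel_b_cols)
    np <- min(na, length(pb))
    T_link <- um_to_m(config$device$channel_height)^3 / (12 * mu)
    g_link <- T_link * um_to_m(config$device$channel_width) /
      um_to_m(config$link_length)
    link_pairs <- cbind(a = idx(pa[seq_len(np)], rep(ny, np)),
                        b = idx(pb[seq_len(np)], rep(ny, np)),
                        cond = g_link / np)
    ii <- c(ii, link_pairs[, "a"], link_pairs[, "b"])
    jj <- c(jj, link_pairs[, "b"], link_pairs[, "a"])
    vv <- c(vv, rep(-link_pairs[, "cond"], 2))
    diag_acc[link_pairs[, "a"]] <- diag_acc[link_pairs[, "a"]] +
      link_pairs[, "cond"]
    diag_acc[link_pairs[, "b"]] <- diag_acc[link_pairs[, "b"]] +
      link_pairs[, "cond"]
  } else if (mode == "single") {
    chb <- g$channel_b_cols
    out_faces <- rbind(cbind(col = ch, row = rep(ny, length(ch))),
                       cbind(col = chb, row = rep(1L, length(chb))),
                       cbind(col = chb, row = rep(ny, length(chb))))
  } else {
    out_faces <- cbind(col = ch, row = rep(ny, length(ch)))
  }
  out_faces <- out_faces[!g$solid[out_faces], , drop = FALSE]
  half_dy <- dym[out_faces[, "row"]] / 2
  cond_out <- Tc[out_faces] * dxm[out_faces[, "col"]] / half_dy
  iout <- idx(out_faces[, "col"], out_faces[, "row"])
  diag_acc[iout] <- diag_acc[iout] + cond_out
  out_cols <- out_faces[, "col"]

  # solid / fully isolated cells: identity rows
  iso <- diag_acc == 0
  diag_acc[iso] <- 1

  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(vv, diag_acc), dims = c(n, n))
  if (qin > 0 && length(out_cols) == 0) {
    stop("solver error: no outlet available (fully blocked barrier?)",
         call. = FALSE)
  }
  p <- as.numeric(Matrix::solve(A, rhs))
  P <- matrix(p, nx, ny)

  # conservative face volumetric fluxes (m^3/s); interior faces only, plus
  # the inlet influx and outlet Dirichlet faces in y
  Fx <- matrix(0, nx + 1L, ny)
  for (i in seq_len(nx - 1L)) {
    cond <- harm(Tc[i, ], Tc[i + 1L, ]) * dym /
      ((g$dxv[i] + g$dxv[i + 1L]) / 2 * 1e-6)
    Fx[i + 1L, ] <- cond * (P[i, ] - P[i + 1L, ])
  }
  Fy <- matrix(0, nx, ny + 1L)
  for (j in seq_len(ny - 1L)) {
    cond <- harm(Tc[, j], Tc[, j + 1L]) * dxm /
      ((g$dyv[j] + g$dyv[j + 1L]) / 2 * 1e-6)
    Fy[, j + 1L] <- cond * (P[, j] - P[, j + 1L])
  }
  Fy[cbind(ch, 1L)] <- rhs[idx(ch, rep(1L, length(ch)))]    # inflow, +y
  for (k in seq_len(nrow(out_faces))) {
    cl <- out_faces[k, "col"]; rw <- out_faces[k, "row"]
    if (rw == ny) {
      Fy[cl, ny + 1L] <- cond_out[k] * P[cl, ny]
    } else {
      Fy[cl, 1L] <- Fy[cl, 1L] - cond_out[k] * P[cl, 1L]
    }
  }

  # cell-centred depth-averaged velocity from adjacent face fluxes
  ux_m <- ((Fx[seq_len(nx), ] + Fx[2:(nx + 1L), ]) / 2) /
    (dm * outer(rep(1, nx), dym))
  uy_m <- ((Fy[, seq_len(ny)] + Fy[, 2:(ny + 1L)]) / 2) /
    (dm * outer(dxm, rep(1, ny)))
  ux_m[g$solid] <- 0; uy_m[g$solid] <- 0
  ux_m[!is.finite(ux_m)] <- 0; uy_m[!is.finite(uy_m)] <- 0
  speed <- sqrt(ux_m^2 + uy_m^2)
  P[g$solid] <- NA

  link <- NULL
  if (!is.null(link_pairs)) {
    link <- data.frame(a = link_pairs[, "a"], b = link_pairs[, "b"],
                       flux = link_pairs[, "cond"] *
                         (p[link_pairs[, "a"]] - p[link_pairs[, "b"]]))
  }

  sol <- structure(list(
    config = config, grid = g, pressure = P,
    ux = m_to_um(ux_m), uy = m_to_um(uy_m), speed = m_to_um(speed),
    flux_x = Fx, flux_y = Fy, link = link,
    inlet_cols = ch, out_faces = out_faces, cond_out = cond_out,
    A = A, rhs = rhs, out_cols = out_cols
  ), class = "flow_solution")
  sol$vbar <- chamber_mean_velocity(sol)
  sol$peclet <- peclet_number(sol$vbar, config$peclet_length,
                              config$diffusivity)
  sol
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "flow_solution: Q = %g uL/h, chamber vbar = %.4g um/s, Pe(L = %g um) = %.3g\n",
    x$config$flow_rate, x$vbar, x$config$peclet_length, x$peclet))
  invisible(x)
}

#' Volume-averaged speed over the cell chamber
#'
#' Depth-weighted average of the speed magnitude over the (open) chamber
#' region; for the duct layout, over the whole duct.
#'
#' @param flow A \code{\link{flow_solution}}.
#' @return Mean speed (um/s).
#' @export
chamber_mean_velocity <- function(flow) {
  stopifnot(inherits(flow, "flow_solution"))
  g <- flow$grid
  cols <- if (flow$config$layout == "duct") seq_len(g$nx) else g$chamber_cols
  mask <- matrix(FALSE, g$nx, g$ny)
  mask[cols, ] <- TRUE
  mask[g$solid] <- FALSE
  if (!any(mask)) stop("geometry error: empty chamber mask", call. = FALSE)
  wt <- (g$depth * outer(g$dxv, g$dyv))[mask]
  sum(flow$speed[mask] * wt) / sum(wt)
}

#' Peclet number
#'
#' \eqn{Pe = \bar{v} L / D}, the ratio of advective to diffusive transport
#' rates; \eqn{Pe < 1} indicates diffusion-dominant transport into the
#' chamber.
#'
#' @param vbar Mean speed (um/s).
#' @param L Characteristic length (um).
#' @param D Diffusivity (cm^2/s).
#' @return Dimensionless Peclet number.
#' @examples
#' peclet_number(0.476, 273, 9.3e-7)  # ~1.4
#' @export
peclet_number <- function(vbar, L, D) {
  stopifnot_positive(L, "L")
  stopifnot_positive(D, "D")
  if (!is.numeric(vbar) || vbar < 0) stop("'vbar' must be >= 0", call. = FALSE)
  (vbar * 1e-6) * um_to_m(L) / cm2s_to_m2s(D)
}
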