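# Transient advection-diffusion of a dilute solute (albumin) across the
# barrier, on the same depth-weighted finite-volume grid as the flow solve.
# Advection uses the conservative face fluxes of the flow solution with
# upwinding; diffusion uses harmonic-mean face depths. Time integration is
# implicit Euler with a fixed step, so the system matrix is factorized once.

#' Simulate solute transport into the cell chamber
#'
#' Marches the depth-averaged advection-diffusion equation for the solute
#' concentration with inlet concentration \code{c0} at the perfused media
#' inlet, outflow at the outlet ports, and no-flux walls/solids, and records
#' the chamber space-averaged concentration.
#'
#' @param config A \code{\link{transport_config}}.
#' @param flow A \code{\link{flow_solution}} for the same config (solved if
#'   missing).
#' @param t_end End time (h).
#' @param dt Time step (h).
#' @return An object of class \code{concentration_trace}: a data frame
#'   \code{trace} with \code{t_hours} and \code{c_over_c0}, plus chamber
#'   volume (m^3), barrier area (m^2, chamber-facing face convention) and
#'   bookkeeping needed for permeability and mass-balance checks.
#' @export
simulate_solute_transport <- function(config, flow = NULL, t_end = 60,
                                      dt = 0.05) {
  stopifnot(inherits(config, "transport_config"))
  if (is.null(flow)) flow <- solve_flow(config)
  stopifnot(inherits(flow, "flow_solution"))
  stopifnot_positive(t_end, "t_end")
  stopifnot_positive(dt, "dt")

  g <- flow$grid
  nx <- g$nx; ny <- g$ny; n <- nx * ny
  idx <- function(i, j) (j - 1L) * nx + i
  dxm <- um_to_m(g$dxv); dym <- um_to_m(g$dyv)
  dm <- um_to_m(g$depth)
  open <- !g$solid
  Dm <- cm2s_to_m2s(config$diffusivity)

  vol <- dm * outer(dxm, dym)          # cell volumes (m^3)
  vol[!open] <- 0

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_acc <- numeric(n)
  rhs_c0 <- numeric(n)                  # inflow source per unit concentration

  harm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)

  add_pair <- function(a, b, flux, dcond) {
    # flux: volumetric advective flux from a to b (m^3/s); dcond: diffusive
    # conductance (m^3/s)
    up <- pmax(flux, 0); dn <- pmax(-flux, 0)
    keep <- dcond > 0 | flux != 0
    a <- a[keep]; b <- b[keep]; up <- up[keep]; dn <- dn[keep]
    dc <- dcond[keep]
    # row a: -(dc + dn) * c_b ; diag a: + (dc + up)
    ii <<- c(ii, a, b); jj <<- c(jj, b, a)
    vv <<- c(vv, -(dc + dn), -(dc + up))
    diag_acc[a] <<- diag_acc[a] + dc + up
    diag_acc[b] <<- diag_acc[b] + dc + dn
    invisible(NULL)
  }

  for (i in seq_len(nx - 1L)) {
    ok <- open[i, ] & open[i + 1L, ]
    if (!any(ok)) next
    j <- which(ok)
    dcond <- Dm * harm(dm[i, j], dm[i + 1L, j]) * dym[j] /
      ((g$dxv[i] + g$dxv[i + 1L]) / 2 * 1e-6)
    add_pair(idx(i, j), idx(i + 1L, j), flow$flux_x[i + 1L, j], dcond)
  }
  for (j in seq_len(ny - 1L)) {
    ok <- open[, j] & open[, j + 1L]
    if (!any(ok)) next
    i <- which(ok)
    dcond <- Dm * harm(dm[i, j], dm[i, j + 1L]) * dxm[i] /
      ((g$dyv[j] + g$dyv[j + 1L]) / 2 * 1e-6)
    add_pair(idx(i, j), idx(i, j + 1L), flow$flux_y[i, j + 1L], dcond)
  }

  # serpentine connecting segment: advective coupling between channel ends
  if (!is.null(flow$link)) {
    add_pair(flow$link$a, flow$link$b, flow$link$flux,
             numeric(nrow(flow$link)))
  }

  # inlet: advective influx carries c0, and the inlet port also exchanges
  # diffusively with the feed at c0 (this is what lets a zero-flow device
  # equilibrate by diffusion alone)
  inlet <- idx(flow$inlet_cols, rep(1L, length(flow$inlet_cols)))
  fin <- flow$flux_y[cbind(flow$inlet_cols, 1L)]
  din <- Dm * dm[cbind(flow$inlet_cols, 1L)] * dxm[flow$inlet_cols] /
    (dym[1L] / 2)
  rhs_c0[inlet] <- rhs_c0[inlet] + pmax(fin, 0) + din
  diag_acc[inlet] <- diag_acc[inlet] + pmax(-fin, 0) + din
  if (nrow(flow$out_faces) > 0) {
    of <- idx(flow$out_faces[, "col"], flow$out_faces[, "row"])
    fout <- ifelse(flow$out_faces[, "row"] == ny,
                   flow$flux_y[cbind(flow$out_faces[, "col"], ny + 1L)],
                   -flow$flux_y[cbind(flow$out_faces[, "col"], 1L)])
    diag_acc[of] <- diag_acc[of] + pmax(fout, 0)
  }

  dts <- hours_to_s(dt)
  vdt <- as.numeric(vol) / dts
  iso <- vdt == 0 & diag_acc == 0
  diag_acc[iso] <- 1

  # row-equilibrate: cell volumes span many orders of magnitude between the
  # shallow barrier and the deep channels
  rscale <- 1 / (diag_acc + vdt)
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(vv * rscale[ii], rep(1, n)),
                            dims = c(n, n))
  lu <- Matrix::lu(A)

  c0 <- nM_to_molm3(config$c0)
  cden <- if (c0 > 0) c0 else 1      # report c/c0; a zero-c0 trace stays 0
  cvec <- numeric(n)
  src <- rhs_c0 * c0

  cham <- matrix(FALSE, nx, ny)
  cols <- if (config$layout == "duct") seq_len(nx) else g$chamber_cols
  cham[cols, ] <- TRUE
  cham[g$solid] <- FALSE
  wch <- as.numeric(vol)[as.logical(cham)]
  chi <- which(as.logical(cham))

  out_idx <- integer(0); out_flux <- numeric(0)
  if (nrow(flow$out_faces) > 0) {
    out_idx <- idx(flow$out_faces[, "col"], flow$out_faces[, "row"])
    out_flux <- pmax(ifelse(flow$out_faces[, "row"] == ny,
                            flow$flux_y[cbind(flow$out_faces[, "col"], ny + 1L)],
                            -flow$flux_y[cbind(flow$out_faces[, "col"], 1L)]),
                     0)
  }

  nsteps <- ceiling(t_end / dt)
  tt <- numeric(nsteps + 1L)
  cc <- numeric(nsteps + 1L)
  tt[1] <- 0; cc[1] <- 0
  inflow_int <- 0; outflow_int <- 0
  for (s in seq_len(nsteps)) {
    b <- (vdt * cvec + src) * rscale
    cvec <- as.numeric(Matrix::solve(lu, b))
    tt[s + 1L] <- s * dt
    cc[s + 1L] <- sum(cvec[chi] * wch) / sum(wch) / cden
    inflow_int <- inflow_int +
      (sum(src) - sum(din * cvec[inlet])) * dts
    if (length(out_idx)) {
      outflow_int <- outflow_int + sum(out_flux * cvec[out_idx]) * dts
    }
  }

  dev <- config$device
  chamber_volume <- sum(wch)
  barrier_area <- if (config$layout == "duct") NA_real_ else
    2 * um_to_m(dev$chamber_length) * um_to_m(dev$chamber_height)

  structure(list(
    trace = data.frame(t_hours = tt, c_over_c0 = cc),
    c0 = c0, chamber_volume = chamber_volume,
    barrier_area = barrier_area,
    barrier_area_convention = "chamber-facing barrier face area, both sides",
    total_mass = sum(cvec * as.numeric(vol)),
    inflow_mass = inflow_int, outflow_mass = outflow_int,
    final_field = matrix(cvec, nx, ny),
    config = config
  ), class = "concentration_trace")
}

#' @export
print.concentration_trace <- function(x, ...) {
  cat(sprintf(
    "concentration_trace: %d samples to %.3g h, final c/c0 = %.3f\n",
    nrow(x$trace), max(x$trace$t_hours), utils::tail(x$trace$c_over_c0, 1)))
  invisible(x)
}

#' Barrier permeability evaluated at half saturation
#'
#' \eqn{P = V_{ch} (dc/dt)|_{c = 0.5 c_0} / (A_b (c_0 - 0.5 c_0))}, with the
#' derivative taken by centred difference on the stored trace at the
#' half-saturation crossing. For a clean exponential trace
#' \eqn{c(t) = c_0 (1 - e^{-kt})} this reduces to \eqn{k V_{ch} / A_b}
#' exactly.
#'
#' @param trace A \code{\link{simulate_solute_transport}} result (or any
#'   object with a \code{trace} data frame in the same layout).
#' @param chamber_volume Chamber volume (m^3); defaults to the trace's.
#' @param barrier_area Barrier exchange area (m^2); defaults to the trace's
#'   chamber-facing face-area convention.
#' @return Permeability (cm/s).
#' @export
permeability_at_half_saturation <- function(trace, chamber_volume = NULL,
                                            barrier_area = NULL) {
  tr <- trace$trace
  stopifnot(is.data.frame(tr), all(c("t_hours", "c_over_c0") %in% names(tr)))
  if (is.null(chamber_volume)) chamber_volume <- trace$chamber_volume
  if (is.null(barrier_area)) barrier_area <- trace$barrier_area
  stopifnot_positive(chamber_volume, "chamber_volume")
  stopifnot_positive(barrier_area, "barrier_area")

  cfrac <- tr$c_over_c0
  tv <- tr$t_hours
  k <- which(cfrac >= 0.5)[1]
  if (is.na(k) || k == 1L) {
    stop("not-reached error: trace never crosses 0.5 c0", call. = FALSE)
  }
  # centred-difference derivative at the stored samples, linearly
  # interpolated to the half-saturation crossing
  slope <- function(i) {
    lo <- max(i - 1L, 1L); hi <- min(i + 1L, length(cfrac))
    (cfrac[hi] - cfrac[lo]) / hours_to_s(tv[hi] - tv[lo])
  }
  w <- (0.5 - cfrac[k - 1L]) / (cfrac[k] - cfrac[k - 1L])
  dcdt <- (1 - w) * slope(k - 1L) + w * slope(k)    # units of c0 per s
  p_ms <- chamber_volume * dcdt / (barrier_area * 0.5)
  p_ms * 100   # m/s -> cm/s
}

#' Time for the chamber to equilibrate to a threshold fraction of c0
#'
#' First time the chamber-averaged concentration reaches
#' \code{threshold * c0}, linearly interpolated between stored samples.
#'
#' @param trace A \code{\link{simulate_solute_transport}} result.
#' @param threshold Fraction of \code{c0} in (0, 1]; default 0.95.
#' @return Equilibration time (h).
#' @export
equilibration_time <- function(trace, threshold = 0.95) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("'threshold' must be in (0, 1]", call. = FALSE)
  }
  tr <- trace$trace
  cfrac <- tr$c_over_c0
  if (cfrac[1] >= threshold) return(0)
  k <- which(cfrac >= threshold)[1]
  if (is.na(k)) {
    stop(sprintf("not-reached error: trace never reaches %.3g c0", threshold),
         call. = FALSE)
  }
  t0 <- tr$t_hours[k - 1L]; t1 <- tr$t_hours[k]
  c0f <- cfrac[k - 1L]; c1f <- cfrac[k]
  t0 + (threshold - c0f) / (c1f - c0f) * (t1 - t0)
}
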