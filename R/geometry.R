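# Parametric geometry of the pillar-array barrier and the MPS device.
#
# The barrier is a shallow strip separating the cell chamber from a media
# channel, perforated either by a single straight microchannel or by the gaps
# ("pores") between a row of circular pillars. All lengths are micrometres.

#' Hydraulic diameter of a rectangular duct
#'
#' For a rectangular cross-section of height \code{h} and width \code{w} the
#' hydraulic diameter is \eqn{D_h = 2hw/(h+w)}, the standard equivalence
#' metric between channel-type and membrane-type pores.
#'
#' @param height Duct height (um).
#' @param width Duct width (um).
#' @return Hydraulic diameter (um).
#' @examples
#' hydraulic_diameter(4, 4)   # square duct: D_h equals the side
#' hydraulic_diameter(2, 8)   # the 2 um x 8 um fenestra: 3.2 um
#' @export
hydraulic_diameter <- function(height, width) {
  stopifnot_positive(height, "height")
  stopifnot_positive(width, "width")
  2 * height * width / (height + width)
}

#' Construct a pillar-array barrier layout
#'
#' Places \code{n_pillars} equal circular pillars on a line along the barrier
#' region, with gaps of exactly \code{pore_size} between adjacent pillar
#' surfaces. Under the default \code{"end_gaps"} convention the pillars are
#' also separated from the region ends by one pore each (n + 1 gaps), so the
#' array acts as a barrier rather than a wall; \code{"internal_only"} uses
#' n - 1 gaps.
#'
#' @param n_pillars Number of pillars (>= 1).
#' @param pore_size Gap between adjacent pillar surfaces (um, >= 0).
#' @param region_length Barrier region extent along the pillar line (um).
#' @param region_width Barrier region extent across the flow direction (um).
#' @param height Pillar (= barrier) height (um).
#' @param gap_convention \code{"end_gaps"} or \code{"internal_only"}.
#' @return An object of class \code{pillar_layout} with the resolved pillar
#'   diameter and centre positions.
#' @examples
#' lay <- build_pillar_layout(8, 8, region_length = 708)
#' lay$pillar_diameter  # 79.5 um
#' @export
build_pillar_layout <- function(n_pillars, pore_size, region_length,
                                region_width = 125, height = 2,
                                gap_convention = c("end_gaps", "internal_only")) {
  gap_convention <- match.arg(gap_convention)
  if (!is.numeric(n_pillars) || n_pillars < 1 || n_pillars %% 1 != 0) {
    stop("'n_pillars' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(pore_size) || pore_size < 0) {
    stop("'pore_size' must be non-negative", call. = FALSE)
  }
  stopifnot_positive(region_length, "region_length")
  stopifnot_positive(region_width, "region_width")
  stopifnot_positive(height, "height")

  n_gaps <- if (gap_convention == "end_gaps") n_pillars + 1 else n_pillars - 1
  d <- (region_length - n_gaps * pore_size) / n_pillars
  if (d <= 0) {
    stop(sprintf(
      "infeasible layout: %d pillars with %g um pores do not fit in %g um",
      n_pillars, pore_size, region_length), call. = FALSE)
  }
  pitch <- d + pore_size
  first <- if (gap_convention == "end_gaps") pore_size + d / 2 else d / 2
  centers <- first + pitch * (seq_len(n_pillars) - 1)

  structure(list(
    region_length = region_length,
    region_width = region_width,
    n_pillars = as.integer(n_pillars),
    pillar_diameter = d,
    pore_size = pore_size,
    height = height,
    gap_convention = gap_convention,
    centers = centers
  ), class = "pillar_layout")
}

#' @export
print.pillar_layout <- function(x, ...) {
  cat(sprintf(
    "pillar_layout: %d pillars, d = %.3g um, pore = %.3g um, region %g x %g um, height %g um (%s)\n",
    x$n_pillars, x$pillar_diameter, x$pore_size,
    x$region_length, x$region_width, x$height, x$gap_convention))
  invisible(x)
}

#' Plan-view porosity of a pillar layout
#'
#' Void fraction of the rectangular barrier region in plan view,
#' \eqn{1 - n \pi (d/2)^2 / (L W)}. Because the pillars span the full barrier
#' height the volume fraction equals the plan-area fraction, so porosity is
#' independent of height.
#'
#' @param layout A \code{pillar_layout}.
#' @return Porosity in [0, 1].
#' @export
porosity <- function(layout) {
  stopifnot(inherits(layout, "pillar_layout"))
  solid <- layout$n_pillars * pi * (layout$pillar_diameter / 2)^2
  p <- 1 - solid / (layout$region_length * layout$region_width)
  max(0, min(1, p))
}

#' Porous (void) volume of a pillar layout
#'
#' Porosity times region plan area times height; exactly linear in height,
#' which is the knob that tunes the barrier's hydraulic resistance at fixed
#' pore size.
#'
#' @param layout A \code{pillar_layout}.
#' @return Void volume (um^3).
#' @export
porous_volume <- function(layout) {
  stopifnot(inherits(layout, "pillar_layout"))
  porosity(layout) * layout$region_length * layout$region_width * layout$height
}

#' Fenestra geometry (straight microchannel or pillar-array pore)
#'
#' Describes the single fenestra used by the burst-valve simulator: either a
#' straight microchannel of given width, or a pillar-array pore whose throat
#' gap is taken from a \code{pillar_layout}. The hydraulic diameter is derived
#' from the (throat) cross-section as \eqn{2hw/(h+w)}.
#'
#' @param kind \code{"straight_channel"} or \code{"pillar_array"}.
#' @param height Fenestra height (um).
#' @param width_or_layout Channel width (um) for a straight fenestra, or a
#'   \code{pillar_layout} for a pillar fenestra.
#' @param length Fenestra length in the flow direction (um).
#' @return An object of class \code{fenestra_geometry}.
#' @examples
#' fenestra_geometry("straight_channel", height = 2, width_or_layout = 8)
#' @export
fenestra_geometry <- function(kind = c("straight_channel", "pillar_array"),
                              height = 2, width_or_layout = 8, length = 125) {
  kind <- match.arg(kind)
  stopifnot_positive(height, "height")
  stopifnot_positive(length, "length")
  if (kind == "straight_channel") {
    stopifnot_positive(width_or_layout, "width_or_layout")
    width <- width_or_layout
    layout <- NULL
  } else {
    if (!inherits(width_or_layout, "pillar_layout")) {
      stop("a pillar_array fenestra needs a pillar_layout", call. = FALSE)
    }
    layout <- width_or_layout
    width <- layout$pore_size   # throat gap sets the pore cross-section
    if (width <= 0) stop("pillar fenestra has zero pore size", call. = FALSE)
  }
  structure(list(
    kind = kind, height = height, width = width, layout = layout,
    length = length,
    hydraulic_diameter = hydraulic_diameter(height, width)
  ), class = "fenestra_geometry")
}

#' @export
print.fenestra_geometry <- function(x, ...) {
  cat(sprintf("fenestra_geometry: %s, h = %g um, w = %g um, L = %g um, D_h = %.3g um\n",
              x$kind, x$height, x$width, x$length, x$hydraulic_diameter))
  invisible(x)
}

#' MPS device geometry
#'
#' Plan-view description of the cardiac MPS: a central cell chamber flanked by
#' two media channels, connected through shallow barrier strips. Defaults are
#' the printed device dimensions (300 um chamber, 100 um channels, 150 um
#' channel/chamber depth, 125 um wide barrier strips).
#'
#' @param chamber_width Cell chamber width (um).
#' @param chamber_height Cell chamber depth (um).
#' @param channel_width Media channel width (um).
#' @param channel_height Media channel depth (um).
#' @param barrier A \code{fenestra_geometry}; its \code{height} is the barrier
#'   strip depth and, for a pillar fenestra, its layout populates the strip.
#' @param chamber_length Chamber (and barrier) extent along the channels (um).
#' @param chamber_pillars Include the three 75 um force-measuring pillars
#'   (225 um spacing) inside the chamber.
#' @return An object of class \code{device_geometry}.
#' @export
device_geometry <- function(chamber_width = 300, chamber_height = 150,
                            channel_width = 100, channel_height = 150,
                            barrier = fenestra_geometry(
                              "pillar_array", height = 2,
                              width_or_layout = build_pillar_layout(8, 8, 708)),
                            chamber_length = 708,
                            chamber_pillars = TRUE) {
  for (nm in c("chamber_width", "chamber_height", "channel_width",
               "channel_height", "chamber_length")) {
    stopifnot_positive(get(nm), nm)
  }
  stopifnot(inherits(barrier, "fenestra_geometry"))
  structure(list(
    chamber_width = chamber_width, chamber_height = chamber_height,
    channel_width = channel_width, channel_height = channel_height,
    barrier = barrier, chamber_length = chamber_length,
    chamber_pillars = isTRUE(chamber_pillars),
    chamber_pillar_diameter = 75, chamber_pillar_spacing = 225
  ), class = "device_geometry")
}

#' Fluid and wetting properties
#'
#' Air-water interfacial properties used by the burst-valve model. The static
#' contact angle is the printed goniometer value; the advancing angle governs
#' invasion in the reduced model and defaults to its supplement (see the
#' methods vignette for the rationale).
#'
#' @param surface_tension Liquid-vapour surface tension (N/m).
#' @param contact_angle Static contact angle (degrees, in (0, 180)).
#' @param contact_angle_adv Effective advancing contact angle (degrees);
#'   default 105, a typical measured advancing angle of water on PDMS.
#' @param viscosity Dynamic viscosity (Pa s).
#' @param density Density (kg/m^3).
#' @return An object of class \code{fluid_properties}.
#' @export
fluid_properties <- function(surface_tension = 0.072, contact_angle = 66,
                             contact_angle_adv = 105,
                             viscosity = 1e-3, density = 1000) {
  if (!is.numeric(surface_tension) || surface_tension < 0) {
    stop("'surface_tension' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(contact_angle) || contact_angle <= 0 || contact_angle >= 180) {
    stop("'contact_angle' must be in (0, 180) degrees", call. = FALSE)
  }
  if (!is.numeric(contact_angle_adv) || contact_angle_adv <= 0 ||
      contact_angle_adv >= 180) {
    stop("'contact_angle_adv' must be in (0, 180) degrees", call. = FALSE)
  }
  stopifnot_positive(viscosity, "viscosity")
  stopifnot_positive(density, "density")
  structure(list(
    surface_tension = surface_tension,
    contact_angle = contact_angle,
    contact_angle_adv = contact_angle_adv,
    viscosity = viscosity, density = density
  ), class = "fluid_properties")
}

#' Export pillar centres and diameters as a data frame
#'
#' @param layout A \code{pillar_layout}.
#' @return A data frame with one row per pillar (centre position along the
#'   barrier line, centre across the region, diameter), suitable for
#'   \code{write.csv}.
#' @export
layout_table <- function(layout) {
  stopifnot(inherits(layout, "pillar_layout"))
  data.frame(
    pillar = seq_len(layout$n_pillars),
    center_along_um = layout$centers,
    center_across_um = rep(layout$region_width / 2, layout$n_pillars),
    diameter_um = rep(layout$pillar_diameter, layout$n_pillars)
  )
}
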