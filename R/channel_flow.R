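# Pressure-driven laminar flow in a rectangular microchannel.
#
# Coordinates: y in [0, w] spanwise (y = 0 at the side wall from which the
# hyphae emerge), z in [0, h] vertical (z = 0 at the floor). The velocity
# field is the classical odd-harmonic series solution with cosh terms across
# the width and sine terms across the height, scaled so that its integral
# over the cross-section equals the imposed volumetric flow rate Q.

#' Measurement-chamber geometry
#'
#' Cross-section of the rectangular measurement chamber. In the floor
#' configuration the hypha rests on the channel floor; in the center
#' configuration a mirrored second half doubles the chamber height and the
#' hypha sits at mid-height, away from any wall.
#'
#' @param width Chamber width w in um (spanwise; hyphae grow along this axis
#'   from a side wall).
#' @param height Chamber height h in um (vertical).
#' @param configuration `"center"` or `"floor"`.
#' @param chamber_length Optional chamber length in um, used when a total
#'   (rather than per-unit-length) resistance is needed.
#' @return An object of class `channel_geometry`.
#' @export
#' @examples
#' channel_geometry(500, 90, "center")
channel_geometry <- function(width, height,
                             configuration = c("center", "floor"),
                             chamber_length = NULL) {
  configuration <- match.arg(configuration)
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stop("`width` must be a single positive number (um)")
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) || height <= 0)
    stop("`height` must be a single positive number (um)")
  if (!is.null(chamber_length) && (!is.numeric(chamber_length) || chamber_length <= 0))
    stop("`chamber_length` must be positive when given")
  structure(
    list(width = width, height = height, configuration = configuration,
         chamber_length = chamber_length),
    class = "channel_geometry"
  )
}

#' Center-configuration twin of a floor-configuration chamber
#'
#' The center configuration is molded from the same master as the floor
#' configuration; only the measurement-chamber height is doubled by bonding
#' a mirrored second half.
#'
#' @param geom A floor-configuration `channel_geometry`.
#' @return A `channel_geometry` in center configuration with doubled height.
#' @export
paired_center_geometry <- function(geom) {
  stopifnot(inherits(geom, "channel_geometry"))
  if (geom$configuration != "floor")
    stop("`geom` must be a floor-configuration chamber")
  channel_geometry(geom$width, 2 * geom$height, "center", geom$chamber_length)
}

#' Working fluid
#'
#' @param viscosity Dynamic viscosity in uN s um^-2 (water is about 1e-9).
#' @return An object of class `fluid`.
#' @export
fluid <- function(viscosity = water_viscosity()) {
  if (!is.numeric(viscosity) || length(viscosity) != 1L ||
      !is.finite(viscosity) || viscosity <= 0)
    stop("`viscosity` must be a single positive number")
  structure(list(viscosity = viscosity), class = "fluid")
}

#' Imposed flow condition
#'
#' @param q_ul_min Volumetric flow rate in uL/min (the pump unit). Exactly
#'   one of `q_ul_min` and `q_um3_s` must be given.
#' @param q_um3_s Volumetric flow rate in um^3/s (the internal unit).
#' @return An object of class `flow_condition` with element `q` in um^3/s.
#' @export
flow_condition <- function(q_ul_min = NULL, q_um3_s = NULL) {
  if (is.null(q_ul_min) == is.null(q_um3_s))
    stop("give exactly one of `q_ul_min` or `q_um3_s`")
  q <- if (is.null(q_um3_s)) ul_min_to_um3_s(q_ul_min) else q_um3_s
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0)
    stop("flow rate must be a single finite number >= 0")
  structure(list(q = q, q_ul_min = um3_s_to_ul_min(q)), class = "flow_condition")
}

# odd harmonics 1, 3, ..., n_max
odd_harmonics <- function(n_max) {
  if (length(n_max) != 1L || !is.finite(n_max) || n_max < 1 || n_max %% 2 != 1)
    stop("`n_max` must be a single odd integer >= 1")
  seq(1L, as.integer(n_max), by = 2L)
}

# cosh(a)/cosh(b) for |a| <= b, overflow-safe for large b
cosh_ratio <- function(a, b) {
  (exp(a - b) + exp(-a - b)) / (1 + exp(-2 * b))
}

check_geom_fluid <- function(geom, fl) {
  if (!inherits(geom, "channel_geometry")) stop("`geom` must be a channel_geometry")
  if (!inherits(fl, "fluid")) stop("`fluid` must be a fluid object")
}

#' Hydraulic resistance per unit length of a rectangular duct
#'
#' Series solution for the pressure drop per unit length and unit flow rate,
#' `R_f = (dp/dx) / Q`. Consistent with [velocity_field()]: the same
#' truncation order makes the cross-section integral of the velocity equal
#' Q exactly.
#'
#' @param geom A [channel_geometry()].
#' @param fluid A [fluid()].
#' @param n_max Odd truncation order of the series (default 51, converged
#'   well below 0.1%).
#' @return Resistance per unit length in uN s um^-6.
#' @export
resistance_per_length <- function(geom, fluid, n_max = 51) {
  check_geom_fluid(geom, fluid)
  w <- geom$width; h <- geom$height; mu <- fluid$viscosity
  n <- odd_harmonics(n_max)
  s <- sum(tanh(n * pi * w / (2 * h)) / n^5)
  denom <- 1 - (192 * h / (pi^5 * w)) * s
  if (denom <= 0) stop("series truncation too low for this aspect ratio")
  12 * mu / (h^3 * w) / denom
}

#' Poiseuille velocity field in a rectangular channel
#'
#' Two-dimensional axial velocity u(y, z) of fully developed pressure-driven
#' laminar flow, scaled so that its integral over the cross-section equals
#' the volumetric flow rate.
#'
#' @param geom A [channel_geometry()].
#' @param fluid A [fluid()].
#' @param flow A [flow_condition()].
#' @param y Spanwise coordinate(s) in um, within `[0, w]`.
#' @param z Vertical coordinate(s) in um, within `[0, h]`; recycled against
#'   `y`.
#' @param n_max Odd series truncation order (default 51).
#' @return Velocity in um/s, vectorised over `y`/`z`.
#' @export
#' @examples
#' g <- channel_geometry(500, 90, "center")
#' velocity_field(g, fluid(), flow_condition(q_ul_min = 10),
#'                y = 250, z = 45)
velocity_field <- function(geom, fluid, flow, y, z, n_max = 51) {
  check_geom_fluid(geom, fluid)
  if (!inherits(flow, "flow_condition")) stop("`flow` must be a flow_condition")
  w <- geom$width; h <- geom$height; mu <- fluid$viscosity
  if (any(!is.finite(y)) || any(y < 0 | y > w))
    stop("`y` must lie within [0, w]")
  if (any(!is.finite(z)) || any(z < 0 | z > h))
    stop("`z` must lie within [0, h]")
  m <- max(length(y), length(z))
  y <- rep_len(y, m); z <- rep_len(z, m)
  gradp <- resistance_per_length(geom, fluid, n_max) * flow$q
  pref <- 4 * gradp * h^2 / (pi^3 * mu)
  u <- numeric(m)
  for (n in odd_harmonics(n_max)) {
    u <- u + (1 / n^3) *
      (1 - cosh_ratio(n * pi * (y - w / 2) / h, n * pi * w / (2 * h))) *
      sin(n * pi * z / h)
  }
  pref * u
}

#' Vertical velocity gradient at the channel floor
#'
#' Term-wise derivative of the series of [velocity_field()] with respect to
#' z, evaluated at the floor (z -> 0). This is the unperturbed wall shear
#' rate that sets the drag on a hypha lying on the floor.
#'
#' @inheritParams velocity_field
#' @return Gradient du/dz at z = 0 in 1/s, vectorised over `y`.
#' @export
wall_velocity_gradient <- function(geom, fluid, flow, y, n_max = 51) {
  check_geom_fluid(geom, fluid)
  if (!inherits(flow, "flow_condition")) stop("`flow` must be a flow_condition")
  w <- geom$width; h <- geom$height; mu <- fluid$viscosity
  if (any(!is.finite(y)) || any(y < 0 | y > w))
    stop("`y` must lie within [0, w]")
  gradp <- resistance_per_length(geom, fluid, n_max) * flow$q
  pref <- 4 * gradp * h / (pi^2 * mu)
  g <- numeric(length(y))
  for (n in odd_harmonics(n_max)) {
    g <- g + (1 / n^2) *
      (1 - cosh_ratio(n * pi * (y - w / 2) / h, n * pi * w / (2 * h)))
  }
  pref * g
}

#' Recover the volumetric flow rate from a measured velocity profile
#'
#' Linear least-squares fit of the single scale factor Q to velocity samples,
#' holding the cross-section geometry fixed. By default only horizontal
#' samples (spanwise profile at mid-height) are used: vertical profiles from
#' particle-image velocimetry carry a depth-of-field artifact near the
#' horizontal walls (apparent velocity floored at roughly 30% of the
#' maximum) and would bias the fit.
#'
#' @param samples Data frame with columns `axis` (`"H"` for a spanwise
#'   profile at mid-height, `"V"` for a vertical profile at mid-width),
#'   `position_um` and `velocity_um_s`, e.g. from
#'   [read_velocity_profiles()] or [simulate_velocity_profiles()].
#' @param geom A [channel_geometry()].
#' @param fluid A [fluid()].
#' @param n_max Odd series truncation order.
#' @param include_vertical Include vertical-axis samples in the fit
#'   (sensitivity studies only; default `FALSE`).
#' @return An object of class `flow_fit`: estimated flow rate (`q_um3_s`,
#'   `q_ul_min`), `residual_norm`, indices of `samples_used`, `n_used`.
#' @export
fit_flow_rate <- function(samples, geom, fluid, n_max = 51,
                          include_vertical = FALSE) {
  check_geom_fluid(geom, fluid)
  req <- c("axis", "position_um", "velocity_um_s")
  if (!is.data.frame(samples) || !all(req %in% names(samples)))
    stop("`samples` must be a data frame with columns ",
         paste(req, collapse = ", "))
  use <- samples$axis == "H" | (include_vertical & samples$axis == "V")
  if (!any(use))
    stop("no usable samples: all samples are on the vertical axis and ",
         "`include_vertical` is FALSE")
  if (sum(use) < 3L)
    stop("need at least 3 usable samples to fit the flow rate")
  v <- samples$velocity_um_s[use]
  if (all(v == 0)) stop("degenerate profile: all usable velocities are zero")
  pos <- samples$position_um[use]
  ax <- samples$axis[use]
  unit_flow <- flow_condition(q_um3_s = 1)
  g <- numeric(length(pos))
  if (any(ax == "H"))
    g[ax == "H"] <- velocity_field(geom, fluid, unit_flow,
                                   y = pos[ax == "H"], z = geom$height / 2,
                                   n_max = n_max)
  if (any(ax == "V"))
    g[ax == "V"] <- velocity_field(geom, fluid, unit_flow,
                                   y = geom$width / 2, z = pos[ax == "V"],
                                   n_max = n_max)
  q_hat <- sum(g * v) / sum(g^2)
  structure(
    list(q_um3_s = q_hat,
         q_ul_min = um3_s_to_ul_min(q_hat),
         residual_norm = sqrt(sum((v - q_hat * g)^2)),
         samples_used = which(use),
         n_used = sum(use),
         n_max = n_max),
    class = "flow_fit"
  )
}

#' @export
print.flow_fit <- function(x, ...) {
  cat("Flow-rate fit to velocity profile\n")
  cat(sprintf("  Q = %.4g uL/min (%.4g um^3/s)\n", x$q_ul_min, x$q_um3_s))
  cat(sprintf("  samples used: %d, residual norm: %.3g um/s\n",
              x$n_used, x$residual_norm))
  invisible(x)
}

#' Read a velocity-profile table
#'
#' Comma-separated, header mandatory, columns `axis` (H/V), `position_um`,
#' `velocity_um_s` and optionally `z_plane_um`.
#'
#' @param path Path to the CSV file.
#' @return A data frame.
#' @export
read_velocity_profiles <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("axis", "position_um", "velocity_um_s")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("velocity-profile table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(d$axis %in% c("H", "V")))
    stop("`axis` must be 'H' or 'V'")
  d
}
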