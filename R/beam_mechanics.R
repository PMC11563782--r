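# Euler-Bernoulli mechanics of a hypha clamped at the channel side wall:
# forward prediction of tip deflection under the distributed hydrodynamic
# load plus the hemispherical-tip point force, and inverse least-squares
# estimation of the bending stiffness k_b from deflections measured across
# flow rates.
#
# Conventions (in-plane, top view): the hypha axis makes the angle alpha0
# with the spanwise axis y before flow is applied; under flow the base-tip
# chord makes the angle alpha1. The beam equation addresses the deflection
# perpendicular to the hypha axis, so the displacement measured along the
# flow (x) direction equals w_max * cos(alpha0). The load acting
# perpendicular to the deflected hypha is diminished globally by cos(alpha1)
# (f* = cos(alpha1) * f).

#' Geometry of a single hypha
#'
#' @param length Exposed length L in um (arc length from the clamped base to
#'   the tip; must exceed the radius).
#' @param radius Outer radius r in um (defaults to 1.4, the average measured
#'   by transmission electron microscopy for the studied strain).
#' @param wall_thickness Cell-wall thickness t in um (default 0.287, same
#'   source); only used downstream by [youngs_modulus()].
#' @param base_offset Distance y0 of the clamped base from the side wall in
#'   um (default 0: the hypha emerges at the growth-channel exit in the
#'   side wall).
#' @param tilt Initial in-plane angle alpha0 between the hypha axis and the
#'   spanwise axis, in radians (|alpha0| < pi/2).
#' @param z_offset Vertical offset from the channel mid-plane in um.
#' @return An object of class `hypha_geometry`.
#' @export
#' @examples
#' hypha_geometry(length = 100)
hypha_geometry <- function(length, radius = 1.4, wall_thickness = 0.287,
                           base_offset = 0, tilt = 0, z_offset = 0) {
  if (!is.numeric(radius) || radius <= 0) stop("`radius` must be positive")
  if (!is.numeric(wall_thickness) || wall_thickness <= 0 ||
      wall_thickness > radius)
    stop("`wall_thickness` must satisfy 0 < t <= r")
  if (!is.numeric(length) || length <= radius)
    stop("`length` must exceed the radius")
  if (!is.numeric(tilt) || abs(tilt) >= pi / 2)
    stop("`tilt` must satisfy |alpha0| < pi/2")
  if (!is.numeric(base_offset) || base_offset < 0)
    stop("`base_offset` must be >= 0")
  structure(
    list(length = length, radius = radius, wall_thickness = wall_thickness,
         base_offset = base_offset, tilt = tilt, z_offset = z_offset),
    class = "hypha_geometry"
  )
}

#' Deflection measurements for one hypha
#'
#' One record per applied flow rate: the tip displacement observed along the
#' flow (x) direction and the equilibrium chord angle alpha1 read from the
#' deflected image.
#'
#' @param q_ul_min Applied flow rates in uL/min (>= 0).
#' @param x_disp_um Measured tip displacements along x in um.
#' @param alpha1 Deflected chord angles in radians (|alpha1| < pi/2);
#'   defaults to 0.
#' @param exclude Logical user-exclusion flags (default all `FALSE`).
#' @return A data frame with one row per measurement.
#' @export
deflection_measurements <- function(q_ul_min, x_disp_um, alpha1 = 0,
                                    exclude = FALSE) {
  n <- length(q_ul_min)
  alpha1 <- rep_len(alpha1, n); exclude <- rep_len(exclude, n)
  if (any(q_ul_min < 0)) stop("flow rates must be >= 0")
  if (any(abs(alpha1) >= pi / 2)) stop("|alpha1| must be < pi/2")
  data.frame(q_ul_min = q_ul_min, x_disp_um = x_disp_um,
             alpha1 = alpha1, exclude = as.logical(exclude))
}

# cumulative trapezoid integral, from the first grid point
cum_int <- function(x, y) as.vector(pracma::cumtrapz(x, y))

#' Cantilever deflection under the distributed load
#'
#' Solves `d^4 w / dy'^4 = cos(alpha1) f(y') / k_b` with a clamped base
#' (w = w' = 0 at y' = 0) and a free end (w'' = w''' = 0 at y' = L) by
#' quadruple cumulative quadrature on a uniform grid, where y' is the arc
#' coordinate along the hypha and f is the distributed load evaluated at
#' the channel coordinate of each arc point.
#'
#' @param load A [distributed_load()].
#' @param k_b Bending stiffness in uN um^2 (> 0).
#' @param hypha A [hypha_geometry()].
#' @param alpha1 Deflected chord angle in radians (global load-diminution
#'   factor cos(alpha1); default 0).
#' @param n_grid Number of grid points (default 2001).
#' @return List with the grid `y_prime`, the deflection curve `w` (um) and
#'   the tip value `w_f_max`.
#' @export
deflection_distributed <- function(load, k_b, hypha, alpha1 = 0,
                                   n_grid = 2001) {
  if (!inherits(load, "distributed_load"))
    stop("`load` must be a distributed_load")
  if (!inherits(hypha, "hypha_geometry"))
    stop("`hypha` must be a hypha_geometry")
  if (!is.numeric(k_b) || k_b <= 0) stop("`k_b` must be positive")
  L <- hypha$length
  s <- seq(0, L, length.out = n_grid)
  q <- cos(alpha1) * load$f(arc_to_channel(s, hypha$base_offset, hypha$tilt)) / k_b
  cq <- cum_int(s, q)                 # integral of q from 0 to y
  g <- cq[n_grid] - cq                # integral of q from y to L = -w'''
  e <- cum_int(s, g)
  wpp <- e[n_grid] - e                # w'' = integral_y^L (-w''') dt
  wp <- cum_int(s, wpp)
  w <- cum_int(s, wp)
  list(y_prime = s, w = w, w_f_max = w[n_grid])
}

#' Total tip deflection: distributed load plus tip point force
#'
#' Superposition of the distributed-load solution and the cantilever
#' point-load closed form:
#' `w_max = w_f_max + F_tip L^3 / (3 k_b)`, where the tip force is computed
#' from the diminished load f* = cos(alpha1) f (see [tip_force()]).
#'
#' @inheritParams deflection_distributed
#' @param include_tip_force Set `FALSE` to omit the hemispherical-tip point
#'   force (diagnostic use).
#' @return List with `w_max`, `w_f_max`, `w_F_max` and `F_tip` (uN).
#' @export
tip_deflection_total <- function(load, k_b, hypha, alpha1 = 0,
                                 include_tip_force = TRUE, n_grid = 2001) {
  wf <- deflection_distributed(load, k_b, hypha, alpha1, n_grid)$w_f_max
  ft <- if (include_tip_force) {
    cos(alpha1) * tip_force(load, hypha$length, hypha$radius,
                            hypha$base_offset, hypha$tilt)
  } else 0
  wF <- ft * hypha$length^3 / (3 * k_b)
  list(w_max = wf + wF, w_f_max = wf, w_F_max = wF, F_tip = ft)
}

#' Unit tip-deflection response of a hypha
#'
#' Tip deflection per unit flow rate and unit bending stiffness at zero
#' chord angle. Because the load is linear in Q, the deflection is linear in
#' 1/k_b and the angle enters only as a global factor, the predicted total
#' tip deflection of any measurement is
#' `w_max = (A / k_b) * Q * cos(alpha1)` with A this response.
#'
#' @param hypha A [hypha_geometry()].
#' @param geom A [channel_geometry()].
#' @param fluid A [fluid()].
#' @param n_max Odd truncation order of the drag series (default 11).
#' @param include_tip_force Include the hemispherical-tip point force.
#' @param n_grid Beam quadrature grid size.
#' @return Response A in um per (um^3/s) per (uN um^2)^-1.
#' @export
unit_response <- function(hypha, geom, fluid, n_max = 11,
                          include_tip_force = TRUE, n_grid = 2001) {
  load <- distributed_load(geom, fluid, flow_condition(q_um3_s = 1),
                           hypha$radius, n_max)
  tip_deflection_total(load, k_b = 1, hypha, alpha1 = 0,
                       include_tip_force = include_tip_force,
                       n_grid = n_grid)$w_max
}

#' Forward model: predicted measured displacement and chord angle
#'
#' Self-consistent forward solve of the full measurement model. The chord
#' angle alpha1 depends on the deflected tip position while the effective
#' load depends on cos(alpha1); the fixed point is found by iteration
#' starting from alpha1 = alpha0. The returned displacement is the
#' x-component of the tip motion, `w_max * cos(alpha0)`, i.e. what the
#' microscope image shows.
#'
#' @inheritParams unit_response
#' @param flow A [flow_condition()].
#' @param k_b True bending stiffness in uN um^2.
#' @param tol Convergence tolerance on alpha1 in radians.
#' @param max_iter Iteration cap; non-convergence signals deflections far
#'   outside small-angle validity and raises an error.
#' @return List with `x_disp` (um), `alpha1` (rad), `w_max` (um),
#'   `iterations`.
#' @export
forward_model <- function(hypha, geom, fluid, flow, k_b, n_max = 11,
                          n_grid = 2001, tol = 1e-8, max_iter = 50) {
  if (!is.numeric(k_b) || k_b <= 0) stop("`k_b` must be positive")
  A <- unit_response(hypha, geom, fluid, n_max, n_grid = n_grid)
  forward_from_response(A, hypha, flow, k_b, tol, max_iter)
}

# fixed-point iteration given a precomputed unit response (shared by
# forward_model and the synthetic generator, which caches A per hypha)
forward_from_response <- function(A, hypha, flow, k_b, tol = 1e-8,
                                  max_iter = 50) {
  a0 <- hypha$tilt; L <- hypha$length
  alpha1 <- a0
  w <- 0
  for (it in seq_len(max_iter)) {
    w <- flow$q * A * cos(alpha1) / k_b
    new_a1 <- atan2(L * sin(a0) + w * cos(a0), L * cos(a0) - w * sin(a0))
    if (abs(new_a1 - alpha1) < tol) {
      alpha1 <- new_a1
      return(list(x_disp = w * cos(a0), alpha1 = alpha1, w_max = w,
                  iterations = it))
    }
    alpha1 <- new_a1
  }
  stop("forward model did not converge: deflection outside small-angle validity")
}

#' Partition measurements by the validity criteria
#'
#' Two criteria guard the small-deflection beam inversion: (i) only
#' measurements with a relative tip deflection `w_max / L <= 0.25`
#' (boundary inclusive) are kept, where w_max is the vertical tip deflection
#' recovered as `|x_disp| / cos(alpha0)`; (ii) in the center configuration a
#' hypha growing more than `center_plane_tol` away from the channel
#' mid-plane is flagged invalid as a whole, because the load model assumes
#' mid-plane flow.
#'
#' @param measurements Data frame from [deflection_measurements()].
#' @param hypha A [hypha_geometry()].
#' @param configuration `"center"` or `"floor"`; the mid-plane criterion
#'   applies only to the center configuration.
#' @param max_rel_deflection Relative-deflection bound (default 0.25).
#' @param center_plane_tol Mid-plane proximity tolerance in um (default 10).
#' @return List with `kept` and `excluded` (data frames, the latter with a
#'   `reason` column), `hypha_valid` and `hypha_reason`.
#' @export
validity_filter <- function(measurements, hypha,
                            configuration = c("center", "floor"),
                            max_rel_deflection = 0.25,
                            center_plane_tol = 10) {
  configuration <- match.arg(configuration)
  if (!inherits(hypha, "hypha_geometry"))
    stop("`hypha` must be a hypha_geometry")
  w_obs <- abs(measurements$x_disp_um) / cos(hypha$tilt)
  ok <- w_obs / hypha$length <= max_rel_deflection
  excluded <- measurements[!ok, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "validity filter: w_max/L > 0.25"
  else excluded$reason <- character(0)
  hypha_valid <- !(configuration == "center" &&
                     abs(hypha$z_offset) > center_plane_tol)
  list(kept = measurements[ok, , drop = FALSE],
       excluded = excluded,
       hypha_valid = hypha_valid,
       hypha_reason = if (hypha_valid) NA_character_ else
         sprintf("hypha more than %g um from the center plane (|dz| = %g um)",
                 center_plane_tol, abs(hypha$z_offset)))
}

#' Estimate the bending stiffness from measured deflections
#'
#' Converts each measured x-displacement to the vertical tip deflection via
#' `1/cos(alpha0)`, applies [validity_filter()], and fits
#' `w_max = (A / k_b) * Q * cos(alpha1)` by least squares through the
#' origin, where A is the Q-normalised response of [unit_response()] and
#' alpha1 is taken from each measurement record as observed (not
#' recomputed). A zero-flow measurement carries no leverage in the
#' through-origin fit; an optional intercept can be added to diagnose
#' adhesion artifacts at low flow.
#'
#' @param measurements Data frame from [deflection_measurements()] (columns
#'   `q_ul_min`, `x_disp_um`, `alpha1`, optional `exclude`).
#' @param hypha A [hypha_geometry()].
#' @param geom A [channel_geometry()].
#' @param fluid A [fluid()].
#' @param n_max Odd truncation order of the drag series.
#' @param intercept Add an intercept term (default `FALSE`: zero flow
#'   implies zero deflection).
#' @param include_tip_force Include the tip point force in the response
#'   (default `TRUE`; `FALSE` quantifies the omission bias).
#' @param max_rel_deflection,center_plane_tol Passed to [validity_filter()].
#' @param n_grid Beam quadrature grid size.
#' @return An object of class `bending_fit`: `k_b` (uN um^2), `se`,
#'   `intercept`, `n_used`, `used`, `excluded` (with reasons), `predicted`,
#'   `residuals`, `response_A`.
#' @export
fit_bending_stiffness <- function(measurements, hypha, geom, fluid,
                                  n_max = 11, intercept = FALSE,
                                  include_tip_force = TRUE,
                                  max_rel_deflection = 0.25,
                                  center_plane_tol = 10, n_grid = 2001) {
  if (!inherits(hypha, "hypha_geometry"))
    stop("`hypha` must be a hypha_geometry")
  check_geom_fluid(geom, fluid)
  m <- measurements
  if (is.null(m$exclude)) m$exclude <- FALSE
  if (is.null(m$alpha1)) m$alpha1 <- 0

  vf <- validity_filter(m, hypha, geom$configuration,
                        max_rel_deflection, center_plane_tol)
  if (!vf$hypha_valid) stop("hypha invalid: ", vf$hypha_reason)

  excluded <- vf$excluded
  user_out <- vf$kept[vf$kept$exclude, , drop = FALSE]
  if (nrow(user_out)) {
    user_out$reason <- "user flag"
    excluded <- rbind(excluded, user_out)
  }
  used <- vf$kept[!vf$kept$exclude, , drop = FALSE]

  n_pos <- sum(used$q_ul_min > 0)
  if (n_pos < 2) {
    if (nrow(m[m$q_ul_min > 0, ]) >= 2 && nrow(vf$kept[vf$kept$q_ul_min > 0, ]) < 2)
      stop("all measurements with Q > 0 were removed by the relative-deflection ",
           "validity filter (w_max/L > ", max_rel_deflection, ")")
    stop("need at least 2 usable measurements with Q > 0; excluded: ",
         if (nrow(excluded)) paste(unique(excluded$reason), collapse = "; ")
         else "none")
  }

  signs <- sign(used$x_disp_um[used$x_disp_um != 0 & used$q_ul_min > 0])
  if (length(unique(signs)) > 1)
    warning("mixed displacement signs; fitting absolute values")

  A <- unit_response(hypha, geom, fluid, n_max,
                     include_tip_force = include_tip_force, n_grid = n_grid)
  w_obs <- abs(used$x_disp_um) / cos(hypha$tilt)
  cc <- A * ul_min_to_um3_s(used$q_ul_min) * cos(used$alpha1)

  fit <- if (intercept) stats::lm(w_obs ~ cc) else stats::lm(w_obs ~ 0 + cc)
  beta <- stats::coef(fit)[["cc"]]
  if (!is.finite(beta) || beta <= 0)
    stop("non-positive fitted slope; measurements inconsistent with the model")
  se_beta <- summary(fit)$coefficients["cc", "Std. Error"]
  k_b <- 1 / beta
  structure(
    list(k_b = k_b,
         se = se_beta / beta^2,           # delta method on k_b = 1/beta
         intercept = if (intercept) stats::coef(fit)[["(Intercept)"]] else NULL,
         n_used = nrow(used),
         used = used,
         excluded = excluded,
         predicted = as.numeric(stats::fitted(fit)),
         residuals = as.numeric(stats::residuals(fit)),
         response_A = A,
         include_tip_force = include_tip_force),
    class = "bending_fit"
  )
}

#' @export
print.bending_fit <- function(x, ...) {
  cat("Bending-stiffness fit\n")
  cat(sprintf("  k_b = %.3f +/- %.3f uN um^2 (%d measurements used, %d excluded)\n",
              x$k_b, x$se, x$n_used, nrow(x$excluded)))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.3g um\n", x$intercept))
  invisible(x)
}

#' Bias from omitting the hemispherical-tip force
#'
#' Generates noiseless deflections with the full forward model, then
#' re-estimates the bending stiffness with the tip point force left out of
#' the response. The result is the percent underestimation of k_b, which is
#' largest for short hyphae (the tip segment is a larger fraction of the
#' beam).
#'
#' @inheritParams unit_response
#' @param q_ul_min Flow-rate schedule for the synthetic measurements.
#' @param k_b True bending stiffness used in the forward model.
#' @return Percent underestimation of k_b (positive = underestimate).
#' @export
tip_force_bias <- function(hypha, geom, fluid, q_ul_min = c(2, 5, 10),
                           k_b = 18.3, n_max = 11) {
  A <- unit_response(hypha, geom, fluid, n_max)
  rows <- lapply(q_ul_min, function(q) {
    fm <- forward_from_response(A, hypha, flow_condition(q_ul_min = q), k_b)
    data.frame(q_ul_min = q, x_disp_um = fm$x_disp, alpha1 = fm$alpha1)
  })
  m <- do.call(rbind, rows)
  fit <- fit_bending_stiffness(m, hypha, geom, fluid, n_max = n_max,
                               include_tip_force = FALSE)
  100 * (k_b - fit$k_b) / k_b
}

#' Relative force error for a hypha off the channel mid-plane
#'
#' In the center configuration the drag scales with the local velocity; a
#' hypha a distance dz from the mid-plane sees a slightly lower velocity
#' than assumed. Returns the relative reduction
#' `1 - u(w/2, h/2 + dz) / u(w/2, h/2)`.
#'
#' @param geom A [channel_geometry()].
#' @param fluid A [fluid()].
#' @param dz Vertical offset from the mid-plane in um.
#' @param n_max Odd series truncation order.
#' @return Relative force deviation (dimensionless, >= 0 for |dz| > 0).
#' @export
center_plane_force_deviation <- function(geom, fluid, dz, n_max = 51) {
  fl <- flow_condition(q_um3_s = 1)
  u0 <- velocity_field(geom, fluid, fl, geom$width / 2, geom$height / 2, n_max)
  u1 <- velocity_field(geom, fluid, fl, geom$width / 2,
                       geom$height / 2 + dz, n_max)
  1 - u1 / u0
}

#' Read a deflection-measurement table
#'
#' Comma-separated, header mandatory, columns `hypha_id`, `Q_uL_min`,
#' `x_disp_um`, `alpha0_deg`, `alpha1_deg` and optionally `exclude` (0/1).
#' Angles are converted to radians on read.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `hypha_id`, `q_ul_min`, `x_disp_um`,
#'   `alpha0`, `alpha1` (radians), `exclude` (logical).
#' @export
read_measurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("hypha_id", "Q_uL_min", "x_disp_um", "alpha0_deg", "alpha1_deg")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("measurement table is missing column(s): ",
         paste(miss, collapse = ", "))
  out <- data.frame(hypha_id = d$hypha_id,
                    q_ul_min = d$Q_uL_min,
                    x_disp_um = d$x_disp_um,
                    alpha0 = deg2rad(d$alpha0_deg),
                    alpha1 = deg2rad(d$alpha1_deg),
                    exclude = if (!is.null(d$exclude)) d$exclude != 0 else FALSE)
  out
}
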