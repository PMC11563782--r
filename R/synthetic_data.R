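# Seeded synthetic-data generator standing in for the wet-lab experiment.
# It draws virtual hypha populations, pushes them through the full forward
# model (distributed load + tip force + angle conventions) to produce
# deflection-measurement tables with Gaussian measurement noise, and
# renders velocity profiles as a particle-image-velocimetry setup would see
# them, including the depth-of-field artifact in the vertical profile.
# Every stage takes its own seed so any one of them can be regenerated
# independently.

#' Configuration of a synthetic bending experiment
#'
#' Defaults emulate the experimental envelope of the studied system:
#' exposed lengths uniform over 30-150 um (measurements start once 30 um of
#' hypha are exposed), radius normal around 1.4 um, true bending stiffness
#' log-normal around 18.3 uN um^2 with a coefficient of variation matching
#' the observed 8.7/18.3 spread, flow rates within the 0-50 uL/min pump
#' range. Chamber width 500 um and height 90 um (center configuration; 45
#' in floor configuration) are plausible scales, not reported device
#' dimensions, and are deliberately configuration-exposed.
#'
#' @param configuration `"center"` or `"floor"`.
#' @param width,height Chamber cross-section in um; `height = NULL` picks
#'   90 (center) or 45 (floor).
#' @param viscosity Fluid viscosity in uN s um^-2.
#' @param n_hyphae Number of virtual hyphae.
#' @param length_range Range of exposed lengths in um (uniform draw).
#' @param radius_mean,radius_sd Normal parameters for the radius in um.
#' @param wall_thickness Cell-wall thickness in um.
#' @param tilt_sd Standard deviation of the initial in-plane angle alpha0,
#'   radians.
#' @param z_offset_sd Standard deviation of the vertical offset from the
#'   mid-plane in um (clamped to +/- h/2).
#' @param kb_mean,kb_cv Log-normal mean and coefficient of variation of the
#'   true bending stiffness in uN um^2.
#' @param kb_trend_slope Optional linear dependence of k_b on L in
#'   uN um^2 per um (0 disables the trend and uses the log-normal draw).
#' @param kb_trend_intercept Intercept of the trend in uN um^2; `NULL`
#'   centres the trend on `kb_mean` at the mid-range length.
#' @param kb_trend_sd Gaussian scatter around the trend line in uN um^2.
#' @param flow_rates_ul_min Flow-rate schedule applied to every hypha; a
#'   zero-flow anchor row is always included.
#' @param noise_sd_um Gaussian noise on the measured tip displacement, um.
#' @param seed Master seed.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(configuration = c("center", "floor"),
                             width = 500, height = NULL,
                             viscosity = water_viscosity(),
                             n_hyphae = 25,
                             length_range = c(30, 150),
                             radius_mean = 1.4, radius_sd = 0.1,
                             wall_thickness = 0.287,
                             tilt_sd = deg2rad(5),
                             z_offset_sd = 3,
                             kb_mean = 18.3, kb_cv = 8.7 / 18.3,
                             kb_trend_slope = 0,
                             kb_trend_intercept = NULL,
                             kb_trend_sd = 1,
                             flow_rates_ul_min = c(0, 2, 5, 10, 15, 20, 25),
                             noise_sd_um = 0.2,
                             seed = 1L) {
  configuration <- match.arg(configuration)
  if (is.null(height)) height <- if (configuration == "center") 90 else 45
  if (n_hyphae < 0) stop("`n_hyphae` must be >= 0")
  if (length(length_range) != 2L || any(length_range <= 0) ||
      diff(length_range) < 0)
    stop("`length_range` must be an increasing positive pair")
  for (p in c(radius_mean, radius_sd, kb_mean, kb_cv, kb_trend_sd))
    if (!is.numeric(p) || p <= 0) stop("scale parameters must be positive")
  if (tilt_sd < 0 || z_offset_sd < 0 || noise_sd_um < 0)
    stop("spread parameters must be >= 0")
  if (any(flow_rates_ul_min < 0)) stop("flow rates must be >= 0")
  structure(
    list(configuration = configuration, width = width, height = height,
         viscosity = viscosity, n_hyphae = as.integer(n_hyphae),
         length_range = length_range, radius_mean = radius_mean,
         radius_sd = radius_sd, wall_thickness = wall_thickness,
         tilt_sd = tilt_sd, z_offset_sd = z_offset_sd,
         kb_mean = kb_mean, kb_cv = kb_cv,
         kb_trend_slope = kb_trend_slope,
         kb_trend_intercept = kb_trend_intercept,
         kb_trend_sd = kb_trend_sd,
         flow_rates_ul_min = sort(unique(c(0, flow_rates_ul_min))),
         noise_sd_um = noise_sd_um, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

config_geom <- function(config)
  channel_geometry(config$width, config$height, config$configuration)
config_fluid <- function(config) fluid(config$viscosity)

#' Draw a virtual hypha population
#'
#' Reproducible draws of per-hypha geometry and true bending stiffness.
#' Radii are redrawn until positive and below the exposed length; vertical
#' offsets are clamped to the half-height. With a non-zero trend slope the
#' true stiffness follows `k_b = a + b L + noise` (kept positive),
#' otherwise the log-normal law of the configuration.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed for this stage (default: the master seed).
#' @return Data frame with columns `hypha_id`, `L_um`, `r_um`,
#'   `alpha0_rad`, `z_offset_um`, `kb_true`; the configuration is attached
#'   as attribute `"config"`.
#' @export
generate_hypha_population <- function(config, seed = config$seed) {
  if (!inherits(config, "synthetic_config"))
    stop("`config` must be a synthetic_config")
  n <- config$n_hyphae
  pop <- withr::with_seed(seed, {
    L <- stats::runif(n, config$length_range[1], config$length_range[2])
    r <- stats::rnorm(n, config$radius_mean, config$radius_sd)
    for (k in seq_len(50)) {
      bad <- r <= 0 | r >= L
      if (!any(bad)) break
      r[bad] <- stats::rnorm(sum(bad), config$radius_mean, config$radius_sd)
    }
    a0 <- stats::rnorm(n, 0, config$tilt_sd)
    a0 <- pmin(pmax(a0, -pi / 2 + 1e-6), pi / 2 - 1e-6)
    dz <- stats::rnorm(n, 0, config$z_offset_sd)
    dz <- pmin(pmax(dz, -config$height / 2), config$height / 2)
    kb <- if (config$kb_trend_slope != 0) {
      a <- config$kb_trend_intercept
      if (is.null(a))
        a <- config$kb_mean - config$kb_trend_slope * mean(config$length_range)
      pmax(a + config$kb_trend_slope * L +
             stats::rnorm(n, 0, config$kb_trend_sd), 0.1)
    } else {
      sdlog <- sqrt(log(1 + config$kb_cv^2))
      stats::rlnorm(n, log(config$kb_mean) - sdlog^2 / 2, sdlog)
    }
    data.frame(hypha_id = sprintf("H%03d", seq_len(n)),
               L_um = L, r_um = r, alpha0_rad = a0, z_offset_um = dz,
               kb_true = kb)
  })
  attr(pop, "config") <- config
  pop
}

#' Simulate a bending experiment on a virtual population
#'
#' For each hypha and each scheduled flow rate, the self-consistent forward
#' model produces the noiseless x-displacement and chord angle alpha1; the
#' recorded displacement then receives Gaussian measurement noise. The
#' recorded alpha1 is the noiseless forward value, mirroring how the angle
#' is read from the image rather than recomputed. Rows whose forward solve
#' does not converge are flagged, not dropped.
#'
#' @param population From [generate_hypha_population()].
#' @param config The same [synthetic_config()] used for the population.
#' @param seed Seed for the measurement-noise stage.
#' @return Data frame with columns `hypha_id`, `q_ul_min`, `x_disp_um`
#'   (noisy), `x_disp_true_um`, `alpha0`, `alpha1` (radians), `exclude`,
#'   `flag`.
#' @export
simulate_bending_experiment <- function(population, config,
                                        seed = config$seed + 1L) {
  if (!inherits(config, "synthetic_config"))
    stop("`config` must be a synthetic_config")
  pc <- attr(population, "config")
  if (is.null(pc) ||
      !identical(pc[c("configuration", "width", "height", "viscosity")],
                 config[c("configuration", "width", "height", "viscosity")]))
    stop("population/config mismatch: the population was generated under a ",
         "different experimental configuration")
  geom <- config_geom(config); fl <- config_fluid(config)
  rows <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    hy <- hypha_geometry(length = population$L_um[i],
                         radius = population$r_um[i],
                         wall_thickness = config$wall_thickness,
                         tilt = population$alpha0_rad[i],
                         z_offset = population$z_offset_um[i])
    A <- unit_response(hy, geom, fl)
    per_q <- lapply(config$flow_rates_ul_min, function(q) {
      fm <- tryCatch(
        forward_from_response(A, hy, flow_condition(q_ul_min = q),
                              population$kb_true[i]),
        error = function(e) NULL)
      if (is.null(fm))
        data.frame(hypha_id = population$hypha_id[i], q_ul_min = q,
                   x_disp_true_um = NA_real_, alpha0 = hy$tilt,
                   alpha1 = NA_real_, flag = "no convergence")
      else
        data.frame(hypha_id = population$hypha_id[i], q_ul_min = q,
                   x_disp_true_um = fm$x_disp, alpha0 = hy$tilt,
                   alpha1 = fm$alpha1, flag = "")
    })
    rows[[i]] <- do.call(rbind, per_q)
  }
  out <- do.call(rbind, rows)
  out$x_disp_um <- withr::with_seed(seed, {
    out$x_disp_true_um + stats::rnorm(nrow(out), 0, config$noise_sd_um)
  })
  out$x_disp_um[is.na(out$x_disp_true_um)] <- NA_real_
  out$exclude <- out$flag != ""
  out[, c("hypha_id", "q_ul_min", "x_disp_um", "x_disp_true_um",
          "alpha0", "alpha1", "exclude", "flag")]
}

#' Simulate micro-PIV-like velocity profiles
#'
#' The horizontal profile (spanwise, at mid-height) follows the exact
#' series solution; the vertical profile (at mid-width) can optionally
#' carry the depth-of-field artifact: out-of-focus particles keep the
#' apparent near-wall velocity from falling below about 30% of the maximum,
#' modelled as a hard floor `max(u_true, 0.30 u_max)`. Noise is
#' multiplicative Gaussian, applied after the floor.
#'
#' @param geom A [channel_geometry()].
#' @param fluid A [fluid()].
#' @param flow A [flow_condition()].
#' @param artifact Apply the 30% depth-of-field floor to the vertical
#'   profile (default `TRUE`).
#' @param noise_rel Relative (multiplicative) noise standard deviation
#'   (default 0).
#' @param seed Seed for the noise stage.
#' @param n_points Samples per profile (default 41).
#' @param artifact_floor Artifact level as a fraction of the maximum
#'   velocity (default 0.30).
#' @return Data frame in the dialect of [read_velocity_profiles()]:
#'   `axis` (H/V), `position_um`, `velocity_um_s`, `z_plane_um`.
#' @export
simulate_velocity_profiles <- function(geom, fluid, flow, artifact = TRUE,
                                       noise_rel = 0, seed = 1L,
                                       n_points = 41,
                                       artifact_floor = 0.30) {
  check_geom_fluid(geom, fluid)
  w <- geom$width; h <- geom$height
  y <- seq(0, w, length.out = n_points)
  z <- seq(0, h, length.out = n_points)
  u_h <- velocity_field(geom, fluid, flow, y = y, z = h / 2)
  u_v <- velocity_field(geom, fluid, flow, y = w / 2, z = z)
  u_max <- velocity_field(geom, fluid, flow, y = w / 2, z = h / 2)
  if (artifact) u_v <- pmax(u_v, artifact_floor * u_max)
  d <- data.frame(
    axis = rep(c("H", "V"), each = n_points),
    position_um = c(y, z),
    velocity_um_s = c(u_h, u_v),
    z_plane_um = c(rep(h / 2, n_points), rep(NA_real_, n_points))
  )
  if (noise_rel > 0)
    d$velocity_um_s <- withr::with_seed(seed, {
      d$velocity_um_s * (1 + stats::rnorm(nrow(d), 0, noise_rel))
    })
  d
}
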