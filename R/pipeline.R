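# Orchestration: write/read the tabular dialects, run the per-hypha fits,
# assemble the end-of-run study report (population statistics plus the
# ordinary-least-squares regression of bending stiffness on exposed
# length), and the design calculator for the loading circuit.

#' Generate and write a complete synthetic data set
#'
#' Draws a population, simulates the bending experiment and the velocity
#' profiles, and writes four comma-separated tables to `out_dir`:
#' `hyphae.csv` (per-hypha geometry), `measurements.csv` (the
#' deflection-measurement dialect read by [read_measurements()]),
#' `profiles.csv` (the velocity-profile dialect) and `truth.csv`
#' (`hypha_id`, `true_kb`) for recovery scoring. Deterministic given the
#' seed: population, measurement-noise and profile-noise stages use
#' `seed`, `seed + 1`, `seed + 2`.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (default from the configuration).
#' @param flow_q_ul_min Flow rate for the simulated velocity profiles
#'   (default 10).
#' @return Invisibly, a named list of the file paths.
#' @export
run_simulate <- function(config, out_dir, seed = config$seed,
                         flow_q_ul_min = 10) {
  if (!inherits(config, "synthetic_config"))
    stop("`config` must be a synthetic_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- generate_hypha_population(config, seed)
  meas <- if (nrow(pop)) simulate_bending_experiment(pop, config, seed + 1L)
  else data.frame(hypha_id = character(0), q_ul_min = numeric(0),
                  x_disp_um = numeric(0), x_disp_true_um = numeric(0),
                  alpha0 = numeric(0), alpha1 = numeric(0),
                  exclude = logical(0), flag = character(0))
  prof <- simulate_velocity_profiles(config_geom(config),
                                     config_fluid(config),
                                     flow_condition(q_ul_min = flow_q_ul_min),
                                     artifact = TRUE, noise_rel = 0.02,
                                     seed = seed + 2L)
  paths <- list(hyphae = file.path(out_dir, "hyphae.csv"),
                measurements = file.path(out_dir, "measurements.csv"),
                profiles = file.path(out_dir, "profiles.csv"),
                truth = file.path(out_dir, "truth.csv"))
  utils::write.csv(data.frame(hypha_id = pop$hypha_id,
                              L_um = pop$L_um, r_um = pop$r_um,
                              alpha0_deg = rad2deg(pop$alpha0_rad),
                              z_offset_um = pop$z_offset_um),
                   paths$hyphae, row.names = FALSE)
  utils::write.csv(data.frame(hypha_id = meas$hypha_id,
                              Q_uL_min = meas$q_ul_min,
                              x_disp_um = meas$x_disp_um,
                              alpha0_deg = rad2deg(meas$alpha0),
                              alpha1_deg = rad2deg(meas$alpha1),
                              exclude = as.integer(meas$exclude),
                              flag = meas$flag),
                   paths$measurements, row.names = FALSE)
  utils::write.csv(prof, paths$profiles, row.names = FALSE)
  utils::write.csv(data.frame(hypha_id = pop$hypha_id,
                              true_kb = pop$kb_true),
                   paths$truth, row.names = FALSE)
  invisible(paths)
}

#' Fit every hypha in a measurement table and summarise the study
#'
#' Per hypha: inversion of the deflection measurements into a bending
#' stiffness ([fit_bending_stiffness()]) and conversion to the cell-wall
#' Young's modulus ([youngs_modulus()]). Population level: mean and
#' standard deviation of k_b and E, the modulus computed both from the mean
#' stiffness and as the mean of per-hypha moduli, and the
#' ordinary-least-squares regression of k_b on exposed length with its
#' two-sided slope p-value. Hyphae whose fit fails (too few usable points,
#' mid-plane violation, ...) are logged and skipped; the run only errors
#' when no hypha at all can be fitted.
#'
#' @param measurements Path to a measurement CSV (dialect of
#'   [read_measurements()]) or an equivalent data frame with radian angle
#'   columns `alpha0`, `alpha1`.
#' @param hyphae Path to a hypha-geometry CSV (`hypha_id`, `L_um`, `r_um`,
#'   `alpha0_deg`, `z_offset_um`) or an equivalent data frame with
#'   `alpha0_rad`.
#' @param geom A [channel_geometry()].
#' @param fluid A [fluid()].
#' @param wall_thickness Cell-wall thickness in um used for E (default
#'   0.287).
#' @param n_max,intercept,include_tip_force,max_rel_deflection,center_plane_tol
#'   Passed to [fit_bending_stiffness()].
#' @param seed Seed recorded in the provenance block (no randomness is used
#'   in fitting).
#' @return An object of class `study_report`.
#' @export
run_fit <- function(measurements, hyphae, geom, fluid,
                    wall_thickness = 0.287, n_max = 11, intercept = FALSE,
                    include_tip_force = TRUE, max_rel_deflection = 0.25,
                    center_plane_tol = 10, seed = NA_integer_) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.character(hyphae)) {
    h <- utils::read.csv(hyphae, stringsAsFactors = FALSE)
    req <- c("hypha_id", "L_um", "r_um", "alpha0_deg", "z_offset_um")
    miss <- setdiff(req, names(h))
    if (length(miss))
      stop("hypha table is missing column(s): ", paste(miss, collapse = ", "))
    h$alpha0_rad <- deg2rad(h$alpha0_deg)
    hyphae <- h
  }
  per <- list(); errors <- list()
  for (id in unique(hyphae$hypha_id)) {
    hrow <- hyphae[hyphae$hypha_id == id, , drop = FALSE][1, ]
    mrows <- measurements[measurements$hypha_id == id, , drop = FALSE]
    res <- tryCatch({
      hy <- hypha_geometry(length = hrow$L_um, radius = hrow$r_um,
                           wall_thickness = wall_thickness,
                           tilt = hrow$alpha0_rad,
                           z_offset = hrow$z_offset_um)
      fit <- fit_bending_stiffness(mrows, hy, geom, fluid, n_max = n_max,
                                   intercept = intercept,
                                   include_tip_force = include_tip_force,
                                   max_rel_deflection = max_rel_deflection,
                                   center_plane_tol = center_plane_tol)
      el <- youngs_modulus(fit$k_b, hrow$r_um, wall_thickness)
      data.frame(hypha_id = id, L_um = hrow$L_um, r_um = hrow$r_um,
                 k_b = fit$k_b, k_b_se = fit$se, E_MPa = el$E_MPa,
                 I_um4 = el$I_um4, n_used = fit$n_used,
                 n_excluded = nrow(fit$excluded))
    }, error = function(e) e)
    if (inherits(res, "error")) errors[[id]] <- conditionMessage(res)
    else per[[id]] <- res
  }
  if (!length(per))
    stop("no fittable hyphae; exclusions: ",
         paste(sprintf("%s: %s", names(errors), unlist(errors)),
               collapse = " | "))
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  regression <- NULL
  if (nrow(per) >= 3) {
    lmfit <- stats::lm(k_b ~ L_um, data = per)
    cf <- summary(lmfit)$coefficients
    regression <- list(slope = cf["L_um", "Estimate"],
                       intercept = cf["(Intercept)", "Estimate"],
                       p_value = cf["L_um", "Pr(>|t|)"],
                       r_squared = summary(lmfit)$r.squared,
                       n = nrow(per))
  }
  summary <- list(
    n_fitted = nrow(per), n_failed = length(errors),
    kb_mean = mean(per$k_b), kb_sd = stats::sd(per$k_b),
    E_mean_MPa = mean(per$E_MPa), E_sd_MPa = stats::sd(per$E_MPa),
    # two aggregation routes for the population modulus
    E_of_mean_kb_MPa = youngs_modulus(mean(per$k_b), mean(per$r_um),
                                      wall_thickness)$E_MPa,
    E_mean_of_per_hypha_MPa = mean(per$E_MPa)
  )
  structure(
    list(per_hypha = per, summary = summary, regression = regression,
         errors = errors,
         provenance = list(seed = seed, n_max = n_max,
                           intercept = intercept,
                           include_tip_force = include_tip_force,
                           max_rel_deflection = max_rel_deflection,
                           center_plane_tol = center_plane_tol,
                           package_version =
                             as.character(utils::packageVersion("hyphabend")))),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  s <- x$summary
  cat("Bending-test study report\n")
  cat(sprintf("  hyphae fitted: %d (failed: %d)\n", s$n_fitted, s$n_failed))
  cat(sprintf("  k_b = %.1f +/- %.1f uN um^2\n", s$kb_mean, s$kb_sd))
  cat(sprintf("  E (mean of per-hypha) = %.2f +/- %.2f MPa\n",
              s$E_mean_of_per_hypha_MPa, s$E_sd_MPa))
  cat(sprintf("  E (from mean k_b)     = %.2f MPa\n", s$E_of_mean_kb_MPa))
  if (!is.null(x$regression))
    cat(sprintf("  k_b ~ L: slope = %.4g uN um^2/um, p = %.3g (n = %d)\n",
                x$regression$slope, x$regression$p_value, x$regression$n))
  invisible(x)
}

#' Fit the flow rate from a velocity-profile table
#'
#' Thin wrapper: reads the profile dialect and runs [fit_flow_rate()] with
#' the horizontal-only default policy.
#'
#' @param profiles Path to a profile CSV or an equivalent data frame.
#' @param geom A [channel_geometry()].
#' @param fluid A [fluid()].
#' @param ... Passed to [fit_flow_rate()].
#' @return A `flow_fit` object.
#' @export
run_flow_fit <- function(profiles, geom, fluid, ...) {
  if (is.character(profiles)) profiles <- read_velocity_profiles(profiles)
  fit_flow_rate(profiles, geom, fluid, ...)
}

#' Loading-circuit design report
#'
#' Sizes the serpentine for the requested flow ratio, solves the circuit at
#' the start of loading and sweeps the number of blocked channels.
#'
#' @param design A [loading_design()].
#' @param fluid A [fluid()].
#' @param sweep_out Optional path; when given the sweep table is written
#'   there as CSV (`blocked`, `ratio`, `pressure_Pa`).
#' @return An object of class `design_report` with the resistances, the
#'   start-of-loading flow ratio and chamber pressure, and the sweep table.
#' @export
run_design <- function(design = loading_design(), fluid = hyphabend::fluid(),
                       sweep_out = NULL) {
  net <- build_network(design, fluid)
  res <- attr(net, "resistances")
  start <- loading_flow_ratio(design, fluid)
  sweep <- blocking_sweep(design, fluid)
  if (!is.null(sweep_out))
    utils::write.csv(sweep, sweep_out, row.names = FALSE)
  structure(
    list(resistances = res, ratio = start$ratio,
         chamber_pressure_Pa = start$chamber_pressure_Pa,
         sweep = sweep, design = design),
    class = "design_report"
  )
}

#' @export
print.design_report <- function(x, ...) {
  cat("Loading-circuit design report\n")
  cat(sprintf("  serpentine resistance: %.4g uN s um^-5 (%.3g x parallel growth)\n",
              x$resistances$serpentine,
              x$resistances$serpentine / x$resistances$parallel))
  cat(sprintf("  start-of-loading flow ratio (growth/serpentine): %.4g\n",
              x$ratio))
  cat(sprintf("  chamber pressure: %.4g Pa; all-blocked maximum: %.4g Pa\n",
              x$chamber_pressure_Pa, max(x$sweep$pressure_Pa)))
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [synthetic_config()]; unknown keys raise an
#' error so typos do not silently fall back to defaults.
#'
#' @param path Path to the YAML file.
#' @return A [synthetic_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the `yaml` package is required to read configuration files")
  vals <- yaml::read_yaml(path)
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(synthetic_config, vals)
}
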