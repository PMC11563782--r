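test_that("cantilever closed forms are reproduced by the quadrature", {
  hy <- hypha_geometry(length = 100, radius = 1.4)
  f0 <- 1e-5; kb <- 18.3; L <- hy$length; r <- hy$radius
  load <- make_load(function(y) rep(f0, length(y)))
  wd <- deflection_distributed(load, kb, hy)
  expect_lt(abs(wd$w_f_max / (f0 * L^4 / (8 * kb)) - 1), 1e-6)
  # superposition with the tip point force: f0 L^4/(8 kb) + f0 r L^3/(3 kb)
  tt <- tip_deflection_total(load, kb, hy)
  expect_lt(abs(tt$w_max /
                  (f0 * L^4 / (8 * kb) + f0 * r * L^3 / (3 * kb)) - 1), 1e-6)
  # pure point force: F L^3 / (3 kb) exactly
  zero_load <- make_load(function(y) rep(0, length(y)))
  F <- 5e-4
  wF <- deflection_distributed(zero_load, kb, hy)$w_f_max +
    F * L^3 / (3 * kb)
  expect_equal(wF, F * L^3 / (3 * kb))
})

test_that("deflection is linear in the load and inverse in the stiffness", {
  hy <- hypha_geometry(length = 80)
  load1 <- make_load(function(y) 1e-5 * (1 + y / 500))
  load2 <- make_load(function(y) 2e-5 * (1 + y / 500))
  w1 <- deflection_distributed(load1, 10, hy)
  w2 <- deflection_distributed(load2, 10, hy)
  expect_equal(w2$w, 2 * w1$w)
  w_half <- deflection_distributed(load1, 20, hy)
  expect_equal(w_half$w, w1$w / 2)
})

test_that("quadrature agrees with an independent finite-difference
           boundary-value solve for random load profiles", {
  set.seed(301)
  hy_pool <- replicate(20, list(
    L = runif(1, 40, 140),
    a = runif(1, 0.5e-5, 2e-5),
    b = runif(1, -5e-8, 5e-8),
    k = sample(1:3, 1),
    amp = runif(1, 0, 0.5)
  ), simplify = FALSE)
  for (p in hy_pool) {
    qfun <- function(y) p$a * (1 + p$b * y / p$a +
                                 p$amp * sin(p$k * pi * y / p$L)^2)
    hy <- hypha_geometry(length = p$L)
    load <- make_load(qfun)
    kb <- 15
    tip_pkg <- deflection_distributed(load, kb, hy)$w_f_max
    tip_fd <- fd_beam_tip(qfun, p$L, kb, N = 2000)
    expect_lt(abs(tip_pkg / tip_fd - 1), 1e-5)
  }
})

test_that("the real series load matches the boundary-value oracle", {
  g <- default_center_geom(); fl <- fluid(); q <- flow_condition(q_ul_min = 10)
  load <- distributed_load(g, fl, q, 1.4)
  hy <- hypha_geometry(length = 120)
  kb <- 18.3
  tip_pkg <- deflection_distributed(load, kb, hy)$w_f_max
  tip_fd <- fd_beam_tip(function(y) load$f(y), 120, kb, N = 2000)
  expect_lt(abs(tip_pkg / tip_fd - 1), 1e-5)
})

test_that("forward model behaves at zero flow, without tilt, and grows
           with the flow rate", {
  g <- default_center_geom(); fl <- fluid()
  hy <- hypha_geometry(length = 90, tilt = 0.15)
  fm0 <- forward_model(hy, g, fl, flow_condition(q_ul_min = 0), k_b = 18.3)
  expect_equal(fm0$x_disp, 0)
  expect_equal(fm0$alpha1, hy$tilt)
  # without tilt and at small flow the displacement equals the
  # angle-free superposition formula
  hy0 <- hypha_geometry(length = 90)
  q_small <- flow_condition(q_ul_min = 0.05)
  fm <- forward_model(hy0, g, fl, q_small, k_b = 18.3)
  load <- distributed_load(g, fl, q_small, hy0$radius)
  w_ref <- tip_deflection_total(load, 18.3, hy0, alpha1 = fm$alpha1)$w_max
  expect_lt(abs(fm$x_disp / w_ref - 1), 1e-6)
  # strictly increasing in Q
  disp <- sapply(seq(1, 15, by = 2), function(qq)
    forward_model(hy0, g, fl, flow_condition(q_ul_min = qq), 18.3)$x_disp)
  expect_true(all(diff(disp) > 0))
})

test_that("noiseless forward-inverse round trip recovers the stiffness", {
  g <- default_center_geom(); fl <- fluid()
  hy <- hypha_geometry(length = 100)
  qs <- c(2, 5, 10)
  fms <- lapply(qs, function(qq)
    forward_model(hy, g, fl, flow_condition(q_ul_min = qq), k_b = 18.3))
  m <- deflection_measurements(qs, sapply(fms, `[[`, "x_disp"),
                               alpha1 = sapply(fms, `[[`, "alpha1"))
  fit <- fit_bending_stiffness(m, hy, g, fl)
  expect_lt(abs(fit$k_b / 18.3 - 1), 1e-4)
  expect_equal(fit$n_used, 3)
})

test_that("noisy measurements still yield an accurate mean stiffness", {
  # 5% relative Gaussian noise on displacements, 6 flow rates,
  # Monte-Carlo over repeats with a fixed seed
  g <- default_center_geom(); fl <- fluid()
  hy <- hypha_geometry(length = 100)
  qs <- c(2, 4, 6, 8, 10, 12)
  fms <- lapply(qs, function(qq)
    forward_model(hy, g, fl, flow_condition(q_ul_min = qq), k_b = 18.3))
  x_true <- sapply(fms, `[[`, "x_disp")
  a1 <- sapply(fms, `[[`, "alpha1")
  kbs <- withr::with_seed(99, {
    replicate(200, {
      m <- deflection_measurements(qs, x_true * (1 + rnorm(6, 0, 0.05)),
                                   alpha1 = a1)
      suppressWarnings(fit_bending_stiffness(m, hy, g, fl)$k_b)
    })
  })
  expect_lt(abs(mean(kbs) / 18.3 - 1), 0.02)
})

test_that("validity filter applies the inclusive relative-deflection bound
           and the mid-plane rule", {
  hy <- hypha_geometry(length = 100)
  m <- deflection_measurements(c(5, 10), c(25, 26))
  vf <- validity_filter(m, hy, "center")
  expect_equal(vf$kept$x_disp_um, 25)     # ratio 0.25: boundary inclusive
  expect_equal(vf$excluded$x_disp_um, 26) # ratio 0.26: out
  expect_match(vf$excluded$reason, "validity filter")
  hy_off <- hypha_geometry(length = 100, z_offset = 12)
  vf2 <- validity_filter(m, hy_off, "center")
  expect_false(vf2$hypha_valid)
  # the mid-plane rule does not apply on the floor
  expect_true(validity_filter(m, hy_off, "floor")$hypha_valid)
})

test_that("a filtered point leaves the fit unchanged and exclusions are
           reported with reasons", {
  g <- default_center_geom(); fl <- fluid()
  hy <- hypha_geometry(length = 100)
  qs <- c(2, 5, 10)
  fms <- lapply(qs, function(qq)
    forward_model(hy, g, fl, flow_condition(q_ul_min = qq), k_b = 18.3))
  m <- deflection_measurements(qs, sapply(fms, `[[`, "x_disp"),
                               alpha1 = sapply(fms, `[[`, "alpha1"))
  m_plus <- rbind(m, data.frame(q_ul_min = 30, x_disp_um = 30,
                                alpha1 = 0.3, exclude = FALSE))
  fit0 <- fit_bending_stiffness(m, hy, g, fl)
  fit1 <- fit_bending_stiffness(m_plus, hy, g, fl)
  expect_equal(fit1$k_b, fit0$k_b)
  expect_match(fit1$excluded$reason, "validity filter")
  # fewer than two usable positive-flow points is an error
  expect_error(fit_bending_stiffness(m[1, ], hy, g, fl), "at least 2")
  # everything beyond the bound is a dedicated error
  m_big <- deflection_measurements(c(5, 10), c(40, 80))
  expect_error(fit_bending_stiffness(m_big, hy, g, fl),
               "validity filter|relative-deflection")
  # off-plane hypha cannot be fitted at all
  expect_error(
    fit_bending_stiffness(m, hypha_geometry(length = 100, z_offset = 12),
                          g, fl),
    "center plane")
})

test_that("omitting the tip force underestimates the stiffness, more so
           for short hyphae", {
  g <- default_center_geom(); fl <- fluid()
  bias40 <- tip_force_bias(hypha_geometry(length = 40), g, fl)
  bias80 <- tip_force_bias(hypha_geometry(length = 80), g, fl)
  expect_gt(bias40, 0)
  expect_gt(bias80, 0)
  expect_gt(bias40, bias80)
})

test_that("a 10 um mid-plane offset costs under five percent of the load
           for the default chamber height, less for taller chambers", {
  fl <- fluid()
  dev90 <- center_plane_force_deviation(default_center_geom(), fl, 10)
  expect_gt(dev90, 0)
  expect_lt(dev90, 0.05)
  devs <- sapply(c(90, 110, 130, 150), function(h)
    center_plane_force_deviation(channel_geometry(500, h, "center"), fl, 10))
  expect_true(all(diff(devs) < 0))
})

test_that("hypha geometry and measurement constructors validate invariants", {
  expect_error(hypha_geometry(length = 1, radius = 1.4), "exceed the radius")
  expect_error(hypha_geometry(length = 50, wall_thickness = 2), "t <= r")
  expect_error(hypha_geometry(length = 50, tilt = 2), "pi/2")
  expect_error(deflection_measurements(-1, 0), ">= 0")
  expect_error(deflection_measurements(1, 0, alpha1 = 2), "pi/2")
})
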