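test_that("velocity field satisfies no-slip on all four walls", {
  g <- default_center_geom(); fl <- fluid(); q <- flow_condition(q_ul_min = 10)
  u_max <- velocity_field(g, fl, q, g$width / 2, g$height / 2)
  ys <- seq(0, g$width, length.out = 11)
  zs <- seq(0, g$height, length.out = 11)
  walls <- c(velocity_field(g, fl, q, 0, zs),
             velocity_field(g, fl, q, g$width, zs),
             velocity_field(g, fl, q, ys, 0),
             velocity_field(g, fl, q, ys, g$height))
  expect_lt(max(abs(walls)) / u_max, 1e-3)
  # side walls are exactly zero term by term (cosh ratio = 1 there)
  expect_equal(velocity_field(g, fl, q, 0, g$height / 2), 0)
})

test_that("cross-section quadrature of the velocity recovers the flow rate", {
  g <- default_center_geom(); fl <- fluid(); q <- flow_condition(q_ul_min = 10)
  ys <- seq(0, g$width, length.out = 201)
  zs <- seq(0, g$height, length.out = 201)
  U <- outer(ys, zs, function(y, z) velocity_field(g, fl, q, y, z, n_max = 101))
  wy <- rep(diff(ys)[1], length(ys)); wy[c(1, length(ys))] <- wy[1] / 2
  wz <- rep(diff(zs)[1], length(zs)); wz[c(1, length(zs))] <- wz[1] / 2
  q_num <- as.numeric(t(wy) %*% U %*% wz)
  expect_lt(abs(q_num - q$q) / q$q, 1e-3)
})

test_that("wide channels approach the parallel-plate parabolic limit", {
  fl <- fluid(); q <- flow_condition(q_ul_min = 10)
  # u_max/u_mean -> 1.5 and the deviation shrinks with aspect ratio
  dev <- sapply(c(50, 200), function(ar) {
    g <- channel_geometry(ar * 100, 100, "center")
    u_mean <- q$q / (g$width * g$height)
    abs(velocity_field(g, fl, q, g$width / 2, g$height / 2) / u_mean - 1.5) / 1.5
  })
  expect_lt(dev[1], 0.02)
  expect_lt(dev[2], 0.005)
  expect_lt(dev[2], dev[1])
  # wall gradient at mid-span -> 6 Q / (w h^2)
  g <- channel_geometry(5000, 100, "center")
  grad <- wall_velocity_gradient(g, fl, q, g$width / 2)
  expect_lt(abs(grad / (6 * q$q / (g$width * g$height^2)) - 1), 0.01)
})

test_that("wall gradient matches a finite-difference probe of the field", {
  g <- default_center_geom(); fl <- fluid(); q <- flow_condition(q_ul_min = 10)
  for (y in c(50, 250, 400)) {
    dz <- g$height * 1e-6
    fd <- velocity_field(g, fl, q, y, dz) / dz
    expect_lt(abs(fd / wall_velocity_gradient(g, fl, q, y) - 1), 1e-4)
  }
  expect_equal(wall_velocity_gradient(g, fl, q, 0), 0)
})

test_that("hydraulic resistance matches the lubrication limit, a Poisson
           solve of the square duct, and is linear in viscosity", {
  fl <- fluid()
  gwide <- channel_geometry(10000, 100, "center")
  expect_lt(abs(resistance_per_length(gwide, fl) /
                  (12 * fl$viscosity / (100^3 * 10000)) - 1), 0.01)
  gsq <- channel_geometry(100, 100, "floor")
  const_pkg <- resistance_per_length(gsq, fl) * 100^4 / fl$viscosity
  const_fd <- fd_square_duct_constant(120)
  expect_lt(abs(const_pkg / const_fd - 1), 0.01)
  expect_lt(abs(const_pkg / 28.4 - 1), 0.01) # literature duct constant
  fl2 <- fluid(2 * fl$viscosity)
  expect_equal(resistance_per_length(gsq, fl2),
               2 * resistance_per_length(gsq, fl))
})

test_that("pressure gradient implied by the field is consistent with R_f", {
  # momentum balance: mu * laplacian(u) = -dp/dx = -R_f * Q; probe the
  # laplacian by central finite differences at interior points. The
  # term-wise laplacian of the truncated series converges only like
  # 1/n_max (Gibbs), so a high order is used for this pointwise check.
  g <- default_center_geom(); fl <- fluid(); q <- flow_condition(q_ul_min = 10)
  nm <- 1001
  gradp <- resistance_per_length(g, fl, nm) * q$q
  d <- 0.2
  for (pt in list(c(250, 45), c(150, 30), c(350, 60))) {
    y <- pt[1]; z <- pt[2]
    lap <- (velocity_field(g, fl, q, y + d, z, nm) +
              velocity_field(g, fl, q, y - d, z, nm) +
              velocity_field(g, fl, q, y, z + d, nm) +
              velocity_field(g, fl, q, y, z - d, nm) -
              4 * velocity_field(g, fl, q, y, z, nm)) / d^2
    expect_lt(abs(-fl$viscosity * lap / gradp - 1), 0.005)
  }
  # doubling Q doubles the field everywhere (linearity through rf * Q)
  qd <- flow_condition(q_um3_s = 2 * q$q)
  expect_equal(velocity_field(g, fl, qd, 123, 45),
               2 * velocity_field(g, fl, q, 123, 45))
})

test_that("velocity field is symmetric about both mid-planes", {
  g <- default_center_geom(); fl <- fluid(); q <- flow_condition(q_ul_min = 7)
  ys <- c(10, 100, 230); zs <- c(5, 30, 44)
  expect_equal(velocity_field(g, fl, q, ys, zs),
               velocity_field(g, fl, q, g$width - ys, zs))
  expect_equal(velocity_field(g, fl, q, ys, zs),
               velocity_field(g, fl, q, ys, g$height - zs))
})

test_that("series converges monotonically at the channel centre", {
  g <- default_center_geom(); fl <- fluid(); q <- flow_condition(q_ul_min = 10)
  orders <- seq(1, 21, by = 2)
  u <- sapply(orders, function(nm)
    velocity_field(g, fl, q, g$width / 2, g$height / 2, n_max = nm))
  inc <- abs(diff(u))
  expect_true(all(diff(inc) < 0))
})

test_that("flow-rate fit round-trips a noiseless profile and averages out
           multiplicative noise", {
  g <- default_center_geom(); fl <- fluid(); q0 <- flow_condition(q_ul_min = 10)
  y <- seq(10, 490, length.out = 40)
  prof <- data.frame(axis = "H", position_um = y,
                     velocity_um_s = velocity_field(g, fl, q0, y, g$height / 2))
  fit <- fit_flow_rate(prof, g, fl)
  expect_lt(abs(fit$q_um3_s / q0$q - 1), 1e-6)
  # 2% multiplicative Gaussian noise, 200 Monte-Carlo repeats
  qs <- withr::with_seed(42, {
    replicate(200, {
      noisy <- prof
      noisy$velocity_um_s <- noisy$velocity_um_s * (1 + rnorm(40, 0, 0.02))
      fit_flow_rate(noisy, g, fl)$q_um3_s
    })
  })
  expect_lt(abs(mean(qs) / q0$q - 1), 0.01)
})

test_that("vertical-profile samples are excluded from the fit by default", {
  g <- default_center_geom(); fl <- fluid(); q0 <- flow_condition(q_ul_min = 10)
  prof <- simulate_velocity_profiles(g, fl, q0, artifact = TRUE, noise_rel = 0)
  fit_all <- fit_flow_rate(prof, g, fl)
  fit_h <- fit_flow_rate(prof[prof$axis == "H", ], g, fl)
  expect_equal(fit_all$q_um3_s, fit_h$q_um3_s)
  expect_error(fit_flow_rate(prof[prof$axis == "V", ], g, fl),
               "no usable samples")
  zero <- data.frame(axis = "H", position_um = c(100, 200, 300),
                     velocity_um_s = 0)
  expect_error(fit_flow_rate(zero, g, fl), "degenerate")
})

test_that("geometry, fluid and flow constructors validate their inputs", {
  expect_error(channel_geometry(-1, 90), "width")
  expect_error(channel_geometry(500, 0), "height")
  expect_error(fluid(0), "viscosity")
  expect_error(flow_condition(q_ul_min = -1))
  expect_error(flow_condition(q_ul_min = 1, q_um3_s = 1), "exactly one")
  g <- default_center_geom()
  expect_error(velocity_field(g, fluid(), flow_condition(q_ul_min = 1),
                              y = 600, z = 45), "within")
  expect_error(velocity_field(g, fluid(), flow_condition(q_ul_min = 1),
                              y = 100, z = 45, n_max = 10), "odd")
  # the center configuration doubles the molded floor height
  gc <- paired_center_geometry(default_floor_geom())
  expect_equal(gc$height, 2 * default_floor_geom()$height)
  expect_equal(gc$configuration, "center")
})
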