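# Independent numerical oracles and small fixture builders used across the
# test files. The oracles deliberately use different discretisations than
# the package (finite differences instead of cumulative quadrature /
# series) so agreement is evidence, not tautology.

default_center_geom <- function() channel_geometry(500, 90, "center")
default_floor_geom <- function() channel_geometry(500, 45, "floor")

# distributed_load stand-in with an arbitrary force profile f(y) in uN/um
make_load <- function(f, geom = default_center_geom(), r = 1.4) {
  structure(
    list(f = f, configuration = geom$configuration, n_max = 11, geom = geom,
         fluid = fluid(), flow = flow_condition(q_um3_s = 0), r = r),
    class = "distributed_load"
  )
}

# Finite-difference solve of the clamped-free cantilever w'''' = q(y)/kb.
# Second-order central biharmonic stencil in the interior with
# second-order one-sided stencils for the free-end conditions; entirely
# independent of the package's cumulative-quadrature route.
fd_beam_tip <- function(qfun, L, kb, N = 2000) {
  h <- L / N
  s <- seq(0, L, length.out = N + 1)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0); rhs <- numeric(N + 1)
  add <- function(row, cols, vals) {
    ii <<- c(ii, rep(row, length(cols))); jj <<- c(jj, cols); xx <<- c(xx, vals)
  }
  add(1, 1, 1)                                   # w(0) = 0
  add(2, 1:3, c(-3, 4, -1))                      # w'(0) = 0
  for (i in 2:(N - 2)) {                         # interior biharmonic
    row <- i + 1
    add(row, (i - 1):(i + 3), c(1, -4, 6, -4, 1))
    rhs[row] <- h^4 * qfun(s[i + 1]) / kb
  }
  add(N, (N + 1) - (3:0), c(-1, 4, -5, 2))        # w''(L) = 0
  add(N + 1, (N + 1) - (4:0), c(1.5, -7, 12, -9, 2.5)) # w'''(L) = 0
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(N + 1, N + 1))
  w <- as.numeric(Matrix::solve(A, rhs))
  w[N + 1]
}

# Finite-difference Poisson solve of fully developed axial flow on a square
# cross-section (unit side, unit pressure gradient over viscosity):
# -lap(u) = 1, u = 0 on the boundary. Returns the duct constant
# R_f h^4 / mu = 1 / integral(u).
fd_square_duct_constant <- function(m = 120) {
  h <- 1 / (m + 1)
  e <- rep(1, m)
  # 1-D second-difference matrix: 2 on the diagonal, -1 off
  D <- Matrix::bandSparse(m, k = c(-1, 0, 1),
                          diagonals = list(-e[-1], 2 * e, -e[-1]))
  I <- Matrix::Diagonal(m)
  A <- (Matrix::kronecker(I, D) + Matrix::kronecker(D, I)) / h^2
  u <- as.numeric(Matrix::solve(A, rep(1, m * m)))
  q <- sum(u) * h^2
  1 / q
}

# Series-parallel fold of a ladder network: series resistors r_series[i]
# between nodes i and i+1, shunt resistors r_shunt[i] from node i to the
# reference, inflow q at node 1. Returns node pressures and branch flows.
ladder_fold <- function(r_series, r_shunt, q) {
  n <- length(r_shunt)
  stopifnot(length(r_series) == n - 1)
  req <- numeric(n)
  req[n] <- r_shunt[n]
  for (k in (n - 1):1)
    req[k] <- 1 / (1 / r_shunt[k] + 1 / (r_series[k] + req[k + 1]))
  p <- numeric(n); i_in <- q
  for (k in seq_len(n)) {
    p[k] <- i_in * req[k]
    if (k < n) i_in <- i_in - p[k] / r_shunt[k]
  }
  shunt_flow <- p / r_shunt
  series_flow <- if (n > 1) (p[-n] - p[-1]) / r_series else numeric(0)
  list(pressures = p, shunt_flow = shunt_flow, series_flow = series_flow)
}

# numerical second moment of an annulus by area integration of x^2
area_integral_annulus <- function(r, t, n = 2000) {
  xs <- seq(-r, r, length.out = n)
  h <- xs[2] - xs[1]
  chord <- function(x, rad) 2 * sqrt(pmax(rad^2 - x^2, 0))
  sum(xs^2 * (chord(xs, r) - chord(xs, r - t))) * h
}
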