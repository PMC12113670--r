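test_that("tridiagonal solve agrees with a dense solve and is linear", {
  # identity system
  expect_equal(solve_tridiagonal(c(0, 0), c(1, 1, 1), c(0, 0), c(3, -1, 2)),
               c(3, -1, 2))
  # classic 3x3 case against dense Gaussian elimination
  x <- solve_tridiagonal(c(-1, -1), c(2, 2, 2), c(-1, -1), c(1, 0, 1))
  expect_equal(x, dense_tridiag_solve(c(-1, -1), c(2, 2, 2), c(-1, -1),
                                      c(1, 0, 1)), tolerance = 1e-13)
  # random diagonally dominant systems, padded and unpadded off-diagonals
  set.seed(42)
  for (m in c(1, 2, 7, 40)) {
    lo <- runif(max(m - 1, 1), -1, 1); up <- runif(max(m - 1, 1), -1, 1)
    if (m == 1) { lo <- numeric(0); up <- numeric(0) }
    di <- 2.5 + runif(m)
    r <- rnorm(m)
    x <- solve_tridiagonal(lo, di, up, r)
    expect_equal(x, dense_tridiag_solve(lo, di, up, r), tolerance = 1e-12)
    if (m > 2) {
      xp <- solve_tridiagonal(c(0, lo), di, c(up, 0), r)  # padded layout
      expect_equal(xp, x)
    }
    # linearity
    r2 <- rnorm(m)
    expect_equal(solve_tridiagonal(lo, di, up, r + r2),
                 solve_tridiagonal(lo, di, up, r) +
                 solve_tridiagonal(lo, di, up, r2), tolerance = 1e-12)
  }
  expect_error(solve_tridiagonal(c(0), c(0, 1), c(0), c(1, 1)), "singular")
})

test_that("Poisson solve: zero forcing, linearity, manufactured solution", {
  g <- make_grid(41, 33, A = 5)
  expect_equal(solve_poisson_stream(matrix(0, 41, 33), g),
               matrix(0, 41, 33))

  manufactured_err <- function(N1, N2, A = 5) {
    gg <- make_grid(N1, N2, A)
    psi_star <- outer(sin(pi * gg$x1 / A), sin(pi * gg$x2))
    om <- pi^2 * (1 / A^2 + 1) * psi_star
    max(abs(solve_poisson_stream(om, gg) - psi_star))
  }
  e1 <- manufactured_err(41, 33)
  e2 <- manufactured_err(81, 65)
  expect_lt(e1, 2e-3)
  expect_gt(e1 / e2, 3.5)  # ~second-order convergence

  # linearity and boundary values
  set.seed(7)
  om <- matrix(rnorm(41 * 33), 41, 33)
  p1 <- solve_poisson_stream(om, g)
  expect_equal(solve_poisson_stream(2 * om, g), 2 * p1, tolerance = 1e-12)
  expect_true(all(p1[c(1, 41), ] == 0) && all(p1[, c(1, 33)] == 0))
  # the discrete 5-point residual meets the contract
  i <- 2:40; j <- 2:32
  lap <- (p1[i + 1, j] - 2 * p1[i, j] + p1[i - 1, j]) / g$dx1^2 +
         (p1[i, j + 1] - 2 * p1[i, j] + p1[i, j - 1]) / g$dx2^2
  expect_lt(max(abs(lap + om[i, j])), 1e-8)
})

test_that("ADI advance: constants are fixed points and sine modes decay at
           the exact heat-equation rate", {
  g <- make_grid(9, 81, A = 1)
  z <- matrix(0, 9, 81)
  f0 <- matrix(3.7, 9, 81)
  cfs <- transport_coeffs(1)
  f1 <- adi_advance_scalar(f0, z, z, cfs, dt = 1e-3, g)
  expect_equal(f1, f0, tolerance = 1e-14)

  # Dirichlet-0 sine mode in x2, uniform in x1 (reflecting side walls):
  # amplitude ~ exp(-D pi^2 t)
  f <- matrix(sin(pi * g$x2), 9, 81, byrow = TRUE)
  bc <- function(x) {
    x[, c(1, 81)] <- 0
    x[c(1, 9), ] <- x[c(2, 8), ]
    x
  }
  dt <- 1e-4
  for (k in 1:500) f <- adi_advance_scalar(f, z, z, cfs, dt, g, bc)
  expect_equal(max(f), exp(-pi^2 * 0.05), tolerance = 1e-2)
})

test_that("one ADI step matches an explicit Euler oracle to O(dt^2)", {
  g <- make_grid(7, 7, A = 1)
  set.seed(11)
  f0 <- matrix(runif(49), 7, 7)
  u <- matrix(rnorm(49, sd = 0.3), 7, 7)
  v <- matrix(rnorm(49, sd = 0.3), 7, 7)
  src <- matrix(rnorm(49, sd = 0.5), 7, 7)
  cfs <- transport_coeffs(0.7, swim_velocity = 0.4, source_field = src)
  err <- vapply(c(1e-3, 5e-4, 2.5e-4), function(dt) {
    a <- adi_advance_scalar(f0, u, v, cfs, dt, g)
    e <- euler_scalar_step(f0, u, v + 0.4, 0.7, src, dt, g)
    max(abs(a - e))
  }, numeric(1))
  order1 <- log2(err[1] / err[2])
  order2 <- log2(err[2] / err[3])
  expect_gt(order1, 1.9)
  expect_gt(order2, 1.9)
})

test_that("ADI rejects steps that break diagonal dominance", {
  g <- make_grid(11, 11, A = 1)
  u <- matrix(50, 11, 11)
  f <- matrix(runif(121), 11, 11)
  expect_error(
    adi_advance_scalar(f, u, u, transport_coeffs(0.01), dt = 0.5, g),
    "unstable")
})

test_that("ADI diffusion is stable far beyond the explicit limit", {
  g <- make_grid(21, 41, A = 1)
  z <- matrix(0, 21, 41)
  set.seed(3)
  f <- matrix(runif(21 * 41), 21, 41)
  bc <- function(x) { x[c(1, 21), ] <- 0; x[, c(1, 41)] <- 0; x }
  f <- bc(f)
  dt_expl <- g$dx2^2 / 4          # explicit diffusive limit
  f2 <- f
  norms <- numeric(20)
  for (k in 1:20) {
    f2 <- adi_advance_scalar(f2, z, z, transport_coeffs(1), 100 * dt_expl, g, bc)
    norms[k] <- max(abs(f2))
  }
  expect_true(all(is.finite(norms)))
  expect_true(all(diff(norms) <= 1e-12))  # monotone decay, no blow-up
})

test_that("Thom wall vorticity reproduces the quadratic closure and scales
           linearly", {
  g <- make_grid(21, 21, A = 1)
  z <- matrix(0, 21, 21)
  expect_equal(apply_wall_vorticity(z, z, g), z)

  # psi = x2^2 near the bottom wall: omega_wall = -2 psi_adj/h^2 = -2
  psi <- matrix(g$x2^2, 21, 21, byrow = TRUE)
  psi[, 1] <- 0
  om <- apply_wall_vorticity(psi, z, g)
  expect_equal(om[5, 1], -2)
  om3 <- apply_wall_vorticity(3 * psi, z, g)
  expect_equal(om3[2:20, 1], 3 * om[2:20, 1])
  # interior untouched
  om_in <- matrix(9, 21, 21)
  out <- apply_wall_vorticity(psi, om_in, g)
  expect_true(all(out[2:20, 2:20] == 9))
})

test_that("flux boundary conditions reproduce their defining balances", {
  g <- make_grid(21, 41, A = 2)
  p <- sim_params(Pe = 1, Pen = 0.1, delta_Bm = 0.5, delta_Tm = 0.2, A = 2,
                  phi_zero_net_flux = FALSE)
  tb <- build_theta_boundary(list(), g)

  # Pe = Pen = 0: a vertically uniform n passes unchanged
  p0 <- sim_params(Pe = 0, Pen = 0, A = 2)
  st <- init_basic_state(p0, g)
  st$n <- matrix(1.3, 21, 41)
  out <- apply_flux_bcs(st, p0, g, tb)
  expect_equal(out$n, st$n, tolerance = 1e-14)

  # the exponential rest profile satisfies the discrete microorganism
  # balance at both horizontal walls to truncation order
  p1 <- sim_params(Pe = 1, A = 2)
  stb <- init_basic_state(p1, g)
  out <- apply_flux_bcs(stb, p1, g, tb)
  expect_equal(out$n, stb$n, tolerance = 5e-5)

  # theta with sources off -> exactly 0 on all four walls
  st$theta <- matrix(0.5, 21, 41)
  out <- apply_flux_bcs(st, p, g, tb)
  expect_true(all(out$theta[c(1, 21), ] == 0) &&
              all(out$theta[, c(1, 41)] == 0))
  # psi zeroed on the boundary
  st$psi <- matrix(1, 21, 41)
  out <- apply_flux_bcs(st, p, g, tb)
  expect_true(all(out$psi[c(1, 21), ] == 0) && all(out$psi[, c(1, 41)] == 0))

  # nanoparticle Robin balance holds discretely at the bottom wall
  st$theta <- matrix(g$x2, 21, 41, byrow = TRUE)  # after Dirichlet: interior kept
  st$phi <- matrix(2 + g$x2^2, 21, 41, byrow = TRUE)
  out <- apply_flux_bcs(st, p, g, tb)
  phi <- out$phi; theta <- out$theta
  dphi <- (-3 * phi[10, 1] + 4 * phi[10, 2] - phi[10, 3]) / (2 * g$dx2)
  dth  <- (-3 * theta[10, 1] + 4 * theta[10, 2] - theta[10, 3]) / (2 * g$dx2)
  expect_equal(p$delta_Bm * dphi + p$delta_Tm * dth - p$Pen * phi[10, 1], 0,
               tolerance = 1e-12)
})
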