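# Shared fixtures and independent oracles used across the test files.
# The oracles deliberately re-derive each discrete operation with plain R
# loops/vector code so they stay independent of the package's kernels.

# trapezoidal integral of a field over the cavity
trap_int <- function(f, g) {
  w1 <- rep(1, g$Nx1); w1[c(1, g$Nx1)] <- 0.5
  w2 <- rep(1, g$Nx2); w2[c(1, g$Nx2)] <- 0.5
  g$dx1 * g$dx2 * sum((w1 %o% w2) * f)
}

# dense solve of a tridiagonal system (oracle for the Thomas kernel)
dense_tridiag_solve <- function(lower, diag, upper, rhs) {
  m <- length(diag)
  A <- matrix(0, m, m)
  diag(A) <- diag
  if (m > 1) {
    A[cbind(2:m, 1:(m - 1))] <- lower
    A[cbind(1:(m - 1), 2:m)] <- upper
  }
  solve(A, rhs)
}

# one explicit Euler step of the node-centred semi-discretisation used by
# adi_advance_scalar: conservative centred advection + 5-point Laplacian +
# source, boundary values held fixed.
euler_scalar_step <- function(f, u, veff, D, src, dt, g) {
  Nx <- g$Nx1; Ny <- g$Nx2
  i <- 2:(Nx - 1); j <- 2:(Ny - 1)
  out <- f
  adv <- (u[i + 1, j] * f[i + 1, j] - u[i - 1, j] * f[i - 1, j]) / (2 * g$dx1) +
         (veff[i, j + 1] * f[i, j + 1] - veff[i, j - 1] * f[i, j - 1]) / (2 * g$dx2)
  lap <- (f[i + 1, j] - 2 * f[i, j] + f[i - 1, j]) / g$dx1^2 +
         (f[i, j + 1] - 2 * f[i, j] + f[i, j - 1]) / g$dx2^2
  out[i, j] <- f[i, j] + dt * (-adv + D * lap + src[i, j])
  out
}

# one explicit Euler step of the conservative finite-volume semi-
# discretisation used for the microorganism / nanoparticle fields: interface
# fluxes F = u_half (f_l+f_r)/2 - D (f_r-f_l)/h - dTm (th_r-th_l)/h, wall
# fluxes equal to the Robin balance (zero, or -leak*f at the horizontal
# walls).  All nodes evolve; cell widths are h (interior) and h/2 (walls).
euler_fv_step <- function(f, u, veff, D, th, dTm, leak, dt, g) {
  Nx <- g$Nx1; Ny <- g$Nx2
  h1 <- g$dx1; h2 <- g$dx2
  Fx <- matrix(0, Nx + 1, Ny)  # Fx[i,] = flux at interface i-1/2 (1 = wall)
  Fy <- matrix(0, Nx, Ny + 1)
  for (i in 1:(Nx - 1)) {
    uh <- (u[i, ] + u[i + 1, ]) / 2
    Fx[i + 1, ] <- uh * (f[i, ] + f[i + 1, ]) / 2 -
      D * (f[i + 1, ] - f[i, ]) / h1 - dTm * (th[i + 1, ] - th[i, ]) / h1
  }
  for (j in 1:(Ny - 1)) {
    vh <- (veff[, j] + veff[, j + 1]) / 2
    Fy[, j + 1] <- vh * (f[, j] + f[, j + 1]) / 2 -
      D * (f[, j + 1] - f[, j]) / h2 - dTm * (th[, j + 1] - th[, j]) / h2
  }
  Fy[, 1] <- -leak * f[, 1]
  Fy[, Ny + 1] <- -leak * f[, Ny]
  wx <- rep(h1, Nx); wx[c(1, Nx)] <- h1 / 2
  wy <- rep(h2, Ny); wy[c(1, Ny)] <- h2 / 2
  out <- f
  for (i in 1:Nx) for (j in 1:Ny) {
    out[i, j] <- f[i, j] - dt * ((Fx[i + 1, j] - Fx[i, j]) / wx[i] +
                                 (Fy[i, j + 1] - Fy[i, j]) / wy[j])
  }
  out
}

# one explicit Euler step of the full coupled semi-discretisation, mirroring
# the sub-step ordering of time_step but without operator splitting.
euler_coupled_step <- function(state, cfg, tb) {
  p <- cfg$params; g <- cfg$grid; dt <- cfg$dt
  i <- 2:(g$Nx1 - 1); j <- 2:(g$Nx2 - 1)
  uv <- velocity_from_stream(state$psi, g)
  # vorticity with buoyancy sources
  src <- matrix(0, g$Nx1, g$Nx2)
  src[i, j] <- (-p$Sc * p$Ra * (state$n[i + 1, j] - state$n[i - 1, j]) +
                p$Le * p$Sc * p$RaT * (state$theta[i + 1, j] - state$theta[i - 1, j]) -
                p$Le * p$Sc * p$Ran * (state$phi[i + 1, j] - state$phi[i - 1, j])) /
               (2 * g$dx1)
  om <- euler_scalar_step(state$omega, uv$u, uv$v, p$Sc, src, dt, g)
  psi <- solve_poisson_stream(om, g)
  om <- apply_wall_vorticity(psi, om, g)
  uv <- velocity_from_stream(psi, g)
  leak_n <- if (p$micro_bc_includes_pen) p$Pen else 0
  zero <- matrix(0, g$Nx1, g$Nx2)
  n <- euler_fv_step(state$n, uv$u, uv$v + p$Pe, 1, zero, 0, leak_n, dt, g)
  # temperature with explicit coupling sources, Dirichlet walls
  tx1 <- (state$theta[i + 1, j] - state$theta[i - 1, j]) / (2 * g$dx1)
  tx2 <- (state$theta[i, j + 1] - state$theta[i, j - 1]) / (2 * g$dx2)
  px1 <- (state$phi[i + 1, j] - state$phi[i - 1, j]) / (2 * g$dx1)
  px2 <- (state$phi[i, j + 1] - state$phi[i, j - 1]) / (2 * g$dx2)
  src_th <- matrix(0, g$Nx1, g$Nx2)
  src_th[i, j] <- p$r_rho * p$delta_Bm * (px1 * tx1 + px2 * tx2) +
                  p$r_rho * p$delta_Tm * (tx1^2 + tx2^2)
  th <- euler_scalar_step(state$theta, uv$u, uv$v, p$Le, src_th, dt, g)
  th[1, ] <- tb$left; th[g$Nx1, ] <- tb$right
  th[, 1] <- tb$bottom; th[, g$Nx2] <- tb$top
  phi <- euler_fv_step(state$phi, uv$u, uv$v + p$Pen, p$delta_Bm, th,
                       p$delta_Tm, 0, dt, g)
  new <- state
  new$psi <- psi; new$omega <- om; new$n <- n; new$theta <- th; new$phi <- phi
  new$t <- state$t + dt
  new
}

max_abs_diff_state <- function(a, b) {
  max(abs(a$psi - b$psi), abs(a$omega - b$omega), abs(a$n - b$n),
      abs(a$theta - b$theta), abs(a$phi - b$phi))
}
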