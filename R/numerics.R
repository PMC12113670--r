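## numerics: tridiagonal solves, Poisson solve for psi, ADI advance of one
## scalar, wall vorticity and flux boundary conditions.

#' Solve a tridiagonal linear system
#'
#' Thomas-algorithm solve of `A x = rhs` where `A` has sub-, main and
#' super-diagonals `lower`, `diag`, `upper`.  `lower` and `upper` may be
#' given either with length `m - 1` (the usual band layout) or padded to
#' length `m` (the first entry of `lower` and the last of `upper` are then
#' ignored).
#'
#' @param lower,diag,upper band coefficients.
#' @param rhs right-hand side, length `m`.
#' @return Solution vector of length `m`.
#' @export
solve_tridiagonal <- function(lower, diag, upper, rhs) {
  m <- length(diag)
  if (length(rhs) != m) stop("solve_tridiagonal: rhs length mismatch", call. = FALSE)
  pad <- function(x, side) {
    if (length(x) == m) return(x)
    if (length(x) == m - 1L)
      return(if (side == "lower") c(0, x) else c(x, 0))
    stop("solve_tridiagonal: off-diagonal length must be m or m-1", call. = FALSE)
  }
  if (m == 1L) return(rhs / diag)
  as.vector(cpp_thomas(pad(lower, "lower"), diag, pad(upper, "upper"), rhs))
}

#' Solve the stream-function Poisson equation
#'
#' Direct solve of \eqn{\nabla^2\psi = -\omega} on the uniform grid with
#' homogeneous Dirichlet walls (\eqn{\psi = 0}), via a sine expansion along
#' x2 and tridiagonal solves along x1.  The discrete 5-point residual is at
#' machine level; `tol` is the residual contract checked after the solve.
#'
#' @param omega vorticity matrix on `g`.
#' @param g a [make_grid()] grid.
#' @param tol maximum admissible residual of the discrete Poisson equation.
#' @return Stream-function matrix with zero boundary values.
#' @export
solve_poisson_stream <- function(omega, g, tol = 1e-8) {
  stopifnot(inherits(g, "bc_grid"),
            is.matrix(omega), nrow(omega) == g$Nx1, ncol(omega) == g$Nx2)
  if (!all(is.finite(omega)))
    stop("solve_poisson_stream: omega must be finite", call. = FALSE)
  psi <- cpp_poisson_psi(omega, g$dx1, g$dx2)
  res <- poisson_residual(psi, omega, g)
  if (res > tol)
    stop("solve_poisson_stream: residual ", format(res),
         " exceeds tolerance ", format(tol), call. = FALSE)
  psi
}

## max interior residual of lap(psi) + omega
poisson_residual <- function(psi, omega, g) {
  i <- 2:(g$Nx1 - 1); j <- 2:(g$Nx2 - 1)
  lap <- (psi[i + 1, j] - 2 * psi[i, j] + psi[i - 1, j]) / g$dx1^2 +
         (psi[i, j + 1] - 2 * psi[i, j] + psi[i, j - 1]) / g$dx2^2
  max(abs(lap + omega[i, j]))
}

#' Transport coefficients for one scalar equation
#'
#' Bundles the per-equation pieces of the generic advection--diffusion--source
#' form \eqn{\partial f/\partial t + \partial(u_{eff} f)/\partial x_i =
#' D\nabla^2 f + S}: the diffusivity `D`, an additive vertical swimming
#' velocity (used by the microorganism equation, value `Pe`), and an explicit
#' source field.
#'
#' @param diffusivity positive scalar multiplier of the Laplacian.
#' @param swim_velocity additive vertical advection speed (default 0).
#' @param source_field explicit source matrix, or `NULL` for zero.
#' @return An object of class `transport_coeffs`.
#' @export
transport_coeffs <- function(diffusivity, swim_velocity = 0, source_field = NULL) {
  if (!is.numeric(diffusivity) || diffusivity <= 0)
    stop("transport_coeffs: diffusivity must be > 0", call. = FALSE)
  structure(list(diffusivity = diffusivity, swim_velocity = swim_velocity,
                 source_field = source_field),
            class = "transport_coeffs")
}

#' Advance one scalar field by a full ADI step
#'
#' Performs the x1-implicit then x2-implicit half-steps (each of size
#' `dt/2`) of the conservative advection--diffusion--source equation, with
#' the boundary handler `bc` applied after each half-step.  During each
#' implicit sweep the boundary values of `f` are held at their current
#' values.
#'
#' @param f scalar field matrix.
#' @param u,v velocity component matrices.
#' @param c a [transport_coeffs()] object.
#' @param dt time step, > 0.
#' @param g a [make_grid()] grid.
#' @param bc boundary handler `function(field) field` re-imposing the
#'   physical boundary condition; defaults to holding the current boundary
#'   values (identity).
#' @return The advanced field matrix.
#' @export
adi_advance_scalar <- function(f, u, v, c, dt, g, bc = identity) {
  stopifnot(inherits(g, "bc_grid"), inherits(c, "transport_coeffs"), dt > 0)
  src <- if (is.null(c$source_field)) matrix(0, g$Nx1, g$Nx2) else c$source_field
  veff <- v + c$swim_velocity
  f <- cpp_adi_half(f, u, veff, c$diffusivity, src, dt, g$dx1, g$dx2, 0L)
  f <- bc(f)
  f <- cpp_adi_half(f, u, veff, c$diffusivity, src, dt, g$dx1, g$dx2, 1L)
  bc(f)
}

#' Thom wall-vorticity closure
#'
#' Overwrites the wall rows/columns of `omega` with the first-order Thom
#' value \eqn{\omega_w = -2\psi_{adj}/h^2}, where \eqn{\psi_{adj}} is the
#' first interior stream-function value along the inward normal and `h` the
#' normal spacing.  Requires \eqn{\psi = 0} on the walls.
#'
#' @param psi stream-function matrix (zero on walls).
#' @param omega vorticity matrix.
#' @param g a [make_grid()] grid.
#' @return `omega` with updated wall values.
#' @export
apply_wall_vorticity <- function(psi, omega, g) {
  stopifnot(inherits(g, "bc_grid"))
  cpp_apply_wall_vorticity(psi, omega, g$dx1, g$dx2)
}

#' Apply all physical boundary conditions to a field state
#'
#' Enforces, in order: Dirichlet wall temperatures from `theta_boundary`
#' (0 except on thermal sources); the microorganism wall flux balance
#' `Pe n - dn/dx2 = 0` at the top and bottom walls (with `Pe + Pen` when
#' `micro_bc_includes_pen` is set) and homogeneous Neumann on the side
#' walls; the nanoparticle flux balance
#' \eqn{\delta_{Bm}\partial\phi/\partial x_2 + \delta_{Tm}
#' \partial\theta/\partial x_2 - Pe_n\phi = 0} at the top and bottom with
#' homogeneous Neumann sides; and \eqn{\psi = 0} on all walls.  All Robin /
#' Neumann conditions use second-order one-sided differences at the wall
#' node.
#'
#' @param state a `field_state`.
#' @param p a [sim_params()] object.
#' @param g a [make_grid()] grid.
#' @param theta_boundary boundary value map from [build_theta_boundary()].
#' @return The state with boundary rows/columns updated.
#' @export
apply_flux_bcs <- function(state, p, g, theta_boundary) {
  stopifnot(inherits(p, "sim_params"), inherits(g, "bc_grid"))
  pe_eff <- p$Pe + if (p$micro_bc_includes_pen) p$Pen else 0
  out <- cpp_apply_flux_bcs(state$psi, state$n, state$theta, state$phi,
                            theta_boundary, pe_eff, p$Pen,
                            p$delta_Bm, p$delta_Tm, g$dx2,
                            p$phi_zero_net_flux)
  state$psi <- out$psi
  state$n <- out$n
  state$theta <- out$theta
  state$phi <- out$phi
  state
}
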