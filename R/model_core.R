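## model_core: parameter containers, grid, dimensionless conversion, basic
## states and velocity recovery.

#' Dimensionless parameters of one bioconvection case
#'
#' Container for all dimensionless groups of the coupled model.  Defaults are
#' the regime in which bioconvection dominates while natural convection and
#' nanoparticle buoyancy perturb it: `Ra = 1900`, `RaT = 1708`,
#' `Sc = Le = Pe = 1`, `Pen = 0.1`, `r_rho = 2.5`, in a cavity of aspect
#' ratio `A = 5`.
#'
#' @param Ra bioconvection Rayleigh number (buoyancy from the microorganism
#'   density excess).
#' @param RaT thermal Rayleigh number.
#' @param Ran nanoparticle Rayleigh number (buoyancy from the nanoparticle
#'   volume fraction).
#' @param Sc Schmidt number (momentum vs. microorganism diffusivity), > 0.
#' @param Le Lewis number (thermal vs. microorganism diffusivity), > 0.
#' @param Pe bioconvection Peclet number: dimensionless upward swimming speed.
#' @param Pen nanoparticle Peclet number: dimensionless settling speed scale
#'   entering the wall flux balance of \eqn{\phi}.
#' @param delta_Bm Brownian diffusion parameter (nanoparticle Brownian
#'   diffusivity over microorganism diffusivity), > 0.
#' @param delta_Tm thermophoretic parameter.
#' @param r_rho heat-capacity ratio weighting the Brownian/thermophoretic
#'   coupling terms in the energy equation.
#' @param A cavity aspect ratio \eqn{L/H}, > 0.
#' @param Nbar average microorganism concentration scale (free scale of the
#'   basic state; default 1).
#' @param micro_bc_includes_pen logical; if `TRUE` the wall flux balance for
#'   the microorganisms uses `(Pe + Pen) n - dn/dx2 = 0` instead of the
#'   default `Pe n - dn/dx2 = 0`.  The default is the closure under which the
#'   exponential basic state [init_basic_state()] is an exact rest solution.
#' @param phi_zero_net_flux logical; if `TRUE` (default) the nanoparticle
#'   transport is closed conservatively: the interior equation carries a
#'   vertical `Pen` drift (under which the horizontal-wall Robin balance is
#'   exactly a zero-net-flux condition) and the side walls impose
#'   \eqn{\delta_{Bm}\partial\phi/\partial x_1 + \delta_{Tm}\partial\theta/
#'   \partial x_1 = 0}, so total \eqn{\phi} is conserved and a steady state
#'   exists.  With `FALSE` the literal textbook form is used (no drift,
#'   plain `dphi/dx1 = 0` side walls); the wall balances then drain
#'   \eqn{\phi} mass whenever `Pen != 0` or \eqn{\theta} varies along a side
#'   wall, and no steady state exists.
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [dimensionless_groups()] to derive these groups from dimensional
#'   quantities.
#' @export
sim_params <- function(Ra = 1900, RaT = 1708, Ran = 0.01, Sc = 1, Le = 1,
                       Pe = 1, Pen = 0.1, delta_Bm = 0.1, delta_Tm = 0.1,
                       r_rho = 2.5, A = 5, Nbar = 1,
                       micro_bc_includes_pen = FALSE,
                       phi_zero_net_flux = TRUE) {
  p <- list(Ra = Ra, RaT = RaT, Ran = Ran, Sc = Sc, Le = Le, Pe = Pe,
            Pen = Pen, delta_Bm = delta_Bm, delta_Tm = delta_Tm,
            r_rho = r_rho, A = A, Nbar = Nbar,
            micro_bc_includes_pen = isTRUE(micro_bc_includes_pen),
            phi_zero_net_flux = isTRUE(phi_zero_net_flux))
  for (nm in setdiff(names(p), c("micro_bc_includes_pen",
                                 "phi_zero_net_flux"))) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("sim_params: '", nm, "' must be a finite numeric scalar", call. = FALSE)
  }
  for (nm in c("Sc", "Le", "delta_Bm", "A", "Nbar")) {
    if (p[[nm]] <= 0)
      stop("sim_params: '", nm, "' must be > 0", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' Dimensional inputs for conversion to dimensionless groups
#'
#' Physical (SI) quantities of a cavity suspension; used only by
#' [dimensionless_groups()].  The solver itself operates purely in
#' dimensionless form.
#'
#' @param g gravity (m/s^2).
#' @param nbar average microorganism count concentration (1/m^3).
#' @param vartheta microorganism volume (m^3).
#' @param delta_rho density difference between microorganisms and water
#'   (kg/m^3); may be any sign.
#' @param rho_w,rho_f,rho_p water, base-fluid and particle densities (kg/m^3).
#' @param nu kinematic viscosity (m^2/s).
#' @param alpha thermal diffusivity (m^2/s).
#' @param beta thermal expansion coefficient (1/K); may be any sign.
#' @param Dm microorganism diffusivity (m^2/s).
#' @param DB nanoparticle Brownian diffusivity (m^2/s).
#' @param DT thermophoretic diffusion coefficient (m^2/s).
#' @param Th,Tc,TC hot, cold and reference temperatures (K), `Th >= Tc`.
#' @param phi0 reference nanoparticle volume fraction.
#' @param H cavity height (m).
#' @param Vm upward swimming speed (m/s).
#' @param W0 nanoparticle settling speed (m/s).
#' @param cp,cf particle and fluid specific heats (J/kg/K).
#' @return An object of class `dimensional_inputs`.
#' @export
dimensional_inputs <- function(g = 9.81, nbar, vartheta, delta_rho,
                               rho_w = 1000, rho_f = 1000, rho_p,
                               nu, alpha, beta, Dm, DB, DT,
                               Th, Tc, TC, phi0, H, Vm, W0, cp, cf) {
  d <- list(g = g, nbar = nbar, vartheta = vartheta, delta_rho = delta_rho,
            rho_w = rho_w, rho_f = rho_f, rho_p = rho_p, nu = nu,
            alpha = alpha, beta = beta, Dm = Dm, DB = DB, DT = DT,
            Th = Th, Tc = Tc, TC = TC, phi0 = phi0, H = H, Vm = Vm,
            W0 = W0, cp = cp, cf = cf)
  for (nm in names(d)) {
    if (!is.numeric(d[[nm]]) || length(d[[nm]]) != 1L || !is.finite(d[[nm]]))
      stop("dimensional_inputs: '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
  }
  signed_ok <- c("beta", "delta_rho")
  for (nm in setdiff(names(d), signed_ok)) {
    if (d[[nm]] <= 0)
      stop("dimensional_inputs: '", nm, "' must be > 0", call. = FALSE)
  }
  if (d$Th < d$Tc)
    stop("dimensional_inputs: 'Th' must be >= 'Tc'", call. = FALSE)
  structure(d, class = "dimensional_inputs")
}

#' Convert dimensional quantities to the model's dimensionless groups
#'
#' Evaluates the ten dimensionless groups that govern the coupled system:
#' \deqn{Ra = g\bar n \vartheta \Delta\rho H^3 / (\rho_w \nu D_m), \quad
#'       Ra_T = g\beta(T_h - T_c)H^3/(\nu\alpha), \quad
#'       Ra_n = g(\rho_p-\rho_f)\phi_0 H^3/(\rho_w \nu \alpha),}
#' \deqn{Sc = \nu/D_m,\; Pe = V_m H/D_m,\; Pe_n = W_0 H/D_m,\;
#'       Le = \alpha/D_m,}
#' \deqn{\delta_{Tm} = D_T (T_h-T_c)/(D_m T_C \phi_0), \quad
#'       \delta_{Bm} = D_B/D_m, \quad r_\rho = \rho_p c_p \phi_0/(\rho_f c_f).}
#'
#' @param d a [dimensional_inputs()] object.
#' @param A cavity aspect ratio (not derivable from the dimensional set,
#'   which carries only the height `H`); default 5.
#' @param Nbar microorganism concentration scale passed through to the
#'   parameter set.
#' @return A [sim_params()] object.
#' @examples
#' d <- dimensional_inputs(nbar = 1e9, vartheta = 5e-14, delta_rho = 100,
#'   rho_p = 2500, nu = 1e-6, alpha = 1.43e-7, beta = 2.1e-4, Dm = 1e-8,
#'   DB = 1e-8, DT = 1e-11, Th = 300, Tc = 290, TC = 293, phi0 = 1e-3,
#'   H = 0.005, Vm = 1e-5, W0 = 1e-6, cp = 800, cf = 4180)
#' dimensionless_groups(d)
#' @export
dimensionless_groups <- function(d, A = 5, Nbar = 1) {
  stopifnot(inherits(d, "dimensional_inputs"))
  sim_params(
    Ra  = d$g * d$nbar * d$vartheta * d$delta_rho * d$H^3 / (d$rho_w * d$nu * d$Dm),
    RaT = d$g * d$beta * (d$Th - d$Tc) * d$H^3 / (d$nu * d$alpha),
    Ran = d$g * (d$rho_p - d$rho_f) * d$phi0 * d$H^3 / (d$rho_w * d$nu * d$alpha),
    Sc  = d$nu / d$Dm,
    Pe  = d$Vm * d$H / d$Dm,
    Pen = d$W0 * d$H / d$Dm,
    Le  = d$alpha / d$Dm,
    delta_Tm = d$DT * (d$Th - d$Tc) / (d$Dm * d$TC * d$phi0),
    delta_Bm = d$DB / d$Dm,
    r_rho = d$rho_p * d$cp * d$phi0 / (d$rho_f * d$cf),
    A = A, Nbar = Nbar)
}

#' Uniform rectangular grid over the cavity
#'
#' Node-centred uniform mesh on \eqn{[0,A]\times[0,1]}; the first and last
#' nodes lie exactly on the walls.
#'
#' @param Nx1 number of nodes along x1 (horizontal), >= 3.
#' @param Nx2 number of nodes along x2 (vertical), >= 3.
#' @param A cavity aspect ratio, > 0.
#' @return An object of class `bc_grid` with spacings `dx1 = A/(Nx1-1)`,
#'   `dx2 = 1/(Nx2-1)` and coordinate vectors `x1`, `x2`.
#' @examples
#' g <- make_grid(101, 81, A = 5)  # dx1 = 0.05, dx2 = 0.0125
#' @export
make_grid <- function(Nx1, Nx2, A = 5) {
  if (!is.numeric(Nx1) || !is.numeric(Nx2) || Nx1 < 3 || Nx2 < 3 ||
      Nx1 != round(Nx1) || Nx2 != round(Nx2))
    stop("make_grid: Nx1 and Nx2 must be integers >= 3", call. = FALSE)
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0)
    stop("make_grid: A must be a positive scalar", call. = FALSE)
  Nx1 <- as.integer(Nx1); Nx2 <- as.integer(Nx2)
  structure(list(
    Nx1 = Nx1, Nx2 = Nx2, A = A,
    dx1 = A / (Nx1 - 1), dx2 = 1 / (Nx2 - 1),
    x1 = seq(0, A, length.out = Nx1),
    x2 = seq(0, 1, length.out = Nx2)),
    class = "bc_grid")
}

#' Thermal source segment on a cavity wall
#'
#' Describes a heated wall segment held at dimensionless temperature
#' `theta_value` (the rest of the walls stay at 0).
#'
#' @param wall one of `"bottom"`, `"top"`, `"left"`, `"right"`.
#' @param start_frac,end_frac fractional extent along that wall, with
#'   `0 <= start_frac < end_frac <= 1`.
#' @param theta_value boundary temperature of the source (default 1).
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(wall, start_frac, end_frac, theta_value = 1) {
  wall <- match.arg(wall, c("bottom", "top", "left", "right"))
  if (!is.numeric(start_frac) || !is.numeric(end_frac) ||
      start_frac < 0 || end_frac > 1 || start_frac >= end_frac)
    stop("invalid source segment: need 0 <= start_frac < end_frac <= 1",
         call. = FALSE)
  structure(list(wall = wall, start_frac = start_frac, end_frac = end_frac,
                 theta_value = theta_value),
            class = "source_spec")
}

new_field_state <- function(psi, omega, n, theta, phi, t = 0) {
  structure(list(psi = psi, omega = omega, n = n, theta = theta, phi = phi,
                 t = t),
            class = "field_state")
}

#' Quiescent basic state used as the initial condition
#'
#' At rest the microorganisms balance upward swimming against diffusion,
#' \deqn{n_b(x_2) = \bar N \, Pe \, e^{Pe x_2} / (e^{Pe} - 1),}
#' which integrates to \eqn{\bar N} over the cavity height, and the
#' nanoparticle fraction takes the linear profile
#' \deqn{\phi_b(x_2) = -\delta_{Bm}\theta_b + (1-\delta_{Bm}) x_2 +
#' \delta_{Bm}} with basic temperature \eqn{\theta_b = 0}.  The flow is at
#' rest (\eqn{\psi = \omega = 0}).  For `Pe = 0` the microorganism profile
#' degenerates to the uniform limit \eqn{n_b = \bar N}.
#'
#' @param p a [sim_params()] object.
#' @param g a [make_grid()] grid.
#' @return A `field_state` with fields `psi`, `omega`, `n`, `theta`, `phi`
#'   (matrices of dimension `Nx1 x Nx2`) and time `t = 0`.
#' @export
init_basic_state <- function(p, g) {
  stopifnot(inherits(p, "sim_params"), inherits(g, "bc_grid"))
  nb <- if (p$Pe == 0) rep(p$Nbar, g$Nx2)
        else p$Nbar * p$Pe * exp(p$Pe * g$x2) / (exp(p$Pe) - 1)
  phib <- (1 - p$delta_Bm) * g$x2 + p$delta_Bm
  zero <- matrix(0, g$Nx1, g$Nx2)
  new_field_state(
    psi = zero, omega = zero,
    n = matrix(nb, g$Nx1, g$Nx2, byrow = TRUE),
    theta = zero,
    phi = matrix(phib, g$Nx1, g$Nx2, byrow = TRUE),
    t = 0)
}

#' Recover velocity components from the stream function
#'
#' Computes \eqn{u = \partial\psi/\partial x_2},
#' \eqn{v = -\partial\psi/\partial x_1} by centred differences (second-order
#' one-sided at the walls), the convention under which
#' \eqn{\nabla^2\psi = -\omega} with \eqn{\omega = \partial v/\partial x_1 -
#' \partial u/\partial x_2}.
#'
#' @param psi stream-function matrix on `g`.
#' @param g a [make_grid()] grid.
#' @return A list with matrices `u` and `v`.
#' @export
velocity_from_stream <- function(psi, g) {
  stopifnot(inherits(g, "bc_grid"),
            is.matrix(psi), nrow(psi) == g$Nx1, ncol(psi) == g$Nx2)
  cpp_velocity(psi, g$dx1, g$dx2)
}
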