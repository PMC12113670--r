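---
title: "Methods: the coupled bioconvection–nanoparticle cavity model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coupled bioconvection–nanoparticle cavity model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`biocavity` simulates a dilute aqueous suspension of upward-swimming
(gravitactic) microorganisms such as *Paramecium caudatum* together with
heavy nanoparticles, in a two-dimensional rectangular cavity
$[0,A]\times[0,1]$ (aspect ratio $A = L/H$, gravity along $-x_2$).  Five
coupled dimensionless fields are evolved: the stream function $\psi$,
vorticity $\omega$, microorganism concentration $n$, temperature $\theta$
and nanoparticle volume fraction $\phi$.  Lengths are scaled by the cavity
height $H$, time by $H^2/D_m$ (with $D_m$ the microorganism diffusivity),
and velocities by $D_m/H$; $\theta$ and $\phi$ are affine rescalings of
temperature and particle fraction so that cold walls sit at $\theta = 0$,
thermal sources at $\theta = 1$.

With $u = \partial\psi/\partial x_2$, $v = -\partial\psi/\partial x_1$
(so that $\nabla^2\psi = -\omega$):

$$\nabla^2 \psi = -\omega,$$
$$\partial_t\omega + u_i\partial_i \omega =
  Sc\,\nabla^2\omega - Sc\,Ra\,\partial_{x_1} n
  + Le\,Sc\,Ra_T\,\partial_{x_1}\theta - Le\,Sc\,Ra_n\,\partial_{x_1}\phi,$$
$$\partial_t n = -\partial_i\big[(u_i + Pe\,\gamma_2) n\big] + \nabla^2 n,$$
$$\partial_t\theta + u_i\partial_i\theta = Le\,\nabla^2\theta
  + r_\rho\delta_{Bm}\,\partial_i\phi\,\partial_i\theta
  + r_\rho\delta_{Tm}\,(\partial_i\theta)^2,$$
$$\partial_t\phi + \partial_i\big[(u_i + Pe_n\,\gamma_2)\phi\big] =
  \delta_{Bm}\nabla^2\phi + \delta_{Tm}\nabla^2\theta,$$

where $\gamma_2$ is the vertical unit vector.  The three buoyancy terms in
the vorticity equation are, in order, the weight excess of the swimmers
(bioconvection Rayleigh number $Ra$), thermal buoyancy ($Ra_T$) and
nanoparticle buoyancy ($Ra_n$); $Sc$ and $Le$ are Schmidt and Lewis
numbers, $Pe$ the dimensionless upward swimming speed, $Pe_n$ the
nanoparticle drift speed, $\delta_{Bm}$ and $\delta_{Tm}$ the Brownian and
thermophoretic transport parameters and $r_\rho$ a heat-capacity ratio.
`dimensionless_groups()` evaluates all ten groups from SI quantities.

Boundary conditions: no-slip walls ($\psi = 0$ and zero tangential slip,
closed through the wall vorticity); Dirichlet wall temperatures, $\theta =
0$ everywhere except on configurable heated segments ([source_spec()])
where $\theta = 1$; no flux of microorganisms through any wall
($\partial n/\partial x_1 = 0$ on the side walls, $Pe\,n - \partial
n/\partial x_2 = 0$ at top and bottom, the balance of upward swimming
against diffusion); and a Robin balance for the nanoparticles,
$\delta_{Bm}\partial\phi/\partial x_2 + \delta_{Tm}\partial\theta/\partial
x_2 - Pe_n\phi = 0$ at the horizontal walls.

### The closure of the nanoparticle equation

The horizontal-wall Robin balance above is exactly the statement that the
*total* vertical nanoparticle flux
$Pe_n\phi - \delta_{Bm}\partial_{x_2}\phi - \delta_{Tm}\partial_{x_2}\theta$
vanishes at the wall **provided** the interior transport carries the
vertical drift $Pe_n\gamma_2$.  Without that drift (and with plain
$\partial\phi/\partial x_1 = 0$ side walls) the wall balances pump mass:
$\mathrm{d}/\mathrm{d}t\int\phi\,\mathrm{d}A =
Pe_n\oint(\phi_{top}-\phi_{bot})$ plus a thermophoretic side-wall term
$\delta_{Tm}\partial\theta/\partial x_1$ wherever a heated segment meets a
side wall.  Both residues are structural, not numerical: under them the
$\phi$ problem has **no steady state** — the field level slides
indefinitely while the flow stays quasi-steady.  The package therefore
defaults to the conservative closure (`phi_zero_net_flux = TRUE`): the
$Pe_n$ drift is part of the $\phi$ transport, and the side walls impose the
matching balance
$\delta_{Bm}\partial\phi/\partial x_1 + \delta_{Tm}\partial\theta/\partial
x_1 = 0$.  Total $\phi$ is then conserved to rounding error and steady
states exist.  The literal non-conservative form remains available
(`phi_zero_net_flux = FALSE`) for studying the draining behaviour itself.

A consequence worth stating plainly: with any conservative closure the
cavity mean of $\phi$ is fixed by the initial profile
($\overline{\phi_b} = (1+\delta_{Bm})/2$), so $\phi_{max} \ge
\overline{\phi_b}$ at all times.  Reported $\phi_{max}$ values below the
mean of the initial state can only be produced by mass-draining closures
and then depend on when the run is stopped.

Similarly, the microorganism wall balance is used without the extra
$Pe_n\,n$ term (toggle `micro_bc_includes_pen`): only then is the
exponential rest profile
$n_b(x_2) = \bar N\,Pe\,e^{Pe x_2}/(e^{Pe}-1)$ an exact stationary state of
the transport equation, which the test suite verifies.  The initial
$\phi_b(x_2) = (1-\delta_{Bm})x_2 + \delta_{Bm}$ is *not* stationary under
any of the closures above; it is an initial condition that relaxes (mass-
conservingly, by default) toward the exponential no-flux profile.

## Discretisation

* Uniform node-centred grid ([make_grid()]), second-order centred interior
  differences throughout.
* **ADI time stepping**: each step splits into an $x_1$-implicit and an
  $x_2$-implicit half-step (Peaceman–Rachford style), each solving one
  tridiagonal system per grid line (Thomas algorithm).  Advection is
  discretised in conservative flux form and treated implicitly along the
  sweep direction; the buoyancy, Brownian and thermophoretic coupling
  sources are evaluated explicitly at the old time level, which keeps every
  line system linear and tridiagonal.
* **Species transport in finite-volume form**: for $n$ and $\phi$ the
  sweeps assemble interface fluxes on cells of width $h$ ($h/2$ at walls)
  and impose the wall flux balances *as the wall flux itself*.  This makes
  $\int n\,\mathrm{d}A$ and $\int\phi\,\mathrm{d}A$ conserved to rounding
  error — the property the long quasi-steady runs depend on — at the price
  of first-order accuracy in the wall cells.  The generic
  [adi_advance_scalar()] operator retains the node-centred form with a
  user-supplied boundary handler.
* **Stream function**: $\nabla^2\psi = -\omega$ is solved directly each
  step by a sine expansion along $x_2$ plus tridiagonal solves along $x_1$;
  the discrete residual is at machine precision, comfortably inside the
  $10^{-8}$ residual contract of [solve_poisson_stream()].
* **Wall vorticity**: Thom's first-order closure
  $\omega_w = -2\psi_{adj}/h^2$, the standard choice for
  stream-function–vorticity codes with no-slip walls.
* **Stability**: the tridiagonal assembly verifies diagonal dominance and
  raises an unstable-step error when advection is too strong for the step;
  [run_to_convergence()] reacts by halving `dt` (up to four times) and
  restarting.  Implicit diffusion is stable far beyond the explicit limit
  (verified at $100\times$).

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `Ra` | 1900 | bioconvective buoyancy; plume-forming regime |
| `RaT` | 1708 | thermal buoyancy at the classical convection threshold |
| `Ran` | 0.01 | nanoparticle buoyancy (swept in studies) |
| `Sc`, `Le`, `Pe` | 1 | stabilising unit choices |
| `Pen` | 0.1 | nanoparticle drift; diffusion-dominated, no sedimentation |
| `delta_Bm` | 0.1 | Brownian diffusivity ratio (studies use 0.1–1.9) |
| `delta_Tm` | 0.1 | thermophoretic parameter (studies use 0.01–0.1) |
| `r_rho` | 2.5 | heat-capacity ratio in the energy coupling |
| `A` | 5 | cavity aspect ratio |
| `dt` | 1e-4 | dimensionless time step (auto-halved on instability) |
| `epsilon` | 1e-6 | stopping rule: max per-step change over all fields |

Thermal-source extents are configurable; the bundled defaults are the
bottom-left segment $x_1/A\in[0, 0.1]$ (case 1) and the left-wall segment
$x_2\in[0.4, 0.6]$ (case 2).

A scaling remark that shapes every sweep: with $Ra = 1900$ acting on
$O(1)$ gradients of $n$, the nanoparticle buoyancy $Ra_n\,\partial\phi /
\partial x_1$ at $Ra_n \le 0.14$ is four to five orders of magnitude
weaker.  In this solver the flow amplitude therefore responds only weakly
to $Ra_n$ in the swept range, and onset estimates from the $|\psi|_{max}$
curve ride on that weak response.

## Stopping rule and quasi-steady horizons

The stopping rule is the successive-difference criterion: stop when
$\max_{f,i,j}|f^{m+1}_{i,j} - f^{m}_{i,j}| \le \varepsilon$ over all five
fields.  Because $\omega$ reaches $O(10^2)$ at the walls, this absolute
criterion is demanding; it genuinely fires for moderately forced steady
configurations (several are exercised in the tests), but at the strongly
forced study conditions ($Ra = 1900$, $\delta_{Bm} = 1.6$) the long-time
attractor is weakly unsteady and the criterion does not fire at any
affordable step size.  Such runs are advanced to a fixed dimensionless-time
horizon and their `converged = FALSE` result carries the quasi-steady
diagnostics (the $|\psi|_{max}$ drift is $\sim 0.1\%$ per time unit at
$t\approx 12$).  The bundled analysis script uses cold-start horizons of $t = 8$ for
production-mesh numbers (a further $t = 5$ after the warm restart at the
second probe), and warm-started sweep points of $t = 0.8$ after a $t = 4$
burn-in; the in-suite mesh comparisons use shorter equal horizons within
each compared pair.  Sweeps run on the 51×81 mesh, mesh-study-grade
numbers on the 101×81 mesh.

## What the defaults emulate — and what they do not

The default configuration represents a shallow, laterally extended water
layer in which bioconvection dominates, natural convection sits at its
threshold, and nanoparticles act as a weak buoyancy perturbation.  The
synthetic initial state is the analytic rest state: exponential swimmer
stratification, linear particle profile, quiescent flow.  Passing tests on
these conditions demonstrate internal consistency of the discretisation
(order, conservation, symmetry, stationarity) and reproducibility of the
solver's own dynamics; they cannot certify agreement with laboratory
suspensions, where polydispersity, three-dimensional rolls, temperature-
dependent swimming speeds and finite-Reynolds effects are all outside this
model.

## Known limitations

* Two-dimensional, single-phase Boussinesq-type model; no sedimentation
  beyond the $Pe_n$ drift, no thermotactic term in the swimming law (heat
  steers the swimmers only through the flow and their advection).
* First-order wall treatment (Thom closure, half-cell species fluxes).
* The explicit treatment of the buoyancy and coupling sources caps the
  usable `dt` well below the implicit-diffusion limit at high Rayleigh
  numbers.
* At strongly forced conditions, reported extrema are quasi-steady
  horizon values, not fixed-point values (see above); the cell-count
  diagnostic [count_convection_cells()] is threshold-based (5% of
  $|\psi|_{max}$ by default) and counts only rolls above that relative
  strength.

## A worked micro-example

```{r, eval = FALSE}
library(biocavity)
cfg <- case_config(
  params  = sim_params(Ra = 200, RaT = 200, Ran = 0.02,
                       delta_Bm = 1, delta_Tm = 0.05, Pe = 0.5),
  grid    = make_grid(31, 21, A = 5),
  sources = list(source_spec("bottom", 0.3, 0.5)),
  dt = 1e-3, max_iters = 40000)
rr <- run_to_convergence(cfg)
rr
global_extrema(rr$state)
count_convection_cells(rr$state$psi, cfg$grid)
```
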