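## simulation: thermal-source boundary map, full coupled time step, and
## iteration to the converged steady state.

#' Configuration of one simulation case
#'
#' @param params a [sim_params()] object.
#' @param grid a [make_grid()] grid (default 101 x 81, the production mesh).
#' @param sources list of [source_spec()] thermal sources; the default is the
#'   bottom-left source covering the first tenth of the bottom wall.
#' @param dt time step (dimensionless; default 1e-4).  On numerical
#'   divergence [run_to_convergence()] retries with `dt` halved, up to four
#'   times.
#' @param epsilon convergence tolerance: iteration stops when the largest
#'   per-step change over all five fields and all nodes drops to `epsilon`
#'   or below (default 1e-6).
#' @param max_iters iteration cap.
#' @param seed integer seed for the optional initial perturbation (the
#'   solver itself is deterministic).
#' @param perturbation_amplitude amplitude of an optional infinitesimal
#'   random vorticity perturbation added to the initial state to break exact
#'   symmetry in supercritical regimes; 0 (off) by default.
#' @return An object of class `case_config`.
#' @export
case_config <- function(params = sim_params(),
                        grid = make_grid(101, 81, A = params$A),
                        sources = list(source_spec("bottom", 0, 0.1)),
                        dt = 1e-4, epsilon = 1e-6, max_iters = 200000L,
                        seed = 1L, perturbation_amplitude = 0) {
  stopifnot(inherits(params, "sim_params"), inherits(grid, "bc_grid"))
  if (!is.list(sources) || !all(vapply(sources, inherits, TRUE, "source_spec")))
    stop("case_config: 'sources' must be a list of source_spec objects",
         call. = FALSE)
  if (dt <= 0) stop("case_config: dt must be > 0", call. = FALSE)
  if (epsilon <= 0) stop("case_config: epsilon must be > 0", call. = FALSE)
  if (max_iters < 1) stop("case_config: max_iters must be >= 1", call. = FALSE)
  if (grid$A != params$A)
    stop("case_config: grid aspect ratio does not match params$A", call. = FALSE)
  structure(list(params = params, grid = grid, sources = sources, dt = dt,
                 epsilon = epsilon, max_iters = as.integer(max_iters),
                 seed = as.integer(seed),
                 perturbation_amplitude = perturbation_amplitude),
            class = "case_config")
}

#' Build the Dirichlet wall-temperature map
#'
#' Every boundary node gets \eqn{\theta = 0} unless it falls inside a
#' thermal-source segment (endpoints included after rounding to the nearest
#' node), where it gets the source's `theta_value`.  Overlapping segments on
#' a wall are applied in order, so later sources win on overlap.  At the
#' corners the bottom/top values take precedence over the side walls.
#'
#' @param sources list of [source_spec()] objects.
#' @param g a [make_grid()] grid.
#' @return A list of numeric vectors `bottom`, `top` (length `Nx1`) and
#'   `left`, `right` (length `Nx2`).
#' @export
build_theta_boundary <- function(sources, g) {
  stopifnot(inherits(g, "bc_grid"))
  tb <- list(bottom = numeric(g$Nx1), top = numeric(g$Nx1),
             left = numeric(g$Nx2), right = numeric(g$Nx2))
  for (s in sources) {
    if (!inherits(s, "source_spec"))
      stop("build_theta_boundary: invalid source", call. = FALSE)
    n <- if (s$wall %in% c("bottom", "top")) g$Nx1 else g$Nx2
    i0 <- round(s$start_frac * (n - 1)) + 1
    i1 <- round(s$end_frac * (n - 1)) + 1
    tb[[s$wall]][i0:i1] <- s$theta_value
  }
  tb
}

#' Advance the coupled system by one full time step
#'
#' One ADI step of the five-field system: (1) velocities from \eqn{\psi};
#' (2) vorticity advanced with diffusivity `Sc` and the three buoyancy
#' gradient sources \eqn{-Sc\,Ra\,\partial n/\partial x_1 + Le\,Sc\,Ra_T\,
#' \partial\theta/\partial x_1 - Le\,Sc\,Ra_n\,\partial\phi/\partial x_1};
#' (3) \eqn{\psi} re-solved from the Poisson equation; (4) Thom wall
#' vorticity; (5) microorganisms advanced with upward swimming speed `Pe`;
#' (6) temperature with diffusivity `Le` and explicit Brownian /
#' thermophoretic coupling sources; (7) nanoparticles with diffusivity
#' \eqn{\delta_{Bm}} and explicit \eqn{\delta_{Tm}\nabla^2\theta} source;
#' (8) boundary conditions re-applied throughout.
#'
#' @param state a `field_state` on `cfg$grid`.
#' @param cfg a [case_config()].
#' @param theta_boundary optional precomputed [build_theta_boundary()] map.
#' @return The advanced `field_state` (time incremented by `cfg$dt`).
#' @export
time_step <- function(state, cfg, theta_boundary = NULL) {
  stopifnot(inherits(cfg, "case_config"))
  tb <- theta_boundary %||% build_theta_boundary(cfg$sources, cfg$grid)
  out <- cpp_time_step(unclass(state), unclass(cfg$params), tb, cfg$dt,
                       cfg$grid$dx1, cfg$grid$dx2)
  new_field_state(out$psi, out$omega, out$n, out$theta, out$phi, out$t)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Iterate to the converged (steady) state
#'
#' Repeats [time_step()] until the largest per-step change over all five
#' fields and all grid nodes is at most `cfg$epsilon`, or `cfg$max_iters` is
#' reached.  If a step diverges (non-finite values or an unstable ADI
#' sweep), the run restarts from the initial state with `dt` halved, up to
#' four halvings.  Runs are deterministic given `cfg`.
#'
#' @param cfg a [case_config()].
#' @param initial optional initial `field_state`; defaults to
#'   [init_basic_state()] (with the optional seeded vorticity perturbation
#'   when `cfg$perturbation_amplitude > 0`).
#' @return An object of class `run_result`: the final `state`, `converged`
#'   flag, `iterations` count, `residual_history` (max per-step field change
#'   per iteration), `dt_used`, and a `diagnostics` list (`psi_max`,
#'   `phi_max`, `n_max`, `theta_max`, `cells`).
#' @export
run_to_convergence <- function(cfg, initial = NULL) {
  stopifnot(inherits(cfg, "case_config"))
  tb <- build_theta_boundary(cfg$sources, cfg$grid)
  if (is.null(initial)) {
    initial <- init_basic_state(cfg$params, cfg$grid)
    if (cfg$perturbation_amplitude > 0) {
      set.seed(cfg$seed)
      pert <- matrix(runif(cfg$grid$Nx1 * cfg$grid$Nx2, -1, 1),
                     cfg$grid$Nx1, cfg$grid$Nx2)
      pert[c(1, cfg$grid$Nx1), ] <- 0
      pert[, c(1, cfg$grid$Nx2)] <- 0
      initial$omega <- initial$omega + cfg$perturbation_amplitude * pert
    }
    # put the generated state's wall nodes on the discrete flux balances; a
    # user-supplied (e.g. warm-start) state is taken as-is
    initial <- apply_flux_bcs(initial, cfg$params, cfg$grid, tb)
  }

  dt <- cfg$dt
  for (attempt in 1:5) {
    res <- cpp_run(unclass(initial), unclass(cfg$params), tb, dt,
                   cfg$grid$dx1, cfg$grid$dx2, cfg$epsilon, cfg$max_iters)
    if (!res$diverged) break
    if (attempt == 5)
      stop("run_to_convergence: numerical divergence persists after 4 dt ",
           "halvings (", res$divergence_reason, ")", call. = FALSE)
    dt <- dt / 2
  }

  state <- new_field_state(res$psi, res$omega, res$n, res$theta, res$phi, res$t)
  ext <- global_extrema(state)
  structure(list(
    state = state,
    converged = res$converged,
    iterations = res$iterations,
    residual_history = res$residual_history,
    dt_used = dt,
    diagnostics = c(ext, list(
      cells = count_convection_cells(state$psi, cfg$grid)))),
    class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result> ", if (x$converged) "converged" else "NOT converged",
      " after ", x$iterations, " iterations (dt = ", format(x$dt_used), ")\n",
      "  |psi|max = ", format(x$diagnostics$psi_max),
      ", phi_max = ", format(x$diagnostics$phi_max),
      ", cells = ", x$diagnostics$cells, "\n", sep = "")
  invisible(x)
}
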