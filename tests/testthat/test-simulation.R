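small_case <- function(..., Nx1 = 31, Nx2 = 21,
                       sources = list(source_spec("bottom", 0, 0.1)),
                       dt = 1e-4, max_iters = 1000) {
  p <- sim_params(...)
  case_config(params = p, grid = make_grid(Nx1, Nx2, A = p$A),
              sources = sources, dt = dt, max_iters = max_iters)
}

test_that("wall-temperature map places sources on the requested nodes", {
  g <- make_grid(101, 81, A = 5)
  tb <- build_theta_boundary(list(), g)
  expect_true(all(unlist(tb) == 0))

  # bottom-left source over the first tenth of the bottom wall: 11 nodes
  tb <- build_theta_boundary(list(source_spec("bottom", 0, 0.1)), g)
  expect_equal(sum(tb$bottom == 1), 11)
  expect_equal(tb$bottom[1:11], rep(1, 11))
  expect_true(all(tb$top == 0) && all(tb$left == 0) && all(tb$right == 0))

  # left-wall segment only heats the x1 = 0 column
  tb <- build_theta_boundary(list(source_spec("left", 0.4, 0.6)), g)
  expect_true(all(tb$bottom == 0) && all(tb$right == 0))
  expect_equal(which(tb$left == 1), 33:49)  # x2 in [0.4, 0.6] rounded to nodes

  # overlapping segments merge; invalid extents rejected
  tb <- build_theta_boundary(list(source_spec("bottom", 0, 0.2),
                                  source_spec("bottom", 0.1, 0.3)), g)
  expect_equal(sum(tb$bottom == 1), 31)
  expect_error(source_spec("bottom", 0.5, 0.4), "source")
  expect_error(source_spec("bottom", -0.1, 0.4), "source")
})

test_that("zero forcing keeps the rest state at rest and n, phi on their
           basic profiles", {
  cfg <- small_case(Ra = 0, RaT = 0, Ran = 0, sources = list())
  st <- init_basic_state(cfg$params, cfg$grid)
  tb <- build_theta_boundary(list(), cfg$grid)
  s <- st
  for (k in 1:200) s <- time_step(s, cfg, tb)
  expect_equal(max(abs(s$psi)), 0)
  expect_equal(max(abs(s$omega)), 0)
  expect_lt(max(abs(s$theta)), 1e-14)
  # n relaxes only by the O(h^2) analytic-vs-discrete profile difference;
  # the linear phi profile is an initial condition, not a rest state, so it
  # relaxes toward the exponential no-flux profile while conserving mass
  expect_lt(max(abs(s$n - st$n)), 2e-3)
  expect_lt(max(abs(s$phi - st$phi)), 0.2)
  expect_lt(abs(trap_int(s$phi, cfg$grid) - trap_int(st$phi, cfg$grid)), 1e-10)
})

test_that("one coupled step agrees with a monolithic explicit-Euler oracle
           to O(dt^2)", {
  cfg <- small_case(Nx1 = 7, Nx2 = 7, A = 1, Ra = 50, RaT = 40, Ran = 0.05,
                    delta_Bm = 0.4, delta_Tm = 0.1,
                    sources = list(source_spec("bottom", 0.2, 0.6)))
  tb <- build_theta_boundary(cfg$sources, cfg$grid)
  st <- init_basic_state(cfg$params, cfg$grid)
  st <- apply_flux_bcs(st, cfg$params, cfg$grid, tb)
  # give the oracle a non-trivial flow state to differentiate on
  for (k in 1:50) st <- time_step(st, cfg, tb)

  err <- vapply(c(1e-3, 5e-4, 2.5e-4), function(dt) {
    c2 <- cfg; c2$dt <- dt
    max_abs_diff_state(time_step(st, c2, tb), euler_coupled_step(st, c2, tb))
  }, numeric(1))
  expect_gt(log2(err[1] / err[2]), 1.8)
  expect_gt(log2(err[2] / err[3]), 1.8)
})

test_that("a bottom heat source spins up vorticity of opposite signs on its
           two sides", {
  # centred source, thermal buoyancy only
  cfg <- small_case(Ra = 0, RaT = 500, Ran = 0, Nx1 = 51, Nx2 = 21,
                    sources = list(source_spec("bottom", 0.45, 0.55)))
  tb <- build_theta_boundary(cfg$sources, cfg$grid)
  st <- init_basic_state(cfg$params, cfg$grid)
  st <- apply_flux_bcs(st, cfg$params, cfg$grid, tb)
  for (k in 1:5) st <- time_step(st, cfg, tb)
  mid <- 26
  left <- st$omega[mid - 5, 3]
  right <- st$omega[mid + 5, 3]
  # -dtheta/dx1 changes sign across the source midpoint
  expect_gt(left, 0)
  expect_lt(right, 0)
  expect_equal(left, -right, tolerance = 1e-6)
})

test_that("run_to_convergence: fixed point recognised in one iteration,
           determinism, and dt halving on unstable steps", {
  # uniform stationary species (Pe = Pen = 0, dBm = 1) + a weak thermal
  # source: the flow equilibrates quickly and the criterion genuinely fires
  cfg <- small_case(Ra = 0, RaT = 200, Ran = 0, Pe = 0, Pen = 0,
                    delta_Bm = 1, delta_Tm = 0.05,
                    sources = list(source_spec("bottom", 0.4, 0.6)),
                    max_iters = 20000, dt = 1e-3)
  r1 <- run_to_convergence(cfg)
  expect_true(r1$converged)
  # re-feeding a converged state converges immediately
  r2 <- run_to_convergence(cfg, initial = r1$state)
  expect_equal(r2$iterations, 1)
  expect_true(r2$converged)
  # determinism: bit-identical repeat
  r3 <- run_to_convergence(cfg)
  expect_identical(r3$state, r1$state)
  expect_identical(r3$residual_history, r1$residual_history)
  # residual history nonincreasing over its tail
  tail10 <- utils::tail(r1$residual_history, max(2, r1$iterations %/% 10))
  expect_true(all(diff(tail10) <= 1e-12))

  # an advection-dominated step triggers automatic dt halving
  cfg2 <- small_case(RaT = 800, Ra = 0, Ran = 0, Pe = 0, Pen = 0,
                     delta_Bm = 1, dt = 0.02, max_iters = 300,
                     sources = list(source_spec("bottom", 0.3, 0.7)))
  rr <- run_to_convergence(cfg2)
  expect_lt(rr$dt_used, 0.02)
  expect_true(all(is.finite(rr$state$omega)))
})

test_that("microorganism and nanoparticle totals are conserved through a
           convecting run", {
  # moderately forced case away from the side walls, conservative closure
  cfg <- small_case(Ra = 300, RaT = 300, Ran = 0.02, Nx1 = 41, Nx2 = 31,
                    delta_Bm = 0.2, delta_Tm = 0.1,
                    sources = list(source_spec("bottom", 0.3, 0.5)),
                    max_iters = 4000)
  st0 <- init_basic_state(cfg$params, cfg$grid)
  tb <- build_theta_boundary(cfg$sources, cfg$grid)
  st0 <- apply_flux_bcs(st0, cfg$params, cfg$grid, tb)
  rr <- run_to_convergence(cfg, initial = st0)
  g <- cfg$grid
  expect_gt(max(abs(rr$state$psi)), 1e-3)  # the flow actually developed
  expect_lt(abs(trap_int(rr$state$n, g) - trap_int(st0$n, g)) /
            trap_int(st0$n, g), 1e-10)
  expect_lt(abs(trap_int(rr$state$phi, g) - trap_int(st0$phi, g)) /
            abs(trap_int(st0$phi, g)), 1e-10)
})

test_that("the exponential rest profile is stationary at zero forcing", {
  # fine vertical grid so the discrete and analytic profiles coincide
  p <- sim_params(Ra = 0, RaT = 0, Ran = 0, A = 1, Pe = 1)
  g <- make_grid(5, 321, A = 1)
  cfg <- case_config(params = p, grid = g, sources = list(), dt = 1e-4,
                     max_iters = 1000)
  st0 <- init_basic_state(p, g)
  tb <- build_theta_boundary(list(), g)
  st1 <- apply_flux_bcs(st0, p, g, tb)  # wall nodes on the discrete balance
  st <- st1
  for (k in 1:1000) st <- time_step(st, cfg, tb)
  expect_lt(max(abs(st$n - st0$n)), 1e-6)
  # phi has no stationary linear profile; its total is still conserved
  expect_lt(abs(trap_int(st$phi, g) - trap_int(st1$phi, g)), 1e-10)
})

test_that("a centred bottom source yields mirror-symmetric temperature and
           antisymmetric flow at convergence", {
  cfg <- small_case(Ra = 100, RaT = 200, Ran = 0.01, Nx1 = 51, Nx2 = 21,
                    delta_Bm = 1, delta_Tm = 0.05, dt = 1e-3,
                    sources = list(source_spec("bottom", 0.4, 0.6)),
                    max_iters = 60000)
  rr <- run_to_convergence(cfg)
  expect_true(rr$converged)
  th <- rr$state$theta; ps <- rr$state$psi
  flip <- function(m) m[nrow(m):1, ]
  expect_lt(max(abs(th - flip(th))), 1e-6)
  expect_lt(max(abs(ps + flip(ps))), 1e-6)
})
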