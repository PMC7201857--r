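test_that("virus-free growth matches the exponential closed form", {
  p <- vd_params(beta = 0, v0 = 0)
  res <- run_phase1(p, fast_settings(t_end = 24))
  fx <- res$trajectory$fx
  expect_equal(fx[1], 1)
  expect_equal(fx[length(fx)], exp(p$r1 * 24), tolerance = 1e-6)
  # the field stays spatially uniform
  final <- res$states[[length(res$states)]]
  expect_lt(diff(range(final$x)) / mean(final$x), 1e-12)
})

test_that("the zero-diffusion limit matches an independent adaptive ODE solve", {
  p <- vd_params(D1 = 0, D2 = 0)
  res <- integrate_model(
    initial_state(p, tiny_grid(11)),
    p, tiny_grid(11), fast_settings(t_end = 240, n_nodes = 11),
    model = "phase1", v_inner = "noflux"
  )
  ode_rhs <- function(t, s, q) {
    with(as.list(c(s, q)), {
      list(c(
        r1 * x - beta * x * v,
        beta * x * v - delta * y,
        b * delta * y - kappa * beta * x * v - alpha * v
      ))
    })
  }
  ref <- deSolve::ode(
    c(x = p$x0, y = 0, v = p$v0), res$trajectory$time_h, ode_rhs,
    c(
      r1 = p$r1, beta = p$beta, delta = p$delta, b = p$b,
      kappa = p$kappa, alpha = p$alpha
    ),
    rtol = 1e-10, atol = 1e-6
  )
  node <- 6 # all nodes identical; compare mid-domain
  xs <- vapply(res$states, function(s) s$x[node], 0)
  scale <- max(abs(ref[, "x"]))
  expect_lt(max(abs(xs - ref[, "x"])) / scale, 1e-4)
  vs <- vapply(res$states, function(s) s$v[node], 0)
  expect_lt(max(abs(vs - ref[, "v"])) / max(abs(ref[, "v"])), 1e-4)
})

test_that("long integration reaches the discrete virus steady state", {
  # x = y = 0 decouples the virus equation: D2 lap(v) = alpha v with the wall
  # clamped at v0. Oracle: direct linear solve of the same discrete operator.
  p <- vd_params()
  n <- 41
  g <- radial_grid(p, n_nodes = n)
  init <- field_state(0,
    x = rep(0, n), y = rep(0, n), v = c(p$v0, rep(0, n - 1))
  )
  res <- integrate_model(
    init, p, g, solver_settings(dt = 1, n_nodes = n, t_end = 2400,
      snapshot_every = 100
    ),
    model = "phase1"
  )
  v_end <- res$states[[length(res$states)]]$v

  # assemble the clamped operator column by column
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n)
    e[j] <- 1
    A[, j] <- p$D2 * radial_laplacian(e, g, inner_bc = bc_dirichlet(0)) -
      p$alpha * e
  }
  A[1, ] <- 0
  A[1, 1] <- 1
  rhs <- numeric(n)
  rhs[1] <- p$v0
  # the clamp contributes a constant source to the neighbouring row
  offset <- p$D2 * radial_laplacian(numeric(n), g, inner_bc = bc_dirichlet(p$v0))
  rhs <- rhs - c(0, offset[-1])
  v_star <- solve(A, rhs)
  expect_equal(v_end, v_star, tolerance = 1e-6)
})

test_that("with all reactions off and sealed boundaries mass is conserved", {
  p <- vd_params(r1 = 0, beta = 0, delta = 0, alpha = 0, b = 0, v0 = 0)
  n <- 61
  g <- radial_grid(p, n_nodes = n)
  init <- field_state(0,
    x = p$x0 * (1 + radial_bump(g)), y = radial_bump(g, 1e4),
    v = radial_bump(g, 1e6, width = 0.15)
  )
  res <- integrate_model(
    init, p, g, solver_settings(dt = 0.5, n_nodes = n, t_end = 100),
    model = "phase1", v_inner = "noflux"
  )
  for (species in c("x", "y", "v")) {
    masses <- vapply(
      res$states,
      function(s) normalized_mass(s[[species]], g, 1), 0
    )
    expect_lt(max(abs(masses / masses[1] - 1)), 1e-6)
  }
})

test_that("the scheme converges at second order in dr on a smooth problem", {
  # smooth resolvable problem: enhanced diffusivities, reactions on, 24 h
  base <- vd_params(D1 = 1e-5, D2 = 1e-4)
  fx_end <- vapply(c(25, 49, 97), function(n) {
    g <- radial_grid(base, n_nodes = n)
    init <- field_state(0,
      x = rep(base$x0, n), y = numeric(n),
      v = base$v0 * radial_bump(g)
    )
    res <- integrate_model(
      init, base, g,
      solver_settings(dt = 0.005, n_nodes = n, t_end = 24),
      model = "phase1", v_inner = "noflux",
      M0 = base$x0 * annulus_area(base$r_b, base$BVF)
    )
    res$trajectory$fx[nrow(res$trajectory)]
  }, 0)
  order <- log2(abs(fx_end[1] - fx_end[2]) / abs(fx_end[2] - fx_end[3]))
  expect_gt(order, 1.8)
})

test_that("halving the time step leaves the trajectory unchanged to 0.1%", {
  p <- vd_params()
  f1 <- run_phase1(p, fast_settings(t_end = 240, dt = 0.2))
  f2 <- run_phase1(p, fast_settings(t_end = 240, dt = 0.1))
  expect_lt(
    abs(tail(f1$trajectory$fx, 1) / tail(f2$trajectory$fx, 1) - 1),
    0.001
  )
})

test_that("repeated runs are bit-identical and stability guards trip", {
  p <- vd_params()
  a <- run_phase1(p, fast_settings(t_end = 12))
  b <- run_phase1(p, fast_settings(t_end = 12))
  expect_identical(a$trajectory, b$trajectory)
  expect_error(
    run_phase1(p, solver_settings(dt = 50, n_nodes = 191)),
    "stability bound"
  )
})

test_that("a two-phase run with radiation off continues phase 1 unchanged", {
  p <- vd_params(t_r = 48)
  set <- fast_settings(t_end = 120)
  two <- run_two_phase(p, set, radiation_schedule("off", t0 = 48))
  one <- run_phase1(p, set)
  tr2 <- two$trajectory[two$trajectory$phase == "radiovirotherapy", ]
  tr1 <- one$trajectory[one$trajectory$time_h >= 48, ]
  # same absolute mass trajectory, different normalization per segment
  expect_equal(tr2$mass, tr1$mass, tolerance = 1e-10)
  expect_equal(tr2$fx[1], 1, tolerance = 1e-12)
  # damaged cells stay identically zero without radiation
  expect_true(all(vapply(
    two$states[vapply(two$states, function(s) !is.null(s$u), TRUE)],
    function(s) all(s$u == 0), TRUE
  )))
})

test_that("phase II renormalizes by the viable mass at the handoff", {
  p <- vd_params(t_r = 24)
  set <- fast_settings(t_end = 48)
  two <- run_two_phase(p, set, radiation_schedule("constant", t0 = 24))
  expect_equal(unname(two$M0["phase2"]),
    radial_mass_for_test(two, t = 24),
    tolerance = 1e-12
  )
  expect_error(
    run_two_phase(vd_params(t_r = 100), fast_settings(t_end = 50)),
    "t_r must be smaller"
  )
  expect_error(
    run_two_phase(p, set, radiation_schedule("constant", t0 = 999)),
    "must equal"
  )
})
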