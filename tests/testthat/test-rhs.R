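test_that("uniform uninfected tissue grows at r1 with no other terms active", {
  p <- vd_params()
  g <- tiny_grid(31)
  s <- field_state(0, x = rep(p$x0, 31), y = rep(0, 31), v = rep(0, 31))
  d <- rhs_phase1(s, p, g, v_inner = "noflux")
  interior <- 2:30
  expect_equal(d$x[interior], rep(p$r1 * p$x0, 29)) # 0.02 * 0.5e6 = 1e4
  expect_equal(d$y[interior], rep(0, 29))
  expect_equal(d$v[interior], rep(0, 29))
})

test_that("with no uninfected cells only the linear y-terms survive", {
  p <- vd_params()
  g <- tiny_grid(31)
  y_star <- 3e4
  s <- field_state(0, x = rep(0, 31), y = rep(y_star, 31), v = rep(0, 31))
  d <- rhs_phase1(s, p, g, v_inner = "noflux")
  expect_equal(d$y, rep(-p$delta * y_star, 31))
  expect_equal(d$v[2:30], rep(p$b * p$delta * y_star, 29))
})

test_that("reaction terms reproduce hand-computed rates in the ODE limit", {
  p <- vd_params(D1 = 0, D2 = 0)
  g <- tiny_grid(31)
  s <- field_state(0, x = rep(1e6, 31), y = rep(0, 31), v = rep(1e6, 31))
  d <- rhs_phase1(s, p, g, v_inner = "noflux")
  # dx = r1*x - beta*x*v = 0.02e6 - 7e-10*1e12 = 2e4 - 7e2
  expect_equal(d$x, rep(2e4 - 7e2, 31))
  expect_equal(d$y, rep(7e2, 31))
  expect_equal(d$v, rep(-p$kappa * 7e2 - p$alpha * 1e6, 31))
})

test_that("radiation off reduces the phase-2 model to phase 1 exactly", {
  p <- vd_params()
  g <- tiny_grid(41)
  set.seed(7)
  s1 <- field_state(
    150,
    x = runif(41, 0, 1e6), y = runif(41, 0, 1e5), v = runif(41, 0, 1e7)
  )
  s2 <- field_state(150, s1$x, s1$y, s1$v, u = runif(41, 0, 1e4))
  off <- radiation_schedule("off", t0 = 120)
  d1 <- rhs_phase1(s1, p, g)
  d2 <- rhs_phase2(s2, p, g, off)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$v, d2$v)
  expect_equal(d2$u, -p$gamma * s2$u)
})

test_that("damaged cells equilibrate at R(a1*x + a2*y)/gamma under frozen fields", {
  p <- vd_params()
  g <- tiny_grid(11)
  x_bar <- 1e4
  y_bar <- 0
  R <- 2
  u_star <- R * (p$a1 * x_bar + p$a2 * y_bar) / p$gamma
  expect_equal(u_star, 2e4) # a1 = gamma = 0.01, R = 2
  # long integration of the u-equation alone
  u <- 0
  dt <- 0.1
  for (i in seq_len(20000)) {
    du <- function(u) p$a1 * R * x_bar + p$a2 * R * y_bar - p$gamma * u
    k1 <- du(u); k2 <- du(u + dt / 2 * k1)
    k3 <- du(u + dt / 2 * k2); k4 <- du(u + dt * k3)
    u <- u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(u, u_star, tolerance = 1e-8)
  # and the model's own du/dt vanishes there
  s <- field_state(
    200,
    x = rep(x_bar, 11), y = rep(y_bar, 11), v = rep(0, 11),
    u = rep(u_star, 11)
  )
  d <- rhs_phase2(s, p, g, radiation_schedule("constant", R_const = R, t0 = 120),
    v_inner = "noflux"
  )
  expect_equal(d$u, rep(0, 11), tolerance = 1e-12)
})

test_that("RHS evaluations are pure and diffusion vanishes on uniform fields", {
  for (k in 1:3) {
    p <- perturbed_params(k)
    g <- tiny_grid(31)
    s <- field_state(0,
      x = rep(p$x0, 31), y = rep(1e4, 31), v = rep(p$v0, 31)
    )
    d_a <- rhs_phase1(s, p, g, v_inner = "noflux")
    d_b <- rhs_phase1(s, p, g, v_inner = "noflux")
    expect_identical(d_a, d_b)
    # uniform fields: interior derivative has no diffusion contribution
    expect_equal(
      d_a$x[2:30],
      rep(p$r1 * p$x0 - p$beta * p$x0 * p$v0, 29),
      tolerance = 1e-12
    )
  }
})

test_that("phase mismatches in the state are rejected", {
  p <- vd_params()
  g <- tiny_grid(11)
  s_u <- field_state(0, rep(1, 11), rep(0, 11), rep(0, 11), u = rep(0, 11))
  s_nou <- field_state(0, rep(1, 11), rep(0, 11), rep(0, 11))
  expect_error(rhs_phase1(s_u, p, g), "no damaged-cell field")
  expect_error(
    rhs_phase2(s_nou, p, g, radiation_schedule("off", t0 = 0)),
    "requires a damaged-cell field"
  )
})
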