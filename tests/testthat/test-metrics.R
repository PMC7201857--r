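test_that("the annulus area follows pi*((r_b/BVF)^2 - r_b^2)", {
  expect_equal(annulus_area(0.01, 0.05), 0.0399 * pi) # ~0.125349 mm^2
  expect_equal(annulus_area(1, 0.5), 3 * pi)
  expect_equal(annulus_area(0.01, 0.999999), 0, tolerance = 1e-6)
  expect_error(annulus_area(0.01, 1.5), "BVF")
})

test_that("normalized mass is exact for uniform and 1/r fields", {
  g <- tiny_grid(37)
  V <- annulus_area(0.01, 0.05)
  x0 <- 0.5e6
  expect_equal(normalized_mass(rep(x0, 37), g, x0 * V), 1) # exact at t = 0
  expect_equal(normalized_mass(rep(0, 37), g, x0 * V), 0)
  # x = c/r makes the integrand constant: trapezoid is exact again
  c_ <- 123.4
  expect_equal(
    normalized_mass(c_ / g$r, g, x0 * V),
    2 * pi * c_ * (g$r_outer - g$r_inner) / (x0 * V)
  )
})

test_that("normalized mass is linear and monotone in the field", {
  g <- tiny_grid(41)
  f <- radial_bump(g, amplitude = 1e5)
  h <- rep(2e4, 41)
  M0 <- 1
  expect_equal(
    normalized_mass(3 * f + 0.5 * h, g, M0),
    3 * normalized_mass(f, g, M0) + 0.5 * normalized_mass(h, g, M0)
  )
  expect_gte(normalized_mass(f + h, g, M0), normalized_mass(f, g, M0))
  expect_error(normalized_mass(f, g, M0 = 0), "positive")
})

test_that("quadrature error for a smooth field shrinks at second order", {
  V <- annulus_area(0.01, 0.05)
  exact <- integrate(function(r) 2 * pi * r * exp(-((r - 0.1) / 0.05)^2),
    0.01, 0.2,
    rel.tol = 1e-12
  )$value
  errs <- vapply(c(25, 49, 97), function(n) {
    g <- tiny_grid(n)
    abs(normalized_mass(exp(-((g$r - 0.1) / 0.05)^2), g, 1) - exact)
  }, 0)
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 1.8))
})

test_that("trajectory summaries extract the right landmarks", {
  # build a synthetic result wrapping a known fx series
  make_res <- function(fx) {
    tt <- seq_along(fx) - 1
    structure(
      list(
        trajectory = tibble::tibble(
          time_h = tt, fx = fx, mass = fx, phase = "virotherapy"
        ),
        phase_boundary = NULL
      ),
      class = "vd_result"
    )
  }
  mono <- make_res(seq(1, 2, length.out = 100))
  s <- summarize_run(mono)
  expect_equal(s$t_peak_h, 99)
  expect_false(s$oscillatory)
  expect_false(s$eradicated)

  damped <- make_res(1 + exp(-(0:499) / 100) * cos((0:499) / 20))
  expect_true(summarize_run(damped)$oscillatory)

  # decline with sub-prominence jitter is not oscillatory
  set.seed(1)
  jittered <- make_res(seq(2, 0.5, length.out = 300) +
    runif(300, 0, 0.001))
  expect_false(summarize_run(jittered)$oscillatory)

  # deep monotone decline ending < 1% of start counts as eradication
  erad <- make_res(exp(-(0:199) / 30))
  expect_true(summarize_run(erad)$eradicated)

  expect_error(summarize_run(make_res(c(1, 0.5))), "too few")
})
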