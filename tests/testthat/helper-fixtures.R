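# Shared fixtures: small grids and cheap solver settings keep the unit tests
# fast; the full-resolution reference runs live in test-acceptance.R.

tiny_grid <- function(n = 21, r_b = 0.01, BVF = 0.05) {
  radial_grid(NULL, n_nodes = n, r_b = r_b, BVF = BVF)
}

fast_settings <- function(t_end = 24, n_nodes = 41, dt = 0.05) {
  solver_settings(dt = dt, n_nodes = n_nodes, snapshot_every = 1, t_end = t_end)
}

# deterministic family of perturbed parameter sets for property-style loops
perturbed_params <- function(k, seed = 421) {
  set.seed(seed + k)
  jitter <- function(x) x * exp(stats::runif(1, -0.3, 0.3))
  vd_params(
    r1 = jitter(0.02), beta = jitter(7e-10), delta = jitter(1 / 18),
    b = jitter(50), alpha = jitter(0.008), D1 = jitter(1e-8),
    D2 = jitter(5e-7)
  )
}

# 2*pi*integral(x r dr) of the stored uninfected field nearest time t
radial_mass_for_test <- function(result, t) {
  stored <- vapply(result$states, function(s) s$t, 0)
  s <- result$states[[which.min(abs(stored - t))]]
  g <- result$grid
  w <- rep(g$dr, g$n)
  w[c(1, g$n)] <- g$dr / 2
  2 * pi * sum(w * g$r * s$x)
}

# smooth radial bump used when a spatially structured field is needed
radial_bump <- function(grid, amplitude = 1, width = 0.25) {
  mid <- (grid$r_inner + grid$r_outer) / 2
  span <- grid$r_outer - grid$r_inner
  amplitude * exp(-((grid$r - mid) / (width * span))^2)
}
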