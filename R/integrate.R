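# Internal fast right-hand sides working on raw vectors. The exported
# rhs_phase1()/rhs_phase2() wrap these; the integrator calls them directly so
# the RK4 stage loop carries no object-construction overhead.
.rhs1 <- function(x, y, v, p, grid, v_dirichlet) {
  v_bc <- if (v_dirichlet) {
    v[1L] <- p$v0
    bc_dirichlet(p$v0)
  } else {
    bc_noflux()
  }
  infection <- p$beta * x * v
  list(
    x = p$D1 * radial_laplacian(x, grid) + p$r1 * x - infection,
    y = p$D1 * radial_laplacian(y, grid) + infection - p$delta * y,
    v = p$D2 * radial_laplacian(v, grid, inner_bc = v_bc) +
      p$b * p$delta * y - p$kappa * infection - p$alpha * v,
    u = NULL
  )
}

.rhs2 <- function(x, y, v, u, R_t, p, grid, v_dirichlet) {
  base <- .rhs1(x, y, v, p, grid, v_dirichlet)
  hit_x <- p$a1 * R_t * x
  hit_y <- p$a2 * R_t * y
  list(
    x = base$x - hit_x,
    y = base$y - hit_y,
    v = base$v,
    u = hit_x + hit_y - p$gamma * u
  )
}

#' Method-of-lines integration with classic RK4
#'
#' Advances a field state under either the virotherapy model
#' ([rhs_phase1()]) or the radiovirotherapy model ([rhs_phase2()]) with a
#' fixed-step classic four-stage Runge-Kutta scheme. The virus Dirichlet node
#' is clamped at every stage evaluation and re-clamped after each full step.
#' Snapshots (full fields plus the normalized viable mass f_x) are recorded at
#' the requested cadence, always including the initial and final times.
#'
#' The integrator refuses to start if `dt` violates the explicit-diffusion
#' comfort bound `dt <= 0.25 * dr^2 / max(D1, D2)`, and aborts with the step
#' index if any field becomes non-finite.
#'
#' @param initial A [field_state()] (with `u` for the phase-2 model).
#' @param params A [vd_params()] record.
#' @param grid A [radial_grid()] object.
#' @param settings A [solver_settings()] record (its `n_nodes` is ignored in
#'   favour of `grid`).
#' @param model `"phase1"` or `"phase2"`.
#' @param schedule A [radiation_schedule()] (required for `"phase2"`),
#'   defined over `[initial$t, initial$t + settings$t_end]`.
#' @param v_inner `"dirichlet"` (virus held at `v0` on the wall) or
#'   `"noflux"` (sealed wall; used by conservation and ODE-limit checks).
#' @param M0 Baseline mass for the f_x normalization; defaults to the mass of
#'   the initial uninfected field.
#' @param phase Label stored in the trajectory's `phase` column.
#'
#' @return A `vd_result`: trajectory tibble (`time_h`, `fx`, `mass`, `phase`),
#'   list of snapshot states, and the full provenance record (parameters,
#'   settings, grid, schedule, normalization).
#' @export
integrate_model <- function(initial, params, grid, settings,
                            model = c("phase1", "phase2"), schedule = NULL,
                            v_inner = c("dirichlet", "noflux"), M0 = NULL,
                            phase = NULL) {
  model <- match.arg(model)
  v_inner <- match.arg(v_inner)
  v_dirichlet <- v_inner == "dirichlet"
  if (model == "phase2") {
    if (is.null(schedule)) {
      stop("the radiovirotherapy model requires a radiation schedule",
        call. = FALSE
      )
    }
    if (is.null(initial$u)) {
      stop("the radiovirotherapy model requires a damaged-cell field u",
        call. = FALSE
      )
    }
  }
  dt_bound <- 0.25 * grid$dr^2 / max(params$D1, params$D2)
  if (settings$dt > dt_bound) {
    stop(sprintf(
      "dt = %g exceeds the explicit-diffusion stability bound %.4g for this grid",
      settings$dt, dt_bound
    ), call. = FALSE)
  }
  if (is.null(phase)) {
    phase <- if (model == "phase1") "virotherapy" else "radiovirotherapy"
  }

  n_steps <- ceiling(settings$t_end / settings$dt - 1e-9)
  dt <- settings$t_end / n_steps
  snap_steps <- max(1L, as.integer(round(settings$snapshot_every / dt)))

  x <- initial$x
  y <- initial$y
  v <- initial$v
  u <- initial$u
  t0 <- initial$t
  if (v_dirichlet) v[1L] <- params$v0
  if (is.null(M0)) M0 <- radial_mass(x, grid)

  eval_rhs <- if (model == "phase1") {
    function(x, y, v, u, t) .rhs1(x, y, v, params, grid, v_dirichlet)
  } else {
    function(x, y, v, u, t) {
      .rhs2(x, y, v, u, schedule_rate(schedule, t), params, grid, v_dirichlet)
    }
  }

  has_u <- !is.null(u)
  snap_idx <- unique(c(seq(0L, n_steps, by = snap_steps), n_steps))
  times <- numeric(length(snap_idx))
  fx <- numeric(length(snap_idx))
  states <- vector("list", length(snap_idx))
  k <- 1L
  record <- function(step) {
    times[k] <<- t0 + step * dt
    fx[k] <<- radial_mass(x, grid) / M0
    states[[k]] <<- structure(
      list(t = t0 + step * dt, x = x, y = y, v = v, u = u),
      class = "vd_state"
    )
    k <<- k + 1L
  }
  record(0L)

  for (step in seq_len(n_steps)) {
    t_n <- t0 + (step - 1L) * dt
    k1 <- eval_rhs(x, y, v, u, t_n)
    k2 <- eval_rhs(
      x + dt / 2 * k1$x, y + dt / 2 * k1$y, v + dt / 2 * k1$v,
      if (has_u) u + dt / 2 * k1$u, t_n + dt / 2
    )
    k3 <- eval_rhs(
      x + dt / 2 * k2$x, y + dt / 2 * k2$y, v + dt / 2 * k2$v,
      if (has_u) u + dt / 2 * k2$u, t_n + dt / 2
    )
    k4 <- eval_rhs(
      x + dt * k3$x, y + dt * k3$y, v + dt * k3$v,
      if (has_u) u + dt * k3$u, t_n + dt
    )
    x <- x + dt / 6 * (k1$x + 2 * k2$x + 2 * k3$x + k4$x)
    y <- y + dt / 6 * (k1$y + 2 * k2$y + 2 * k3$y + k4$y)
    v <- v + dt / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
    if (has_u) u <- u + dt / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
    if (v_dirichlet) v[1L] <- params$v0

    if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(v)) ||
      (has_u && !all(is.finite(u)))) {
      stop(sprintf(
        "instability detected: non-finite field values at step %d (t = %g h)",
        step, t0 + step * dt
      ), call. = FALSE)
    }
    if (step %% snap_steps == 0L || step == n_steps) record(step)
  }

  new_vd_result(
    trajectory = tibble::tibble(
      time_h = times, fx = fx, mass = fx * M0, phase = phase
    ),
    states = states,
    params = params, settings = settings, grid = grid,
    schedule = schedule, M0 = M0, phase_boundary = NULL
  )
}

new_vd_result <- function(trajectory, states, params, settings, grid,
                          schedule, M0, phase_boundary, v_init = NULL) {
  structure(
    list(
      trajectory = trajectory, states = states, params = params,
      settings = settings, grid = grid, schedule = schedule, M0 = M0,
      phase_boundary = phase_boundary, v_init = v_init
    ),
    class = "vd_result"
  )
}

#' @export
print.vd_result <- function(x, ...) {
  traj <- x$trajectory
  cat(sprintf(
    "<vd_result> %s run: %d snapshots over %g h on %d nodes\n",
    if (is.null(x$phase_boundary)) "virotherapy" else "two-phase",
    nrow(traj), max(traj$time_h), x$grid$n
  ))
  if (!is.null(x$phase_boundary)) {
    cat(sprintf("  radiotherapy starts at t_r = %g h\n", x$phase_boundary))
  }
  s <- summarize_run(x)
  cat(sprintf(
    "  f_x: min %.4g at %g h, final %.4g; peak at %g h%s%s\n",
    s$fx_min, s$t_min_h, s$fx_final, s$t_peak_h,
    if (s$oscillatory) "; oscillatory" else "",
    if (s$eradicated) "; eradicated" else ""
  ))
  invisible(x)
}
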