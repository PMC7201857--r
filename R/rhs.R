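#' Reaction-diffusion right-hand sides
#'
#' Time derivatives of the per-node fields for the two models, used by the
#' method-of-lines integrator.
#'
#' `rhs_phase1()` evaluates the virotherapy model:
#' \deqn{x_t = D_1 \nabla^2 x + r_1 x - \beta x v}
#' \deqn{y_t = D_1 \nabla^2 y + \beta x v - \delta y}
#' \deqn{v_t = D_2 \nabla^2 v + b \delta y - \kappa \beta x v - \alpha v}
#'
#' `rhs_phase2()` adds radiation at dose-rate R(t): `-a1 R x` on the
#' uninfected cells, `-a2 R y` on the infected cells, and a damaged-cell
#' compartment `u_t = a1 R x + a2 R y - gamma u` with no spatial transport
#' (damaged cells are assumed immobile and cleared in place).
#'
#' Boundary conditions: cells are no-flux at both the vessel wall and the
#' outer rim; virus is clamped to `v0` at the vessel wall (continuous
#' delivery) when `v_inner = "dirichlet"` and no-flux at the outer rim. The
#' clamp is applied to the incoming state before evaluation, so RK4 stage
#' states see the exact wall value.
#'
#' @param state A [field_state()] (without `u` for phase 1, with `u` for
#'   phase 2).
#' @param params A [vd_params()] record.
#' @param grid A [radial_grid()] object.
#' @param schedule A [radiation_schedule()], defined at `state$t`.
#' @param v_inner `"dirichlet"` (virus held at `v0` on the wall, the model's
#'   delivery mechanism) or `"noflux"` (sealed wall, used for conservation
#'   and ODE-limit checks).
#'
#' @return A named list of per-node derivative vectors: `x`, `y`, `v` (and
#'   `u` for phase 2), each in density per hour.
#' @examples
#' p <- vd_params()
#' g <- radial_grid(p, n_nodes = 21)
#' s <- initial_state(p, g)
#' d <- rhs_phase1(s, p, g)
#' d$x[10] / s$x[10] # interior growth rate r1 - beta*v0
#' @export
rhs_phase1 <- function(state, params, grid, v_inner = c("dirichlet", "noflux")) {
  v_inner <- match.arg(v_inner)
  check_rhs_inputs(state, params, grid, need_u = FALSE)
  x <- state$x
  y <- state$y
  v <- state$v
  v_bc <- if (v_inner == "dirichlet") {
    v[1L] <- params$v0
    bc_dirichlet(params$v0)
  } else {
    bc_noflux()
  }
  infection <- params$beta * x * v
  list(
    x = params$D1 * radial_laplacian(x, grid) + params$r1 * x - infection,
    y = params$D1 * radial_laplacian(y, grid) + infection - params$delta * y,
    v = params$D2 * radial_laplacian(v, grid, inner_bc = v_bc) +
      params$b * params$delta * y - params$kappa * infection - params$alpha * v
  )
}

#' @rdname rhs_phase1
#' @export
rhs_phase2 <- function(state, params, grid, schedule,
                       v_inner = c("dirichlet", "noflux")) {
  v_inner <- match.arg(v_inner)
  check_rhs_inputs(state, params, grid, need_u = TRUE)
  R_t <- schedule_rate(schedule, state$t)
  .rhs2(state$x, state$y, state$v, state$u, R_t, params, grid,
    v_dirichlet = v_inner == "dirichlet"
  )
}

check_rhs_inputs <- function(state, params, grid, need_u) {
  if (!inherits(state, "vd_state")) stop("state must be a vd_state", call. = FALSE)
  if (!inherits(params, "vd_params")) stop("params must be a vd_params", call. = FALSE)
  if (length(state$x) != grid$n) {
    stop("state fields do not match the grid size", call. = FALSE)
  }
  if (need_u && is.null(state$u)) {
    stop("the radiovirotherapy model requires a damaged-cell field u",
      call. = FALSE
    )
  }
  if (!need_u && !is.null(state$u)) {
    stop("the virotherapy model has no damaged-cell field u", call. = FALSE)
  }
  invisible(TRUE)
}
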