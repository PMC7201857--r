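#' Run the virotherapy model (Phase I)
#'
#' Builds the radial grid on `[r_b, r_b/BVF]`, sets the initial fields
#' (uninfected cells uniform at `x0`, no infected cells, virus per `v_init`),
#' and integrates the virotherapy model to `t_end`. The trajectory's f_x is
#' normalized by the initial viable mass `M0 = x0 * V`, so `fx[1] = 1`
#' exactly.
#'
#' @param params A [vd_params()] record.
#' @param settings A [solver_settings()] record.
#' @param v_init Initial virus profile, `"uniform"` or `"wall"`; see
#'   [initial_state()].
#' @return A `vd_result`.
#' @examples
#' \donttest{
#' res <- run_phase1(vd_params(), solver_settings(n_nodes = 41, t_end = 72))
#' tidy(res)
#' }
#' @export
run_phase1 <- function(params = vd_params(), settings = solver_settings(),
                       v_init = c("uniform", "wall")) {
  v_init <- match.arg(v_init)
  grid <- radial_grid(params, n_nodes = settings$n_nodes)
  init <- initial_state(params, grid, v_init = v_init)
  res <- integrate_model(init, params, grid, settings, model = "phase1")
  res$v_init <- v_init
  res
}

#' Run the two-phase (radiovirotherapy) protocol
#'
#' Phase I: virotherapy alone from t = 0 to `params$t_r`. Phase II: the final
#' Phase I fields become the initial conditions of the radiovirotherapy model
#' (with the damaged-cell field starting at zero), which is integrated to
#' `t_end` under the given radiation schedule. In the Phase II segment f_x is
#' renormalized by the viable mass at the start of Phase II, so the
#' trajectory restarts at 1 when radiation begins; the `phase` column switches
#' from `"virotherapy"` to `"radiovirotherapy"` exactly once, at `t_r`.
#'
#' @inheritParams run_phase1
#' @param schedule A [radiation_schedule()] whose origin `t0` equals
#'   `params$t_r`.
#' @return A `vd_result` with `phase_boundary = t_r`.
#' @examples
#' \donttest{
#' p <- vd_params(t_r = 24)
#' res <- run_two_phase(p, solver_settings(n_nodes = 41, t_end = 72),
#'   radiation_schedule("constant", t0 = 24))
#' }
#' @export
run_two_phase <- function(params = vd_params(), settings = solver_settings(),
                          schedule = radiation_schedule("constant",
                            t0 = params$t_r
                          ),
                          v_init = c("uniform", "wall")) {
  v_init <- match.arg(v_init)
  if (params$t_r >= settings$t_end) {
    stop("t_r must be smaller than t_end", call. = FALSE)
  }
  if (!isTRUE(all.equal(schedule$t0, params$t_r))) {
    stop("schedule$t0 must equal params$t_r (radiation starts at the phase ",
      "boundary)",
      call. = FALSE
    )
  }
  grid <- radial_grid(params, n_nodes = settings$n_nodes)
  init <- initial_state(params, grid, v_init = v_init)

  settings1 <- settings
  settings1$t_end <- params$t_r
  res1 <- integrate_model(init, params, grid, settings1, model = "phase1")

  handoff <- res1$states[[length(res1$states)]]
  init2 <- field_state(
    t = params$t_r,
    x = handoff$x, y = handoff$y, v = handoff$v,
    u = rep(0, grid$n)
  )
  settings2 <- settings
  settings2$t_end <- settings$t_end - params$t_r
  res2 <- integrate_model(init2, params, grid, settings2,
    model = "phase2", schedule = schedule
  )

  traj1 <- res1$trajectory[res1$trajectory$time_h < params$t_r, , drop = FALSE]
  trajectory <- dplyr::bind_rows(traj1, res2$trajectory)
  new_vd_result(
    trajectory = trajectory,
    states = c(
      res1$states[seq_len(length(res1$states) - 1L)],
      res2$states
    ),
    params = params, settings = settings, grid = grid, schedule = schedule,
    M0 = c(phase1 = res1$M0, phase2 = res2$M0),
    phase_boundary = params$t_r, v_init = v_init
  )
}

#' Parameter and protocol sweeps
#'
#' Runs a family of simulations sharing grid and solver settings while one
#' model parameter and/or the radiation protocol varies, and returns them as
#' a tibble with the swept coordinates alongside a list-column of results —
#' ready for [tidy()] (stacked trajectories) or [glance()] (one outcome row
#' per run).
#'
#' @inheritParams run_phase1
#' @param vary Name of a [vd_params()] field to sweep, or `NULL`.
#' @param values Values for the swept parameter (required when `vary` is
#'   given).
#' @param mode `"phase1"` or `"two_phase"`.
#' @param schedules For `mode = "two_phase"`: a list of
#'   [radiation_schedule()] objects (their `t0` is reset to each `t_r`).
#' @param t_r Phase II start times, h, for `mode = "two_phase"`; defaults to
#'   `params$t_r`.
#' @return A tibble of class `vd_sweep` with columns for the swept
#'   coordinates (`parameter`, `value`, `schedule_mode`, `t_r` as
#'   applicable) and a `result` list-column of `vd_result` objects.
#' @examples
#' \donttest{
#' sw <- run_sweep(vd_params(), solver_settings(n_nodes = 41, t_end = 48),
#'   vary = "b", values = c(2, 50))
#' glance(sw)
#' }
#' @export
run_sweep <- function(params = vd_params(), settings = solver_settings(),
                      vary = NULL, values = NULL,
                      mode = c("phase1", "two_phase"),
                      schedules = NULL, t_r = NULL,
                      v_init = c("uniform", "wall")) {
  mode <- match.arg(mode)
  v_init <- match.arg(v_init)
  if (!is.null(vary)) {
    if (!vary %in% names(params)) {
      stop("unknown parameter name: `", vary, "`", call. = FALSE)
    }
    if (is.null(values) || length(values) == 0L) {
      stop("`values` must be a nonempty vector when `vary` is given",
        call. = FALSE
      )
    }
  } else {
    values <- NA_real_
  }

  if (mode == "phase1") {
    rows <- tidyr::expand_grid(value = values)
    rows$result <- purrr::map(rows$value, function(val) {
      p <- params
      if (!is.null(vary)) {
        p[[vary]] <- val
        p <- do.call(vd_params, unclass(p))
      }
      run_phase1(p, settings, v_init = v_init)
    })
    if (!is.null(vary)) rows <- tibble::add_column(rows, parameter = vary, .before = 1L)
  } else {
    if (is.null(schedules)) {
      schedules <- list(radiation_schedule("constant", t0 = params$t_r))
    }
    if (is.null(t_r)) t_r <- params$t_r
    rows <- tidyr::expand_grid(
      value = values,
      schedule_i = seq_along(schedules),
      t_r = t_r
    )
    rows$schedule_mode <- purrr::map_chr(
      rows$schedule_i, function(i) schedules[[i]]$mode
    )
    rows$result <- purrr::pmap(
      list(rows$value, rows$schedule_i, rows$t_r),
      function(val, si, tr) {
        p <- params
        p$t_r <- tr
        if (!is.null(vary)) p[[vary]] <- val
        p <- do.call(vd_params, unclass(p))
        sch <- schedules[[si]]
        sch$t0 <- tr
        run_two_phase(p, settings, sch, v_init = v_init)
      }
    )
    rows$schedule_i <- NULL
    if (!is.null(vary)) rows <- tibble::add_column(rows, parameter = vary, .before = 1L)
  }
  if (is.null(vary)) rows$value <- NULL
  class(rows) <- c("vd_sweep", class(rows))
  rows
}
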