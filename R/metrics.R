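#' Cross-sectional area of the perivascular annulus
#'
#' `pi * ((r_b/BVF)^2 - r_b^2)`, the area V over which cell densities are
#' integrated; the baseline mass of a uniform field `x0` is `x0 * V`.
#'
#' @param r_b Blood vessel radius, mm.
#' @param BVF Blood volume fraction, in (0, 1).
#' @return Area in mm^2.
#' @examples
#' annulus_area(0.01, 0.05) # 0.0399 * pi
#' @export
annulus_area <- function(r_b, BVF) {
  if (BVF <= 0 || BVF >= 1) stop("BVF must lie in (0, 1)", call. = FALSE)
  pi * ((r_b / BVF)^2 - r_b^2)
}

#' Normalized radial mass of a field
#'
#' Computes `(2*pi/M0) * integral(field * r dr)` over the annulus by
#' composite trapezoid quadrature on the grid nodes. With `field` uniform at
#' `x0` and `M0 = x0 * annulus_area(...)` the result is exactly 1: the
#' trapezoid rule is exact for the linear integrand `x0 * r`, so the
#' normalized mass at t = 0 carries no quadrature error.
#'
#' @param field Per-node densities, length `grid$n`.
#' @param grid A [radial_grid()] object.
#' @param M0 Baseline mass (> 0).
#' @return Dimensionless mass ratio.
#' @examples
#' g <- radial_grid(n_nodes = 51)
#' normalized_mass(rep(2, 51), g, 2 * annulus_area(0.01, 0.05)) # 1
#' @export
normalized_mass <- function(field, grid, M0) {
  if (M0 <= 0) stop("M0 must be positive", call. = FALSE)
  if (length(field) != grid$n) {
    stop("field length does not match grid size", call. = FALSE)
  }
  2 * pi * sum(quadrature_weights(grid) * grid$r * field) / M0
}

# raw (unnormalized) radial mass 2*pi*int f r dr
radial_mass <- function(field, grid) {
  2 * pi * sum(quadrature_weights(grid) * grid$r * field)
}

#' Summarize a simulated trajectory
#'
#' Extracts the outcome landmarks of the normalized-viable-mass trajectory
#' f_x(t): its minimum and final value, the time of its global maximum, an
#' oscillation flag (a local maximum occurring after the first local minimum,
#' using a prominence threshold of 1% of the trajectory range to ignore
#' quadrature jitter), and an eradication flag (f_x below 1% at the end of the
#' run and non-increasing over the final 48 h). Times are reported at snapshot
#' resolution. For a two-phase run the summary describes the Phase II segment
#' (each segment carries its own normalization).
#'
#' @param result A `vd_result` from [run_phase1()] or [run_two_phase()].
#' @return A one-row tibble: `fx_min`, `t_min_h`, `fx_final`, `t_peak_h`,
#'   `oscillatory`, `eradicated`.
#' @examples
#' \donttest{
#' res <- run_phase1(vd_params(), solver_settings(n_nodes = 41, t_end = 48))
#' summarize_run(res)
#' }
#' @export
summarize_run <- function(result) {
  if (!inherits(result, "vd_result")) {
    stop("result must be a vd_result", call. = FALSE)
  }
  traj <- result$trajectory
  if (!is.null(result$phase_boundary)) {
    traj <- traj[traj$phase == "radiovirotherapy", , drop = FALSE]
  }
  if (nrow(traj) < 3L) stop("too few snapshots to summarize", call. = FALSE)
  fx <- traj$fx
  tt <- traj$time_h
  i_min <- which.min(fx)
  i_max <- which.max(fx)

  final_window <- tt >= tt[length(tt)] - 48
  erad <- fx[length(fx)] < 0.01 &&
    all(diff(fx[final_window]) <= 1e-12 * max(fx))

  tibble::tibble(
    fx_min = fx[i_min],
    t_min_h = tt[i_min],
    fx_final = fx[length(fx)],
    t_peak_h = tt[i_max],
    oscillatory = is_oscillatory(fx),
    eradicated = erad
  )
}

# a local maximum after the first local minimum, ignoring wiggles smaller
# than 1% of the trajectory range
is_oscillatory <- function(fx, prominence = 0.01) {
  rng <- diff(range(fx))
  if (rng <= 0) {
    return(FALSE)
  }
  tol <- prominence * rng
  # compress to alternating significant extrema
  turns <- c()
  kinds <- c()
  last <- fx[1]
  direction <- 0
  for (val in fx[-1]) {
    d <- val - last
    if (abs(d) < .Machine$double.eps * max(abs(val), 1)) next
    s <- sign(d)
    if (direction != 0 && s != direction) {
      turns <- c(turns, last)
      kinds <- c(kinds, if (direction > 0) "max" else "min")
    }
    direction <- s
    last <- val
  }
  if (length(turns) < 2L) {
    return(FALSE)
  }
  # prune insignificant turns: a min followed by a max must differ by >= tol
  sig <- abs(diff(c(turns, fx[length(fx)]))) >= tol
  kinds <- kinds[sig]
  turns <- turns[sig]
  first_min <- match("min", kinds)
  !is.na(first_min) && any(kinds[seq_along(kinds) > first_min] == "max")
}
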