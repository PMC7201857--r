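#' Field state on the radial grid
#'
#' Bundles the per-node densities at one instant: uninfected cells `x`,
#' infected cells `y`, free virus `v`, and (only in the radiovirotherapy
#' model) radiation-damaged cells `u`.
#'
#' @param t Time, h.
#' @param x,y,v Numeric vectors of per-node densities (cells or viruses per
#'   mm^3), all the same length.
#' @param u Damaged-cell densities, or `NULL` for the virotherapy-only model.
#'
#' @return An object of class `vd_state`.
#' @examples
#' g <- radial_grid(n_nodes = 11)
#' field_state(0, rep(5e5, 11), rep(0, 11), rep(0, 11))
#' @export
field_state <- function(t, x, y, v, u = NULL) {
  n <- length(x)
  if (length(y) != n || length(v) != n || (!is.null(u) && length(u) != n)) {
    stop("all field vectors must have the same length", call. = FALSE)
  }
  vals <- c(x, y, v, u)
  if (!all(is.finite(vals))) {
    stop("field state contains non-finite values", call. = FALSE)
  }
  structure(list(t = t, x = x, y = y, v = v, u = u), class = "vd_state")
}

#' Initial state for a simulation
#'
#' Builds the t = 0 fields: uninfected cells uniform at `x0`, no infected
#' cells, and one of two readings of the unstated initial virus profile:
#'
#' * `"uniform"` (default): `v(r, 0) = v0` everywhere — the tissue is loaded
#'   with virus at the treatment concentration when delivery starts. This is
#'   the reading under which the model reproduces the reported behaviour of
#'   the combined treatment (see the methods vignette).
#' * `"wall"`: `v(r, 0) = 0` except `v(r_b, 0) = v0` — virus enters only
#'   through the vessel wall. At the reference virus diffusivity the wall
#'   source penetrates only ~0.02 mm in 30 days, so under this reading the
#'   virus barely reaches the tissue on the treatment horizon.
#'
#' @param params A [vd_params()] record.
#' @param grid A [radial_grid()] object.
#' @param v_init `"uniform"` or `"wall"`.
#' @param phase2 If `TRUE`, include a zero damaged-cell field `u`.
#'
#' @return A [field_state()] at t = 0.
#' @export
initial_state <- function(params, grid, v_init = c("uniform", "wall"),
                          phase2 = FALSE) {
  v_init <- match.arg(v_init)
  n <- grid$n
  v <- if (v_init == "uniform") rep(params$v0, n) else c(params$v0, rep(0, n - 1L))
  field_state(
    t = 0,
    x = rep(params$x0, n),
    y = rep(0, n),
    v = v,
    u = if (phase2) rep(0, n) else NULL
  )
}

#' @export
print.vd_state <- function(x, ...) {
  cat(sprintf(
    "<vd_state> t = %g h, %d nodes%s\n", x$t, length(x$x),
    if (is.null(x$u)) "" else " (with damaged-cell field u)"
  ))
  invisible(x)
}
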