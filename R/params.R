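#' Model parameters for the virotherapy / radiovirotherapy models
#'
#' Builds a validated record of every rate and geometry constant used by the
#' reaction-diffusion models. Defaults are the published reference values for
#' an aggressive tumour treated with a continuously delivered oncolytic virus:
#' all times are in hours, lengths in mm, densities in cells (or viruses) per
#' mm^3.
#'
#' The tissue served by one blood vessel of radius `r_b` is the annulus
#' `[r_b, r_b / BVF]`, where `BVF` is the blood volume fraction. Virus is held
#' at density `v0` at the vessel wall; uninfected tumour cells start uniform at
#' `x0`.
#'
#' @param D1 Diffusion coefficient of tumour cells, mm^2/h.
#' @param r1 Tumour growth rate, 1/h.
#' @param beta Viral infection rate, mm^3/(h virus).
#' @param delta Death (lysis) rate of infected cells, 1/h.
#' @param D2 Diffusion coefficient of free virus, mm^2/h.
#' @param b Burst size: viruses released per lysed cell.
#' @param kappa Viruses consumed per infection event (virus/cell). The
#'   radiovirotherapy model as usually written assumes `kappa = 1`; the
#'   parameter is applied in both phases so the two models agree when
#'   radiation is off.
#' @param alpha Clearance rate of free virus, 1/h.
#' @param a1,a2 Radiation damage rates of uninfected / infected cells, 1/h per
#'   unit dose-rate.
#' @param gamma Death rate of radiation-damaged cells, 1/h.
#' @param r_b Blood vessel radius, mm.
#' @param BVF Blood volume fraction, dimensionless, in (0, 1).
#' @param v0 Virus density at the vessel wall, viruses/mm^3.
#' @param x0 Initial uninfected tumour cell density, cells/mm^3.
#' @param t_r Time at which radiotherapy starts (Phase II), h.
#'
#' @return An object of class `vd_params`: a named list of the validated
#'   constants.
#' @examples
#' p <- vd_params()
#' p$beta
#' vd_params(b = 2)$b
#' @export
vd_params <- function(D1 = 1e-8,
                      r1 = 0.02,
                      beta = 7e-10,
                      delta = 1 / 18,
                      D2 = 5e-7,
                      b = 50,
                      kappa = 1,
                      alpha = 0.008,
                      a1 = 0.01,
                      a2 = 0.01,
                      gamma = 0.01,
                      r_b = 0.01,
                      BVF = 0.05,
                      v0 = 0.5e6,
                      x0 = 0.5e6,
                      t_r = 120) {
  p <- list(
    D1 = D1, r1 = r1, beta = beta, delta = delta, D2 = D2, b = b,
    kappa = kappa, alpha = alpha, a1 = a1, a2 = a2, gamma = gamma,
    r_b = r_b, BVF = BVF, v0 = v0, x0 = x0, t_r = t_r
  )
  for (nm in names(p)) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      stop("parameter `", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  # rates may be zero (limiting cases such as the reaction-free conservation
  # check or the virus-free growth law are legitimate model configurations),
  # but never negative; geometry and the phase boundary must be positive
  for (nm in setdiff(names(p), c("r_b", "BVF", "t_r"))) {
    if (p[[nm]] < 0) {
      stop("parameter `", nm, "` must be nonnegative", call. = FALSE)
    }
  }
  if (p$r_b <= 0) stop("parameter `r_b` must be strictly positive", call. = FALSE)
  if (p$t_r <= 0) stop("parameter `t_r` must be strictly positive", call. = FALSE)
  if (p$BVF <= 0) stop("parameter `BVF` must be strictly positive", call. = FALSE)
  if (p$BVF >= 1) {
    stop("parameter `BVF` must lie in (0, 1) so that r_b/BVF > r_b",
      call. = FALSE
    )
  }
  structure(p, class = "vd_params")
}

#' @export
print.vd_params <- function(x, ...) {
  cat("<vd_params> tumour-virus model constants (h, mm, per-mm^3 units)\n")
  print(tibble::tibble(
    parameter = names(x),
    value = unlist(x, use.names = FALSE)
  ), n = Inf)
  invisible(x)
}

#' Uniform radial grid on the perivascular annulus
#'
#' Discretizes `[r_b, r_b/BVF]` with `n_nodes` equally spaced nodes, the first
#' node on the vessel wall and the last on the outer rim of the annulus.
#'
#' @param params A [vd_params()] record (only `r_b` and `BVF` are used), or
#'   `NULL` to pass `r_b` and `BVF` directly.
#' @param n_nodes Number of radial nodes (>= 5).
#' @param r_b,BVF Geometry, used when `params` is `NULL`.
#'
#' @return An object of class `vd_grid`: list with `r` (node coordinates, mm),
#'   `dr` (uniform spacing), `n`, `r_inner`, `r_outer`.
#' @examples
#' g <- radial_grid(vd_params(), n_nodes = 96)
#' range(g$r)
#' @export
radial_grid <- function(params = vd_params(), n_nodes = 191,
                        r_b = NULL, BVF = NULL) {
  if (is.null(params)) {
    stopifnot(is.numeric(r_b), is.numeric(BVF))
  } else {
    r_b <- params$r_b
    BVF <- params$BVF
  }
  if (BVF <= 0 || BVF >= 1) stop("BVF must lie in (0, 1)", call. = FALSE)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 5L) stop("n_nodes must be at least 5", call. = FALSE)
  r_outer <- r_b / BVF
  r <- seq(r_b, r_outer, length.out = n_nodes)
  structure(
    list(
      r = r, dr = r[2] - r[1], n = n_nodes,
      r_inner = r_b, r_outer = r_outer
    ),
    class = "vd_grid"
  )
}

#' @export
print.vd_grid <- function(x, ...) {
  cat(sprintf(
    "<vd_grid> %d nodes on [%g, %g] mm, dr = %g mm\n",
    x$n, x$r_inner, x$r_outer, x$dr
  ))
  invisible(x)
}

#' Trapezoid quadrature weights for a radial grid
#'
#' Weights `w` such that `sum(w * f)` approximates `integral f(r) dr` over the
#' annulus radii. Used (multiplied by `2*pi*r`) for all mass integrals; on the
#' uniform grid these coincide with the finite-volume cell widths, so the
#' discrete diffusion operator conserves exactly the mass this rule measures.
#'
#' @param grid A [radial_grid()] object.
#' @return Numeric vector of length `grid$n`.
#' @keywords internal
quadrature_weights <- function(grid) {
  w <- rep(grid$dr, grid$n)
  w[c(1L, grid$n)] <- grid$dr / 2
  w
}

#' Solver settings for the method-of-lines integration
#'
#' @param dt Time step, h. Must satisfy the explicit-diffusion bound
#'   `dt <= 0.25 * dr^2 / max(D1, D2)` for the grid in use (checked at
#'   integration time). The default, with the default 191-node grid, was fixed
#'   by requiring that halving it changes the final normalized mass by less
#'   than 0.1% relative.
#' @param n_nodes Number of radial nodes.
#' @param snapshot_every Output cadence, h (snapshots also always include t = 0
#'   and t = t_end).
#' @param t_end Total simulated time, h.
#'
#' @return An object of class `vd_settings`.
#' @examples
#' solver_settings(t_end = 240)
#' @export
solver_settings <- function(dt = 0.05, n_nodes = 191, snapshot_every = 1,
                            t_end = 720) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (snapshot_every <= 0) stop("snapshot_every must be positive", call. = FALSE)
  structure(
    list(
      dt = dt, n_nodes = as.integer(n_nodes),
      snapshot_every = snapshot_every, t_end = t_end
    ),
    class = "vd_settings"
  )
}

#' @export
print.vd_settings <- function(x, ...) {
  cat(sprintf(
    "<vd_settings> dt = %g h, %d nodes, snapshots every %g h, t_end = %g h\n",
    x$dt, x$n_nodes, x$snapshot_every, x$t_end
  ))
  invisible(x)
}
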