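#' Radiation dose-rate schedules
#'
#' Constructs a time-dependent dose-rate function R(t) in one of four modes:
#'
#' * `"constant"`: `R(t) = R_const` — temporary brachytherapy, a source held
#'   in place emitting a fixed dose-rate.
#' * `"decay"`: `R(t) = beta1 * exp(-alpha1 * (t - t0))` — permanent
#'   brachytherapy, an implanted source whose emission decays.
#' * `"periodic"`: `R(t) = beta2 + alpha2 * sin(omega * (t - t0))` — external
#'   beam delivered in a periodic pattern.
#' * `"off"`: `R(t) = 0` — the virotherapy-only control.
#'
#' Time is measured from `t0`, the moment radiotherapy starts (the Phase II
#' boundary): the decaying source is implanted, and the periodic beam switched
#' on, at `t0`. With the defaults the constant and decaying schedules agree at
#' `t0` (both 2) and the periodic schedule starts at its offset `beta2 = 1`.
#'
#' @param mode One of `"constant"`, `"decay"`, `"periodic"`, `"off"`.
#' @param R_const Dose-rate of the constant mode.
#' @param beta1,alpha1 Amplitude and decay rate (1/h) of the decay mode.
#' @param beta2,alpha2,omega Offset, amplitude and angular frequency (rad/h)
#'   of the periodic mode. Requires `beta2 >= alpha2` so R(t) stays
#'   nonnegative.
#' @param t0 Schedule origin, h (defaults to the reference Phase II start).
#'
#' @return An object of class `vd_schedule`.
#' @examples
#' sch <- radiation_schedule("decay")
#' schedule_rate(sch, sch$t0 + 100) # 2 * exp(-1)
#' @export
radiation_schedule <- function(mode = c("constant", "decay", "periodic", "off"),
                               R_const = 2,
                               beta1 = 2, alpha1 = 0.01,
                               beta2 = 1, alpha2 = 1, omega = 2,
                               t0 = 120) {
  mode <- match.arg(mode)
  if (mode == "constant" && R_const < 0) {
    stop("R_const must be nonnegative", call. = FALSE)
  }
  if (mode == "decay" && (beta1 < 0 || alpha1 < 0)) {
    stop("decay mode requires beta1 >= 0 and alpha1 >= 0", call. = FALSE)
  }
  if (mode == "periodic" && beta2 < alpha2) {
    stop("periodic mode requires beta2 >= alpha2 so that R(t) >= 0",
      call. = FALSE
    )
  }
  structure(
    list(
      mode = mode, R_const = R_const, beta1 = beta1, alpha1 = alpha1,
      beta2 = beta2, alpha2 = alpha2, omega = omega, t0 = t0
    ),
    class = "vd_schedule"
  )
}

#' @rdname radiation_schedule
#' @param schedule A `vd_schedule` object.
#' @param t Time(s), h; must satisfy `t >= t0`.
#' @return `schedule_rate()`: the dose-rate(s) at `t` (vectorized).
#' @export
schedule_rate <- function(schedule, t) {
  if (!inherits(schedule, "vd_schedule")) {
    stop("schedule must be a vd_schedule", call. = FALSE)
  }
  if (any(t < schedule$t0)) {
    stop("schedule is undefined before its start time t0 = ", schedule$t0,
      call. = FALSE
    )
  }
  s <- t - schedule$t0
  switch(schedule$mode,
    constant = rep(schedule$R_const, length(t)),
    decay = schedule$beta1 * exp(-schedule$alpha1 * s),
    periodic = schedule$beta2 + schedule$alpha2 * sin(schedule$omega * s),
    off = rep(0, length(t))
  )
}

#' @export
print.vd_schedule <- function(x, ...) {
  desc <- switch(x$mode,
    constant = sprintf("R(t) = %g", x$R_const),
    decay = sprintf("R(t) = %g exp(-%g (t - t0))", x$beta1, x$alpha1),
    periodic = sprintf(
      "R(t) = %g + %g sin(%g (t - t0))", x$beta2, x$alpha2, x$omega
    ),
    off = "R(t) = 0"
  )
  cat(sprintf("<vd_schedule> %s mode, t0 = %g h: %s\n", x$mode, x$t0, desc))
  invisible(x)
}
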