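#' Plot the normalized viable-mass trajectory
#'
#' @param object A `vd_result`.
#' @param ... Unused.
#' @return A ggplot: f_x against time in days, with the radiotherapy start
#'   marked for two-phase runs.
#' @method autoplot vd_result
#' @export
autoplot.vd_result <- function(object, ...) {
  df <- tidy(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$time_d, .data$fx)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$phase), linewidth = 0.6) +
    ggplot2::labs(
      x = "time (days)",
      y = "normalized viable tumour mass f_x",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$phase_boundary)) {
    gg <- gg + ggplot2::geom_vline(
      xintercept = object$phase_boundary / 24, linetype = "dashed",
      colour = "grey40"
    )
  }
  gg
}

#' Plot trajectories of a sweep
#'
#' @param object A `vd_sweep`.
#' @param ... Unused.
#' @return A ggplot with one coloured curve per sweep member (faceted by
#'   `t_r` when several radiation timings were swept).
#' @method autoplot vd_sweep
#' @export
autoplot.vd_sweep <- function(object, ...) {
  df <- tidy(object)
  colour_var <- if ("value" %in% names(df)) {
    "value"
  } else if ("schedule_mode" %in% names(df)) {
    "schedule_mode"
  } else {
    NULL
  }
  if (!is.null(colour_var) && colour_var == "value" &&
    "schedule_mode" %in% names(df) &&
    dplyr::n_distinct(df$schedule_mode) > 1L) {
    colour_var <- "schedule_mode"
  }
  aes <- if (is.null(colour_var)) {
    ggplot2::aes(.data$time_d, .data$fx)
  } else {
    ggplot2::aes(.data$time_d, .data$fx,
      colour = factor(.data[[colour_var]])
    )
  }
  gg <- ggplot2::ggplot(df, aes) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::labs(
      x = "time (days)", y = "normalized viable tumour mass f_x",
      colour = colour_var
    ) +
    ggplot2::theme_minimal()
  if ("t_r" %in% names(df) && dplyr::n_distinct(df$t_r) > 1L) {
    gg <- gg + ggplot2::facet_wrap(~t_r, labeller = ggplot2::label_both)
  }
  gg
}

#' Radial density profiles at chosen times
#'
#' Mirrors the customary presentation of this model: the density of each
#' species against radius at a handful of times (e.g. days 2, 4 and 6).
#'
#' @param result A `vd_result`.
#' @param days Times to display, in days.
#' @param species Which fields to show.
#' @return A ggplot faceted by species.
#' @export
plot_profiles <- function(result, days = c(2, 4, 6),
                          species = c("x", "y", "v")) {
  df <- field_snapshots(result, times = days * 24)
  df <- df[df$species %in% species, , drop = FALSE]
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$r_mm, .data$density,
      colour = factor(round(.data$time_h / 24, 2))
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(
      x = "radius (mm)", y = "density (per mm^3)", colour = "day"
    ) +
    ggplot2::theme_minimal()
}
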