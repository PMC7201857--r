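#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation result into its trajectory tibble
#'
#' @param x A `vd_result`.
#' @param ... Unused.
#' @return A tibble with one row per snapshot: `time_h`, `time_d`, `fx`,
#'   `mass`, `phase`.
#' @method tidy vd_result
#' @export
tidy.vd_result <- function(x, ...) {
  dplyr::mutate(x$trajectory, time_d = .data$time_h / 24, .after = "time_h")
}

#' One-row outcome summary of a simulation result
#'
#' @param x A `vd_result`.
#' @param ... Unused.
#' @return The [summarize_run()] tibble.
#' @method glance vd_result
#' @export
glance.vd_result <- function(x, ...) {
  summarize_run(x)
}

#' Stacked trajectories of a sweep
#'
#' @param x A `vd_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A tibble with the swept coordinates plus one row per snapshot per
#'   run.
#' @method tidy vd_sweep
#' @export
tidy.vd_sweep <- function(x, ...) {
  coords <- dplyr::select(tibble::as_tibble(x), -"result")
  out <- purrr::map(x$result, tidy)
  dplyr::bind_cols(
    coords[rep(seq_len(nrow(coords)), vapply(out, nrow, 1L)), , drop = FALSE],
    dplyr::bind_rows(out)
  )
}

#' One outcome row per sweep member
#'
#' @param x A `vd_sweep`.
#' @param ... Unused.
#' @return A tibble with the swept coordinates and the [summarize_run()]
#'   columns.
#' @method glance vd_sweep
#' @export
glance.vd_sweep <- function(x, ...) {
  coords <- dplyr::select(tibble::as_tibble(x), -"result")
  dplyr::bind_cols(coords, dplyr::bind_rows(purrr::map(x$result, glance)))
}

#' Long-format field snapshots
#'
#' Unnests the stored field snapshots of a run into a tidy table, one row per
#' (time, radius, species), suitable for profile plots or CSV export.
#'
#' @param result A `vd_result`.
#' @param times Snapshot times (h) to keep; default all. The nearest stored
#'   snapshots are used.
#' @return A tibble: `time_h`, `r_mm`, `species` (x / y / v / u), `density`.
#' @export
field_snapshots <- function(result, times = NULL) {
  stopifnot(inherits(result, "vd_result"))
  states <- result$states
  stored <- vapply(states, function(s) s$t, 0)
  if (!is.null(times)) {
    idx <- unique(vapply(times, function(tt) which.min(abs(stored - tt)), 0L))
    states <- states[idx]
  }
  purrr::map_dfr(states, function(s) {
    species <- c("x", "y", "v", if (!is.null(s$u)) "u")
    purrr::map_dfr(species, function(sp) {
      tibble::tibble(
        time_h = s$t, r_mm = result$grid$r, species = sp, density = s[[sp]]
      )
    })
  })
}
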