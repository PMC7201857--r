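#' Run configuration
#'
#' A `vd_config` bundles everything needed to reproduce a run: model
#' parameters, solver settings, radiation schedule, the run mode, the initial
#' virus profile, and (for sweeps) the sweep specification. Configurations
#' round-trip losslessly through YAML (or JSON) files whose keys mirror the
#' model's symbol names.
#'
#' @param parameters Named list of [vd_params()] overrides.
#' @param solver Named list of [solver_settings()] overrides.
#' @param schedule Named list of [radiation_schedule()] overrides (must
#'   include `mode` when given); its origin `t0` is tied to `t_r`.
#' @param mode `"phase1"`, `"two_phase"` or `"sweep"`.
#' @param v_init Initial virus profile, `"uniform"` or `"wall"`.
#' @param sweep For `mode = "sweep"`: list with optional `parameter`,
#'   `values`, `timings` (t_r values) and `modes` (radiation schedule modes);
#'   `phase` chooses `"phase1"` (default when no timings/modes are given) or
#'   `"two_phase"`.
#' @param out_dir Output directory for [write_result()].
#' @param seed Reserved; the model is deterministic and the seed is unused.
#' @return A `vd_config` object with fully resolved `params`, `settings` and
#'   `schedule` fields.
#' @examples
#' cfg <- run_config(parameters = list(b = 2))
#' cfg$params$b
#' @export
run_config <- function(parameters = list(), solver = list(), schedule = list(),
                       mode = c("phase1", "two_phase", "sweep"),
                       v_init = c("uniform", "wall"), sweep = list(),
                       out_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  v_init <- match.arg(v_init)
  check_known_keys(parameters, names(formals(vd_params)), "parameters")
  check_known_keys(solver, names(formals(solver_settings)), "solver")
  check_known_keys(
    schedule, names(formals(radiation_schedule)), "schedule"
  )
  check_known_keys(
    sweep, c("parameter", "values", "timings", "modes", "phase"), "sweep"
  )
  params <- do.call(vd_params, parameters)
  settings <- do.call(solver_settings, solver)
  sch <- if (length(schedule) > 0L || mode == "two_phase") {
    schedule$t0 <- params$t_r
    do.call(radiation_schedule, schedule)
  } else {
    NULL
  }
  structure(
    list(
      mode = mode, v_init = v_init,
      parameters = parameters, solver = solver, schedule_spec = schedule,
      params = params, settings = settings, schedule = sch,
      sweep = sweep, out_dir = out_dir, seed = seed
    ),
    class = "vd_config"
  )
}

check_known_keys <- function(x, known, what) {
  if (length(x) == 0L) {
    return(invisible(TRUE))
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("all `", what, "` entries must be named", call. = FALSE)
  }
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L) {
    stop("unknown ", what, " key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Read / write a run configuration file
#'
#' `load_config()` parses a YAML (`.yml`/`.yaml`) or JSON (`.json`) file,
#' rejects unknown keys naming the offender, and fills every unspecified
#' value with the model defaults. `write_config()` writes the resolved
#' configuration back out; `load(write(load(cfg)))` equals `load(cfg)`.
#'
#' @param path Path to the configuration file.
#' @return `load_config()`: a `vd_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  check_known_keys(
    raw,
    c(
      "mode", "v_init", "parameters", "solver", "schedule", "sweep",
      "out_dir", "seed"
    ),
    "config"
  )
  run_config(
    parameters = as_flat_list(raw$parameters),
    solver = as_flat_list(raw$solver),
    schedule = as_flat_list(raw$schedule),
    mode = raw$mode %||% "phase1",
    v_init = raw$v_init %||% "uniform",
    sweep = as_flat_list(raw$sweep),
    out_dir = raw$out_dir,
    seed = raw$seed
  )
}

as_flat_list <- function(x) {
  if (is.null(x)) list() else as.list(x)
}

#' @rdname load_config
#' @param config A `vd_config`.
#' @return `write_config()`: the path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "vd_config"))
  out <- list(
    mode = config$mode,
    v_init = config$v_init,
    parameters = unclass(config$params),
    solver = unclass(config$settings)
  )
  if (!is.null(config$schedule)) out$schedule <- unclass(config$schedule)
  if (length(config$sweep) > 0L) out$sweep <- config$sweep
  if (!is.null(config$out_dir)) out$out_dir <- config$out_dir
  if (!is.null(config$seed)) out$seed <- config$seed
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Execute a configuration
#'
#' Dispatches to [run_phase1()], [run_two_phase()] or [run_sweep()] according
#' to the configuration's mode.
#'
#' @param config A `vd_config`.
#' @return A `vd_result` or `vd_sweep`.
#' @export
execute_config <- function(config) {
  stopifnot(inherits(config, "vd_config"))
  switch(config$mode,
    phase1 = run_phase1(config$params, config$settings, v_init = config$v_init),
    two_phase = run_two_phase(config$params, config$settings, config$schedule,
      v_init = config$v_init
    ),
    sweep = {
      sw <- config$sweep
      two_phase <- identical(sw$phase, "two_phase") ||
        !is.null(sw$timings) || !is.null(sw$modes)
      schedules <- if (!is.null(sw$modes)) {
        lapply(sw$modes, function(m) radiation_schedule(m, t0 = config$params$t_r))
      } else if (!is.null(config$schedule)) {
        list(config$schedule)
      } else {
        NULL
      }
      run_sweep(config$params, config$settings,
        vary = sw$parameter, values = sw$values,
        mode = if (two_phase) "two_phase" else "phase1",
        schedules = schedules, t_r = sw$timings, v_init = config$v_init
      )
    }
  )
}

#' Write a simulation result to disk
#'
#' Emits, into `dir`: `trajectory.csv` (`time_h`, `fx`, `phase`),
#' `snapshots.csv` (long format: `time_h`, `r_mm`, `species`, `density`),
#' `summary.json` (the [summarize_run()] record), and `config.yaml` (the
#' resolved configuration the run can be reproduced from). Numbers are
#' written at 17 significant digits so re-running from the echoed
#' configuration reproduces the files byte for byte.
#'
#' @param result A `vd_result`.
#' @param dir Output directory (created if needed).
#' @param snapshot_times Times (h) whose full fields are written; default all
#'   stored snapshots.
#' @return Invisibly, the paths written.
#' @export
write_result <- function(result, dir, snapshot_times = NULL) {
  stopifnot(inherits(result, "vd_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    trajectory = file.path(dir, "trajectory.csv"),
    snapshots = file.path(dir, "snapshots.csv"),
    summary = file.path(dir, "summary.json"),
    config = file.path(dir, "config.yaml")
  )
  write_csv17(
    result$trajectory[, c("time_h", "fx", "phase")], paths[["trajectory"]]
  )
  write_csv17(field_snapshots(result, snapshot_times), paths[["snapshots"]])
  jsonlite::write_json(
    as.list(summarize_run(result)), paths[["summary"]],
    auto_unbox = TRUE, digits = NA
  )
  write_config(config_from_result(result), paths[["config"]])
  invisible(paths)
}

config_from_result <- function(result) {
  run_config(
    parameters = unclass(result$params),
    solver = unclass(result$settings),
    schedule = if (is.null(result$schedule)) {
      list()
    } else {
      unclass(result$schedule)
    },
    mode = if (is.null(result$phase_boundary)) "phase1" else "two_phase",
    v_init = result$v_init %||% "uniform"
  )
}

write_csv17 <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- trimws(formatC(out[[nm]], digits = 17, format = "g"))
    }
  }
  utils::write.table(out, path,
    sep = ",", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
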