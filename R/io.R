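utils::globalVariables(c("p_initial_reach", "p_disengage"))

config_model_keys <- c(
  "total_population", "exposure_rate", "p_initial_reach", "p_disengage",
  "p_delayed_reach", "p_reengage", "steps_per_year", "horizon_years"
)
config_cost_keys <- c("base_cost", "steepness")
config_run_keys <- c(
  "scenario", "grid_resolution", "output_dir", "formats"
)

#' Load a run configuration
#'
#' Reads a YAML configuration file and merges it over the model defaults.
#' Recognised top-level keys are the model parameters
#' (`total_population`, `exposure_rate`, `p_initial_reach`, `p_disengage`,
#' `p_delayed_reach`, `p_reengage`, `steps_per_year`, `horizon_years`),
#' a `costs:` block with `base_cost` and `steepness` (scalar or per-activity
#' map), and run settings `scenario` (a preset name or `"all"`),
#' `grid_resolution`, `output_dir` and `formats` (any of `csv`, `json`,
#' `png`). Unknown keys are rejected, and every range violation is reported
#' with the offending key's name. An empty file yields the full defaults.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config` with elements `params`
#'   ([program_parameters()]), `costs` ([cost_parameters()]), `scenario`,
#'   `grid_resolution`, `output_dir`, `formats`.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines("p_initial_reach: 0.5\ngrid_resolution: 5", cfg_file)
#' load_config(cfg_file)$grid_resolution
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop("config parse error in '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) {
    stop("config must be a YAML mapping (key: value), got a scalar",
      call. = FALSE
    )
  }
  known <- c(config_model_keys, "costs", config_run_keys)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
      "; valid keys: ", paste(known, collapse = ", "),
      call. = FALSE
    )
  }

  param_args <- raw[intersect(names(raw), config_model_keys)]
  params <- tryCatch(
    do.call(program_parameters, param_args),
    error = function(e) stop(conditionMessage(e), call. = FALSE)
  )

  cost_args <- list()
  if (!is.null(raw$costs)) {
    if (!is.list(raw$costs)) {
      stop("config key 'costs' must be a mapping with base_cost/steepness",
        call. = FALSE
      )
    }
    bad <- setdiff(names(raw$costs), config_cost_keys)
    if (length(bad) > 0) {
      stop("unknown config key(s) under 'costs': ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    cost_args <- lapply(raw$costs, function(v) {
      if (is.list(v)) unlist(v) else v
    })
  }
  costs <- tryCatch(
    do.call(cost_parameters, cost_args),
    error = function(e) stop(conditionMessage(e), call. = FALSE)
  )

  scenario <- raw$scenario %||% "all"
  if (!identical(scenario, "all")) {
    as_scenario(scenario) # validates the name
  }
  grid_resolution <- raw$grid_resolution %||% 21
  if (!is.numeric(grid_resolution) || length(grid_resolution) != 1 ||
    grid_resolution < 2 || grid_resolution != round(grid_resolution)) {
    stop("config key 'grid_resolution' must be an integer >= 2", call. = FALSE)
  }
  formats <- raw$formats %||% "csv"
  formats <- unlist(formats)
  bad_fmt <- setdiff(formats, c("csv", "json", "png"))
  if (length(bad_fmt) > 0) {
    stop("config key 'formats' allows csv, json, png; got: ",
      paste(bad_fmt, collapse = ", "),
      call. = FALSE
    )
  }

  structure(
    list(
      params = params,
      costs = costs,
      scenario = scenario,
      grid_resolution = as.integer(grid_resolution),
      output_dir = raw$output_dir %||% ".",
      formats = formats
    ),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate a trajectory
#'
#' One row per recorded time point: the time in years, the five stocks, the
#' six flows of the step ending at that time point (zero on the initial
#' row), the four per-activity cost increments, and the running cumulative
#' total cost.
#'
#' @param x A `program_trajectory`.
#' @param row.names,optional,... Passed through for S3 compatibility; unused.
#' @return A `data.frame` with `n_steps + 1` rows.
#' @export
as.data.frame.program_trajectory <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  n <- length(x$times)
  zero_flow <- matrix(0, nrow = 1, ncol = 6, dimnames = list(NULL, flow_names))
  zero_cost <- matrix(0, nrow = 1, ncol = 4,
                      dimnames = list(NULL, cost_activity_columns))
  flows <- rbind(zero_flow, x$flows)
  costs <- rbind(zero_cost, x$cost_increments[, cost_activity_columns,
                                              drop = FALSE])
  data.frame(
    time_years = x$times,
    x$states,
    flow = flows,
    cost = costs,
    cumulative_cost = cumsum(c(0, x$cost_increments[, "total"])),
    check.names = FALSE,
    row.names = NULL
  )
}

#' Write a trajectory to CSV
#'
#' Writes the table produced by [as.data.frame.program_trajectory()]:
#' columns `time_years`, the five stocks, `flow.*` for the six flows,
#' `cost.*` for the per-activity cost increments and `cumulative_cost`.
#' The output carries no timestamps, so reruns are byte-identical.
#'
#' @param trajectory A `program_trajectory`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  if (!inherits(trajectory, "program_trajectory")) {
    stop("'trajectory' must be a program_trajectory", call. = FALSE)
  }
  df <- as.data.frame(trajectory)
  write_csv_checked(df, path)
}

#' Write grid sweep results to CSV (long format)
#'
#' One row per grid cell: `scenario`, `p_initial_reach`, `p_disengage`,
#' `participation`, `cumulative_cost`. Rows are ordered reach-major
#' ascending (all disengagement values for the lowest reach first), with
#' scenarios concatenated in the order supplied.
#'
#' @param grid_results A `grid_result` or a list of them.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_grid_csv <- function(grid_results, path) {
  write_csv_checked(grid_long(grid_results), path)
}

grid_long <- function(grid_results) {
  if (inherits(grid_results, "grid_result")) {
    grid_results <- list(grid_results)
  }
  if (length(grid_results) == 0 ||
    !all(vapply(grid_results, inherits, logical(1), "grid_result"))) {
    stop("'grid_results' must be a grid_result or a non-empty list of them",
      call. = FALSE
    )
  }
  do.call(rbind, lapply(grid_results, function(g) {
    nr <- length(g$reach_axis)
    nd <- length(g$disengage_axis)
    data.frame(
      scenario = g$scenario$name,
      p_initial_reach = rep(g$reach_axis, each = nd),
      p_disengage = rep(g$disengage_axis, times = nr),
      participation = as.vector(t(g$participation)),
      cumulative_cost = as.vector(t(g$cost)),
      row.names = NULL
    )
  }))
}

write_csv_checked <- function(df, path) {
  ok <- tryCatch(
    {
      utils::write.csv(df, path, row.names = FALSE)
      TRUE
    },
    error = function(e) {
      stop("cannot write '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  invisible(path)
}

#' Render participation and cost heatmaps
#'
#' Draws one participation panel and one cumulative-cost panel per scenario
#' (a 2 x 4 layout when all four scenarios are supplied), with initial
#' reach on the x axis, disengagement on the y axis, and a colour scale
#' shared across scenarios within each outcome. Two PNG files are written:
#' `<path_prefix>_participation.png` and `<path_prefix>_cost.png`.
#'
#' Rendering is an optional output: if the graphics backend fails, a
#' warning is issued and no files are produced, without raising an error.
#'
#' @param grid_results A `grid_result` or a list of them.
#' @param path_prefix Path prefix for the two output files.
#' @param width,height Image size in inches per file.
#' @return Character vector of the files written (possibly empty), invisibly.
#' @export
render_heatmaps <- function(grid_results, path_prefix,
                            width = NULL, height = 3.2) {
  if (inherits(grid_results, "grid_result")) {
    grid_results <- list(grid_results)
  }
  if (length(grid_results) == 0) {
    warning("no grid results supplied; nothing rendered")
    return(invisible(character(0)))
  }
  long <- grid_long(grid_results)
  long$scenario <- factor(long$scenario,
    levels = unique(long$scenario)
  )
  n_panels <- length(unique(long$scenario))
  if (is.null(width)) width <- 2.6 * n_panels + 1.2

  panel <- function(fill_var, fill_lab) {
    ggplot2::ggplot(
      long,
      ggplot2::aes(
        x = p_initial_reach, y = p_disengage,
        fill = !!as.name(fill_var)
      )
    ) +
      ggplot2::geom_raster() +
      ggplot2::facet_wrap(~scenario, nrow = 1) +
      ggplot2::scale_fill_viridis_c(name = fill_lab) +
      ggplot2::labs(x = "initial reach (annual fraction)",
                    y = "disengagement (annual fraction)") +
      ggplot2::theme_minimal(base_size = 9)
  }

  written <- character(0)
  for (panel_def in list(
    list(var = "participation", lab = "participation",
         file = paste0(path_prefix, "_participation.png")),
    list(var = "cumulative_cost", lab = "cumulative cost",
         file = paste0(path_prefix, "_cost.png"))
  )) {
    ok <- tryCatch(
      {
        ggplot2::ggsave(panel_def$file, panel(panel_def$var, panel_def$lab),
          width = width, height = height, dpi = 150
        )
        TRUE
      },
      error = function(e) {
        warning("heatmap rendering skipped (", conditionMessage(e), ")")
        FALSE
      }
    )
    if (ok) written <- c(written, panel_def$file)
  }
  invisible(written)
}
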