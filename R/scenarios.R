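scenario_order <- c("no_support", "enhanced_reach", "reengagement_support", "both")

#' Support-strategy scenario presets
#'
#' The four scenarios fix the two supported pathways (delayed reach and
#' re-engagement) while initial reach and disengagement are swept over a
#' grid. High support corresponds to an annual effective fraction of 0.94:
#' no support (0, 0), enhanced reach (0.94, 0), re-engagement support
#' (0, 0.94), and both strategies (0.94, 0.94).
#'
#' @return A named list of four `scenario_spec` objects, each with fields
#'   `name`, `label`, `p_delayed_reach`, `p_reengage`.
#' @examples
#' scenario_presets()$both
#' @export
scenario_presets <- function() {
  make <- function(name, label, p_l, p_e) {
    structure(
      list(
        name = name, label = label,
        p_delayed_reach = p_l, p_reengage = p_e
      ),
      class = "scenario_spec"
    )
  }
  list(
    no_support = make("no_support", "no support", 0, 0),
    enhanced_reach = make("enhanced_reach", "enhanced reach", 0.94, 0),
    reengagement_support = make(
      "reengagement_support", "re-engagement support", 0, 0.94
    ),
    both = make("both", "both strategies supported", 0.94, 0.94)
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s' (%s): delayed reach %.2f, re-engagement %.2f\n",
    x$name, x$label, x$p_delayed_reach, x$p_reengage
  ))
  invisible(x)
}

as_scenario <- function(scenario) {
  if (inherits(scenario, "scenario_spec")) {
    return(scenario)
  }
  if (is.character(scenario) && length(scenario) == 1) {
    presets <- scenario_presets()
    if (!scenario %in% names(presets)) {
      stop(
        "unknown scenario '", scenario, "'; valid names: ",
        paste(names(presets), collapse = ", "),
        call. = FALSE
      )
    }
    return(presets[[scenario]])
  }
  stop("'scenario' must be a scenario_spec or one of: ",
    paste(scenario_order, collapse = ", "),
    call. = FALSE
  )
}

# Final participation and cumulative cost for a batch of parameter points
# sharing the scenario's support settings. The difference equations are
# elementwise in the state, so all grid points are integrated in lockstep
# as vectors; only the running cost totals are kept, not the trajectories.
sweep_core <- function(p_initial_reach, p_disengage, scenario, params, costs) {
  n <- length(p_initial_reach)
  spy <- as.integer(params$steps_per_year)
  n_steps <- as.integer(round(params$horizon_years * spy))
  dt <- 1 / spy

  q_l <- annual_to_step_fraction(scenario$p_delayed_reach, spy)
  q_e <- annual_to_step_fraction(scenario$p_reengage, spy)
  q_x <- annual_to_step_fraction(p_disengage, spy)

  uc_ir <- unit_cost_increasing(
    p_initial_reach,
    costs$base_cost[["initial_reach"]], costs$steepness[["initial_reach"]]
  )
  uc_dl <- unit_cost_increasing(
    scenario$p_delayed_reach,
    costs$base_cost[["delayed_reach"]], costs$steepness[["delayed_reach"]]
  )
  uc_mt <- unit_cost_retention(
    p_disengage,
    costs$base_cost[["maintenance"]], costs$steepness[["maintenance"]]
  )
  uc_re <- unit_cost_increasing(
    scenario$p_reengage,
    costs$base_cost[["reengagement"]], costs$steepness[["reengagement"]]
  )

  U <- rep(params$total_population, n)
  NE <- NIP <- P <- D <- rep(0, n)
  total_cost <- rep(0, n)
  exposure_per_step <- params$exposure_rate / spy

  for (i in seq_len(n_steps)) {
    out <- step_core(U, NE, NIP, P, D, exposure_per_step,
                     p_initial_reach, q_l, q_x, q_e)
    total_cost <- total_cost +
      uc_ir * out$flows[, "initial_reach"] +
      uc_dl * NIP * dt + uc_mt * P * dt + uc_re * D * dt
    U <- out$U; NE <- out$NE; NIP <- out$NIP; P <- out$P; D <- out$D
  }

  list(
    participation = unname(P) / params$total_population,
    cost = unname(total_cost)
  )
}

#' Outcomes at a single point of the reach x disengagement plane
#'
#' Simulates the full horizon with the scenario's support settings merged
#' into the parameter set and returns the two outcome measures: the
#' participation proportion at the final time point and the cumulative
#' total implementation cost.
#'
#' @param scenario A `scenario_spec` or a preset name
#'   (`"no_support"`, `"enhanced_reach"`, `"reengagement_support"`, `"both"`).
#' @param p_initial_reach,p_disengage Annual fractions in \[0, 1\].
#' @param params A [program_parameters()] object (its own support
#'   proportions are overridden by the scenario and the two arguments).
#' @param costs A [cost_parameters()] object.
#' @return Named numeric vector `c(participation = ..., cost = ...)`.
#' @examples
#' run_scenario_point("no_support", p_initial_reach = 1, p_disengage = 0)
#' @export
run_scenario_point <- function(scenario, p_initial_reach, p_disengage,
                               params = program_parameters(),
                               costs = cost_parameters()) {
  scenario <- as_scenario(scenario)
  validate_parameters(params)
  validate_cost_parameters(costs)
  if (p_initial_reach < 0 || p_initial_reach > 1) {
    stop("'p_initial_reach' must lie in [0, 1]", call. = FALSE)
  }
  if (p_disengage < 0 || p_disengage > 1) {
    stop("'p_disengage' must lie in [0, 1]", call. = FALSE)
  }
  out <- sweep_core(p_initial_reach, p_disengage, scenario, params, costs)
  c(participation = out$participation, cost = out$cost)
}

#' Sweep a scenario over the reach x disengagement grid
#'
#' Evaluates [run_scenario_point()] on the full Cartesian product of an
#' inclusive, evenly spaced grid over \[0, 1\] for initial reach and
#' disengagement. The sweep is deterministic; matrices are oriented with
#' reach ascending down the rows and disengagement ascending across the
#' columns.
#'
#' @param scenario A `scenario_spec` or preset name.
#' @param grid_resolution Number of grid points per axis, >= 2
#'   (default 21: 0.00, 0.05, ..., 1.00).
#' @param params,costs See [run_scenario_point()].
#' @return An object of class `grid_result`: a list with `scenario`,
#'   `reach_axis`, `disengage_axis`, and two
#'   `grid_resolution x grid_resolution` matrices `participation` and
#'   `cost` (rows = reach, columns = disengagement).
#' @examples
#' g <- run_grid("no_support", grid_resolution = 5)
#' g$participation
#' @export
run_grid <- function(scenario, grid_resolution = 21,
                     params = program_parameters(),
                     costs = cost_parameters()) {
  scenario <- as_scenario(scenario)
  validate_parameters(params)
  validate_cost_parameters(costs)
  if (!is.numeric(grid_resolution) || length(grid_resolution) != 1 ||
    grid_resolution < 2 || grid_resolution != round(grid_resolution)) {
    stop("'grid_resolution' must be an integer >= 2", call. = FALSE)
  }
  axis <- seq(0, 1, length.out = grid_resolution)
  pts <- expand.grid(disengage = axis, reach = axis) # reach varies slowest
  out <- sweep_core(pts$reach, pts$disengage, scenario, params, costs)
  dims <- c(grid_resolution, grid_resolution)
  dn <- list(reach = signif(axis, 6), disengage = signif(axis, 6))
  structure(
    list(
      scenario = scenario,
      reach_axis = axis,
      disengage_axis = axis,
      participation = matrix(out$participation, nrow = grid_resolution,
                             byrow = TRUE, dimnames = dn),
      cost = matrix(out$cost, nrow = grid_resolution,
                    byrow = TRUE, dimnames = dn)
    ),
    class = "grid_result"
  )
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf(
    "Grid sweep (%d x %d) for scenario '%s'\n",
    length(x$reach_axis), length(x$disengage_axis), x$scenario$name
  ))
  cat(sprintf(
    "  participation in [%.3f, %.3f]; cumulative cost in [%.1f, %.1f]\n",
    min(x$participation), max(x$participation), min(x$cost), max(x$cost)
  ))
  invisible(x)
}

#' Dominance of disengagement over reach on a participation surface
#'
#' Summarises which swept axis drives the participation outcome: the mean,
#' over fixed-reach rows, of the participation range across disengagement,
#' divided by the mean, over fixed-disengagement columns, of the range
#' across reach. A ratio above 1 means varying disengagement moves
#' participation more than varying reach does (disengagement dominates).
#' A constant surface (both means 0) returns 1 by convention: neither axis
#' dominates.
#'
#' @param grid A `grid_result` from [run_grid()].
#' @return Dimensionless ratio > 0 (possibly `Inf` if reach has no effect
#'   at all while disengagement does).
#' @examples
#' dominance_ratio(run_grid("no_support", grid_resolution = 11))
#' @export
dominance_ratio <- function(grid) {
  if (!inherits(grid, "grid_result")) {
    stop("'grid' must be a grid_result", call. = FALSE)
  }
  if (length(grid$reach_axis) < 2 || length(grid$disengage_axis) < 2) {
    stop("dominance_ratio needs at least 2 points on each axis", call. = FALSE)
  }
  p <- grid$participation
  range_width <- function(v) max(v) - min(v)
  across_disengage <- mean(apply(p, 1, range_width)) # vary d, reach fixed
  across_reach <- mean(apply(p, 2, range_width)) # vary reach, d fixed
  if (across_disengage == 0 && across_reach == 0) {
    return(1)
  }
  across_disengage / across_reach
}

#' Count grid cells with high participation
#'
#' Number of (reach, disengagement) combinations on the grid whose final
#' participation proportion meets or exceeds a threshold — the size of the
#' region of the plane in which the program achieves high reach.
#'
#' @param grid A `grid_result`.
#' @param threshold Participation fraction in \[0, 1\] (default 0.8).
#' @return Integer count of cells.
#' @examples
#' high_participation_cells(run_grid("both", grid_resolution = 11), 0.8)
#' @export
high_participation_cells <- function(grid, threshold = 0.8) {
  if (!inherits(grid, "grid_result")) {
    stop("'grid' must be a grid_result", call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("'threshold' must lie in [0, 1]", call. = FALSE)
  }
  sum(grid$participation >= threshold)
}
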