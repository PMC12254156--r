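cost_activities <- c(
  "initial_reach", "delayed_reach", "maintenance", "reengagement"
)
cost_activity_columns <- paste0(cost_activities, "_cost")

#' Activity cost-curve parameters
#'
#' Each support activity (initial reach, delayed reach, maintenance i.e.
#' retention support, re-engagement) is priced by a normalised exponential
#' unit-cost curve with two coefficients: `base_cost`, the cost per person
#' (per person-year for the stock-based activities) at maximal support
#' intensity, and `steepness` `k > 0`, which controls the convexity of the
#' curve. Scalars are recycled across the four activities; a named vector
#' over `initial_reach`, `delayed_reach`, `maintenance`, `reengagement`
#' sets them per activity.
#'
#' @param base_cost Cost units per person (or per person-year); >= 0.
#'   Scalar, or named vector over the four activities.
#' @param steepness Dimensionless curve steepness k > 0. Scalar or named
#'   vector as for `base_cost`.
#' @return An object of class `cost_parameters`: a list with numeric
#'   vectors `base_cost` and `steepness`, each named by activity.
#' @examples
#' cost_parameters()
#' cost_parameters(base_cost = c(initial_reach = 2, delayed_reach = 1,
#'                               maintenance = 1, reengagement = 1))
#' @export
cost_parameters <- function(base_cost = 1, steepness = 3) {
  expand <- function(v, what) {
    if (length(v) == 1 && is.null(names(v))) {
      v <- stats::setNames(rep(as.numeric(v), 4), cost_activities)
    } else {
      if (!all(cost_activities %in% names(v))) {
        stop("'", what, "' must be a scalar or a named vector over: ",
          paste(cost_activities, collapse = ", "),
          call. = FALSE
        )
      }
      v <- as.numeric(v[cost_activities])
      names(v) <- cost_activities
    }
    v
  }
  out <- structure(
    list(
      base_cost = expand(base_cost, "base_cost"),
      steepness = expand(steepness, "steepness")
    ),
    class = "cost_parameters"
  )
  validate_cost_parameters(out)
  out
}

#' @keywords internal
validate_cost_parameters <- function(costs) {
  if (!is.list(costs) || !all(c("base_cost", "steepness") %in% names(costs))) {
    stop("cost parameters must carry 'base_cost' and 'steepness'", call. = FALSE)
  }
  if (any(!is.finite(costs$base_cost)) || any(costs$base_cost < 0)) {
    stop("'base_cost' must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(costs$steepness)) || any(costs$steepness <= 0)) {
    stop("'steepness' must be finite and > 0", call. = FALSE)
  }
  invisible(costs)
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat("Activity cost curves: c0 * (exp(k*theta) - 1) / (exp(k) - 1)\n")
  for (a in cost_activities) {
    cat(sprintf("  %-14s base_cost %g, k %g%s\n", a,
                x$base_cost[[a]], x$steepness[[a]],
                if (a == "maintenance") "  (theta = 1 - p_disengage)" else ""))
  }
  invisible(x)
}

#' Unit cost of an increasing support target
#'
#' The per-person cost of delivering a support activity at target intensity
#' `target` follows the normalised exponential curve
#' `base_cost * (exp(k * target) - 1) / (exp(k) - 1)`:
#' zero at a zero target, `base_cost` at full intensity, strictly increasing
#' and convex in between. An unsupported pathway (target 0) therefore incurs
#' no cost at all.
#'
#' @param target Support intensity in \[0, 1\] (an annual effective
#'   fraction the organisation aims to achieve).
#' @param base_cost Cost units per person at full intensity; >= 0.
#' @param steepness Curve steepness k > 0.
#' @return Cost units per person (vectorised over `target`).
#' @examples
#' unit_cost_increasing(c(0, 0.5, 1), base_cost = 1, steepness = 3)
#' @export
unit_cost_increasing <- function(target, base_cost = 1, steepness = 3) {
  if (any(!is.finite(target)) || any(target < 0) || any(target > 1)) {
    stop("cost-curve target must lie in [0, 1]", call. = FALSE)
  }
  base_cost * expm1(steepness * target) / expm1(steepness)
}

#' Unit cost of retention support
#'
#' Lower disengagement requires more intensive retention effort, so the
#' retention unit cost decreases exponentially in the disengagement
#' fraction: `base_cost * (exp(k * (1 - p_disengage)) - 1) / (exp(k) - 1)`.
#' It equals `base_cost` when disengagement is driven to 0 (maximal
#' retention support) and 0 when disengagement is 1 (no retention effort).
#'
#' @param p_disengage Annual disengagement fraction in \[0, 1\].
#' @param base_cost Cost units per participant-year at maximal support.
#' @param steepness Curve steepness k > 0.
#' @return Cost units per participant-year (vectorised over `p_disengage`).
#' @examples
#' unit_cost_retention(c(0, 0.5, 1), base_cost = 1, steepness = 3)
#' @export
unit_cost_retention <- function(p_disengage, base_cost = 1, steepness = 3) {
  if (any(!is.finite(p_disengage)) || any(p_disengage < 0) || any(p_disengage > 1)) {
    stop("'p_disengage' must lie in [0, 1]", call. = FALSE)
  }
  unit_cost_increasing(1 - p_disengage, base_cost, steepness)
}

# Per-person unit costs for the four activities at the parameter point
# `params` (they depend only on the support intensities, so they are
# computed once per simulation, not per step).
unit_costs_for <- function(params, costs) {
  list(
    initial_reach = unit_cost_increasing(
      params$p_initial_reach,
      costs$base_cost[["initial_reach"]], costs$steepness[["initial_reach"]]
    ),
    delayed_reach = unit_cost_increasing(
      params$p_delayed_reach,
      costs$base_cost[["delayed_reach"]], costs$steepness[["delayed_reach"]]
    ),
    maintenance = unit_cost_retention(
      params$p_disengage,
      costs$base_cost[["maintenance"]], costs$steepness[["maintenance"]]
    ),
    reengagement = unit_cost_increasing(
      params$p_reengage,
      costs$base_cost[["reengagement"]], costs$steepness[["reengagement"]]
    )
  )
}

#' Cost increment for one simulation step
#'
#' Prices the support activities delivered during one step of length `dt`
#' years. Initial reach is charged per person crossing the flow (an event
#' cost); delayed-reach and re-engagement support are charged per
#' person-year of the pool they act on (the not-initially-participating and
#' disengaged stocks at step start); retention support is charged per
#' participant-year. Each activity's unit price comes from its cost curve
#' at the configured support intensity, so an unsupported pathway
#' (intensity 0) accrues nothing.
#'
#' @param state_at_step_start The [stock_state()] before the step.
#' @param flows Named numeric flow vector for the step, as returned by
#'   [engagement_step()].
#' @param params A [program_parameters()] object.
#' @param costs A [cost_parameters()] object.
#' @param dt Step length in years (default `1/params$steps_per_year`).
#' @return Named numeric vector with `initial_reach_cost`,
#'   `delayed_reach_cost`, `maintenance_cost`, `reengagement_cost` and
#'   `total`.
#' @examples
#' p <- program_parameters(p_initial_reach = 0.5, p_disengage = 0.3)
#' st <- initial_state(p)
#' stp <- engagement_step(st, p)
#' accrue_step_cost(st, stp$flows, p, cost_parameters())
#' @export
accrue_step_cost <- function(state_at_step_start, flows, params, costs,
                             dt = 1 / params$steps_per_year) {
  validate_parameters(params)
  validate_state(state_at_step_start)
  validate_cost_parameters(costs)
  unit <- unit_costs_for(params, costs)
  inc <- c(
    unit$initial_reach * flows[["initial_reach"]],
    unit$delayed_reach * state_at_step_start[["not_initially_participating"]] * dt,
    unit$maintenance * state_at_step_start[["participating"]] * dt,
    unit$reengagement * state_at_step_start[["disengaged"]] * dt
  )
  stats::setNames(c(inc, sum(inc)), c(cost_activity_columns, "total"))
}

#' Cumulative implementation cost of a trajectory
#'
#' Component-wise sum of every step's cost increment: the cumulative spend
#' on each support activity over the simulated horizon, and their total.
#'
#' @param trajectory A `program_trajectory` from [simulate_program()].
#' @return Named numeric vector with the four per-activity cumulative costs
#'   and `total` (cost units).
#' @examples
#' traj <- simulate_program(program_parameters(p_initial_reach = 0.5))
#' cumulative_cost(traj)
#' @export
cumulative_cost <- function(trajectory) {
  if (!inherits(trajectory, "program_trajectory")) {
    stop("'trajectory' must be a program_trajectory", call. = FALSE)
  }
  colSums(trajectory$cost_increments)
}
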