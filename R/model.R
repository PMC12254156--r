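#' Convert an annual effective fraction to a per-step fraction
#'
#' The model's transition proportions are annual *effective* fractions: the
#' share of a stock that has left after one full simulated year. With
#' `steps_per_year` updates per year, the per-step fraction `q` must satisfy
#' `1 - (1 - q)^steps_per_year = p`, i.e. `q = 1 - (1 - p)^(1/steps_per_year)`.
#' Dividing `p` by the number of steps instead would understate the annual
#' depletion (e.g. an annual 0.94 would become roughly 0.62/year); the
#' compounding form reproduces the annual fraction exactly.
#'
#' @param p Annual effective fraction in \[0, 1\].
#' @param steps_per_year Integer >= 1.
#' @return Per-step fraction `q` in \[0, 1\]; `p = 1` maps to `q = 1` (the
#'   whole source stock moves in a single step).
#' @examples
#' annual_to_step_fraction(0.94, 12) # ~0.2090
#' 1 - (1 - annual_to_step_fraction(0.94, 12))^12 # 0.94
#' @export
annual_to_step_fraction <- function(p, steps_per_year) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("annual fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(steps_per_year < 1)) {
    stop("steps_per_year must be >= 1", call. = FALSE)
  }
  1 - (1 - p)^(1 / steps_per_year)
}

# One elementwise update of the difference equations, vectorised over
# parallel simulations (every argument a vector of common length).
# Within-step order: (1) exposure (clipped at the unaware stock) fills the
# not-engaged transit stock; (2) the whole transit stock splits by the
# initial-reach fraction; (3)-(5) delayed reach, disengagement and
# re-engagement are computed from the step-start values of their source
# stocks, so no flow sees a same-step inflow. Conservation is exact.
step_core <- function(U, NE, NIP, P, D, exposure_per_step, p_r, q_l, q_x, q_e) {
  exposure <- pmin(exposure_per_step, U)
  pool <- NE + exposure
  initial_reach <- p_r * pool
  non_uptake <- pool - initial_reach
  delayed_reach <- q_l * NIP
  disengagement <- q_x * P
  reengagement <- q_e * D
  list(
    U = U - exposure,
    NE = pool - initial_reach - non_uptake, # identically 0; kept for clarity
    NIP = NIP + non_uptake - delayed_reach,
    P = P + initial_reach + delayed_reach + reengagement - disengagement,
    D = D + disengagement - reengagement,
    flows = cbind(
      exposure = exposure, initial_reach = initial_reach,
      non_uptake = non_uptake, delayed_reach = delayed_reach,
      disengagement = disengagement, reengagement = reengagement
    )
  )
}

#' Advance the engagement pathway by one step
#'
#' Applies a single fixed-step update of length `1/steps_per_year` years.
#' Within a step the flows are resolved in a fixed order: the constant
#' exposure flow (clipped at the available unaware stock) moves people into
#' the not-engaged transit stock; the entire transit stock is then split
#' between immediate participation (fraction `p_initial_reach`) and the
#' not-initially-participating pool; delayed reach, disengagement and
#' re-engagement each move a per-step fraction of their source stock,
#' evaluated at its step-start value so that no outflow acts on a same-step
#' inflow. The update conserves the total head-count exactly.
#'
#' @param state A [stock_state()].
#' @param params A [program_parameters()] object.
#' @return A list with components `state` (the new `stock_state`) and
#'   `flows` (named numeric vector of the six flows, persons moved this
#'   step: `exposure`, `initial_reach`, `non_uptake`, `delayed_reach`,
#'   `disengagement`, `reengagement`).
#' @examples
#' p <- program_parameters()
#' engagement_step(initial_state(p), p)$flows["exposure"] # 150/12 = 12.5
#' @export
engagement_step <- function(state, params) {
  validate_parameters(params)
  validate_state(state, params)
  spy <- params$steps_per_year
  out <- step_core(
    U = state[["unaware"]], NE = state[["not_engaged"]],
    NIP = state[["not_initially_participating"]],
    P = state[["participating"]], D = state[["disengaged"]],
    exposure_per_step = params$exposure_rate / spy,
    p_r = params$p_initial_reach,
    q_l = annual_to_step_fraction(params$p_delayed_reach, spy),
    q_x = annual_to_step_fraction(params$p_disengage, spy),
    q_e = annual_to_step_fraction(params$p_reengage, spy)
  )
  new_state <- stock_state(
    unaware = out$U, not_engaged = out$NE,
    not_initially_participating = out$NIP,
    participating = out$P, disengaged = out$D
  )
  list(state = new_state, flows = out$flows[1, ])
}

#' Simulate the full engagement trajectory
#'
#' Integrates the five-stock pathway from an initial state (by default the
#' whole population unaware) over `horizon_years * steps_per_year` fixed
#' steps, recording the stock state at every time point, the six flows for
#' every step, and the per-activity cost increments priced by the activity
#' cost curves in `costs`.
#'
#' @param params A [program_parameters()] object.
#' @param costs A [cost_parameters()] object used to price each step's
#'   support activity; see [accrue_step_cost()].
#' @param init Optional starting [stock_state()]; defaults to
#'   [initial_state()] for `params`. Supplying a custom state (e.g. a seeded
#'   disengaged cohort) is the standard way to study an isolated pathway.
#' @return An object of class `program_trajectory`: a list with
#'   \describe{
#'     \item{times}{numeric vector of time points (years), length
#'       `n_steps + 1`, starting at 0}
#'     \item{states}{`(n_steps + 1) x 5` matrix of stocks, one row per time
#'       point}
#'     \item{flows}{`n_steps x 6` matrix of persons moved per step}
#'     \item{cost_increments}{`n_steps x 5` matrix: the four per-activity
#'       cost increments and their `total`, per step}
#'     \item{params, costs}{the inputs, for provenance}
#'   }
#' @examples
#' traj <- simulate_program(program_parameters(p_initial_reach = 0.5,
#'                                             p_disengage = 0.2))
#' participation_proportion(traj)
#' @export
simulate_program <- function(params = program_parameters(),
                             costs = cost_parameters(),
                             init = initial_state(params)) {
  validate_parameters(params)
  validate_state(init, tol = 1e-9)
  validate_cost_parameters(costs)
  spy <- as.integer(params$steps_per_year)
  n_steps <- as.integer(round(params$horizon_years * spy))
  dt <- 1 / spy

  q_l <- annual_to_step_fraction(params$p_delayed_reach, spy)
  q_x <- annual_to_step_fraction(params$p_disengage, spy)
  q_e <- annual_to_step_fraction(params$p_reengage, spy)
  unit <- unit_costs_for(params, costs)

  states <- matrix(0, nrow = n_steps + 1, ncol = 5,
                   dimnames = list(NULL, stock_names))
  flows <- matrix(0, nrow = n_steps, ncol = 6,
                  dimnames = list(NULL, flow_names))
  cost_inc <- matrix(0, nrow = n_steps, ncol = 5,
                     dimnames = list(NULL, c(cost_activity_columns, "total")))
  states[1, ] <- as.numeric(init[stock_names])

  U <- states[1, "unaware"]; NE <- states[1, "not_engaged"]
  NIP <- states[1, "not_initially_participating"]
  P <- states[1, "participating"]; D <- states[1, "disengaged"]
  exposure_per_step <- params$exposure_rate / spy

  for (i in seq_len(n_steps)) {
    out <- step_core(U, NE, NIP, P, D, exposure_per_step,
                     params$p_initial_reach, q_l, q_x, q_e)
    inc <- c(
      unit$initial_reach * out$flows[1, "initial_reach"],
      unit$delayed_reach * NIP * dt,
      unit$maintenance * P * dt,
      unit$reengagement * D * dt
    )
    cost_inc[i, ] <- c(inc, sum(inc))
    U <- out$U; NE <- out$NE; NIP <- out$NIP; P <- out$P; D <- out$D
    states[i + 1, ] <- c(U, NE, NIP, P, D)
    flows[i, ] <- out$flows[1, ]
  }

  structure(
    list(
      times = seq(0, by = dt, length.out = n_steps + 1),
      states = states,
      flows = flows,
      cost_increments = cost_inc,
      params = params,
      costs = costs
    ),
    class = "program_trajectory"
  )
}

#' @export
print.program_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  final <- x$states[n, ]
  cat(sprintf(
    "Engagement trajectory: %d time points over %g years (%d steps/year)\n",
    n, x$params$horizon_years, as.integer(x$params$steps_per_year)
  ))
  cat("  final stocks: ",
      paste(sprintf("%s=%.1f", names(final), final), collapse = ", "), "\n")
  cat(sprintf(
    "  final participation %.3f, cumulative cost %.1f\n",
    participation_proportion(x), cumulative_cost(x)[["total"]]
  ))
  invisible(x)
}

#' Proportion of the population participating
#'
#' Reach outcome: the number of individuals in the participating stock
#' divided by the total population. For a trajectory the proportion is read
#' at the final time point unless `time_index` selects another row.
#'
#' @param x A [stock_state()] or a `program_trajectory`.
#' @param params A [program_parameters()] object (required for a bare state;
#'   ignored for a trajectory, which carries its own).
#' @param time_index Row of the trajectory to evaluate (default: last).
#' @return Fraction in \[0, 1\].
#' @examples
#' p <- program_parameters()
#' participation_proportion(stock_state(participating = 1250,
#'                                      unaware = 3750, params = p), p) # 0.25
#' @export
participation_proportion <- function(x, params = NULL, time_index = NULL) {
  if (inherits(x, "program_trajectory")) {
    i <- if (is.null(time_index)) nrow(x$states) else time_index
    return(x$states[[i, "participating"]] / x$params$total_population)
  }
  if (is.null(params)) {
    stop("'params' is required when 'x' is a stock state", call. = FALSE)
  }
  validate_state(x)
  x[["participating"]] / params$total_population
}
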