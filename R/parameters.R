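#' Model parameters for the engagement pathway
#'
#' Bundles the global constants of the stock-and-flow model: the closed
#' population size, the constant exposure flow, the four annual effective
#' transition fractions, and the integration settings. Calling
#' `program_parameters()` with no arguments returns the reference
#' configuration used throughout: a population of 5000 initially unaware
#' individuals, exposure of 150 persons/year, a 50-year horizon integrated
#' with 12 equation updates per year, and all four proportions set to 0 (no
#' uptake, no disengagement, no support strategies).
#'
#' The four proportions are *annual effective* fractions: `p_disengage = 0.3`
#' means 30% of the participating stock disengages over one full model year,
#' regardless of the sub-annual step size. See
#' [annual_to_step_fraction()] for the per-step conversion.
#'
#' @param total_population Closed population size (persons), > 0.
#' @param exposure_rate Constant exposure flow (persons/year), >= 0. Moves
#'   people from the unaware stock to the not-engaged transit stock until the
#'   unaware stock is exhausted.
#' @param p_initial_reach Annual fraction of newly exposed individuals who
#'   immediately participate, in \[0, 1\].
#' @param p_disengage Annual effective fraction of participants who disengage,
#'   in \[0, 1\].
#' @param p_delayed_reach Annual effective fraction of the
#'   not-initially-participating pool that joins later (delayed reach),
#'   in \[0, 1\].
#' @param p_reengage Annual effective fraction of the disengaged pool that
#'   resumes participation, in \[0, 1\].
#' @param steps_per_year Integer >= 1; number of equation updates per
#'   simulated year (step length is `1/steps_per_year` years).
#' @param horizon_years Simulated horizon (years), > 0.
#'
#' @return An object of class `program_parameters` (a validated named list).
#' @examples
#' params <- program_parameters()
#' params$total_population  # 5000
#' program_parameters(p_initial_reach = 0.5, p_disengage = 0.3)
#' @export
program_parameters <- function(total_population = 5000,
                               exposure_rate = 150,
                               p_initial_reach = 0,
                               p_disengage = 0,
                               p_delayed_reach = 0,
                               p_reengage = 0,
                               steps_per_year = 12,
                               horizon_years = 50) {
  params <- list(
    total_population = total_population,
    exposure_rate = exposure_rate,
    p_initial_reach = p_initial_reach,
    p_disengage = p_disengage,
    p_delayed_reach = p_delayed_reach,
    p_reengage = p_reengage,
    steps_per_year = steps_per_year,
    horizon_years = horizon_years
  )
  validate_parameters(params)
  structure(params, class = "program_parameters")
}

#' @keywords internal
validate_parameters <- function(params) {
  stopifnot(is.list(params))
  needed <- c(
    "total_population", "exposure_rate", "p_initial_reach", "p_disengage",
    "p_delayed_reach", "p_reengage", "steps_per_year", "horizon_years"
  )
  missing <- setdiff(needed, names(params))
  if (length(missing) > 0) {
    stop("parameters missing field(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  for (nm in needed) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  for (nm in c("p_initial_reach", "p_disengage", "p_delayed_reach", "p_reengage")) {
    if (params[[nm]] < 0 || params[[nm]] > 1) {
      stop("parameter '", nm, "' must lie in [0, 1], got ", params[[nm]],
        call. = FALSE
      )
    }
  }
  if (params$total_population <= 0) {
    stop("parameter 'total_population' must be > 0", call. = FALSE)
  }
  if (params$exposure_rate < 0) {
    stop("parameter 'exposure_rate' must be >= 0", call. = FALSE)
  }
  if (params$steps_per_year < 1 || params$steps_per_year != round(params$steps_per_year)) {
    stop("parameter 'steps_per_year' must be an integer >= 1", call. = FALSE)
  }
  if (params$horizon_years <= 0) {
    stop("parameter 'horizon_years' must be > 0", call. = FALSE)
  }
  invisible(params)
}

#' @export
print.program_parameters <- function(x, ...) {
  cat("Engagement pathway parameters\n")
  cat(sprintf("  population        %g persons\n", x$total_population))
  cat(sprintf("  exposure          %g persons/year\n", x$exposure_rate))
  cat(sprintf(
    "  annual fractions  initial reach %.3f | disengage %.3f | delayed reach %.3f | re-engage %.3f\n",
    x$p_initial_reach, x$p_disengage, x$p_delayed_reach, x$p_reengage
  ))
  cat(sprintf(
    "  integration       %g years, %d steps/year (dt = %.4f yr)\n",
    x$horizon_years, as.integer(x$steps_per_year), 1 / x$steps_per_year
  ))
  invisible(x)
}

stock_names <- c(
  "unaware", "not_engaged", "not_initially_participating",
  "participating", "disengaged"
)

flow_names <- c(
  "exposure", "initial_reach", "non_uptake", "delayed_reach",
  "disengagement", "reengagement"
)

#' Stock state of the engagement pathway
#'
#' A stock state is a named numeric vector of head-counts in the five
#' engagement compartments. `stock_state()` builds and validates one;
#' `initial_state()` returns the model's starting condition, with the whole
#' population in the unaware stock and every other stock empty.
#'
#' @param unaware,not_engaged,not_initially_participating,participating,disengaged
#'   Head-counts (persons), each >= 0.
#' @param params A [program_parameters()] object; when supplied to
#'   `stock_state()` the stocks must additionally sum to `total_population`.
#' @return A named numeric vector of class `stock_state` with components
#'   `unaware`, `not_engaged`, `not_initially_participating`,
#'   `participating`, `disengaged`.
#' @examples
#' initial_state(program_parameters())
#' stock_state(disengaged = 1000)
#' @export
stock_state <- function(unaware = 0, not_engaged = 0,
                        not_initially_participating = 0,
                        participating = 0, disengaged = 0,
                        params = NULL) {
  state <- c(
    unaware = unname(unaware), not_engaged = unname(not_engaged),
    not_initially_participating = unname(not_initially_participating),
    participating = unname(participating), disengaged = unname(disengaged)
  )
  class(state) <- "stock_state"
  validate_state(state, params)
  state
}

#' @rdname stock_state
#' @export
initial_state <- function(params = program_parameters()) {
  stock_state(unaware = params$total_population, params = params)
}

#' @keywords internal
validate_state <- function(state, params = NULL, tol = 1e-9) {
  if (!is.numeric(state) || length(state) != 5 ||
    !all(stock_names %in% names(state))) {
    stop("a stock state must be a numeric vector with components ",
      paste(stock_names, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!is.finite(state))) {
    stop("stock state contains non-finite values", call. = FALSE)
  }
  if (any(state < -tol)) {
    bad <- names(state)[state < -tol][1]
    stop("stock '", bad, "' is negative (", state[[bad]], ")", call. = FALSE)
  }
  if (!is.null(params)) {
    n <- params$total_population
    if (abs(sum(state) - n) > tol * max(1, n)) {
      stop(
        "stocks sum to ", sum(state), " but total_population is ", n,
        call. = FALSE
      )
    }
  }
  invisible(state)
}
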