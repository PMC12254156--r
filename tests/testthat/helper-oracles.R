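# Independent single-step oracle: recomputes one update of the difference
# equations directly from the stated flow rules, deliberately kept separate
# from the package's integrator so the two can disagree.
naive_step <- function(state, params) {
  spy <- params$steps_per_year
  q <- function(p) 1 - (1 - p)^(1 / spy)
  exposure <- min(params$exposure_rate / spy, state[["unaware"]])
  pool <- state[["not_engaged"]] + exposure
  ir <- params$p_initial_reach * pool
  nu <- pool - ir
  dl <- q(params$p_delayed_reach) * state[["not_initially_participating"]]
  dx <- q(params$p_disengage) * state[["participating"]]
  re <- q(params$p_reengage) * state[["disengaged"]]
  c(
    unaware = state[["unaware"]] - exposure,
    not_engaged = 0,
    not_initially_participating =
      state[["not_initially_participating"]] + nu - dl,
    participating = state[["participating"]] + ir + dl + re - dx,
    disengaged = state[["disengaged"]] + dx - re
  )
}

random_parameters <- function() {
  program_parameters(
    total_population = 5000,
    exposure_rate = runif(1, 0, 400),
    p_initial_reach = runif(1),
    p_disengage = runif(1),
    p_delayed_reach = runif(1),
    p_reengage = runif(1),
    steps_per_year = sample(c(1, 4, 12), 1),
    horizon_years = sample(3:10, 1)
  )
}
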