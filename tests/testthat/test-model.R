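test_that("reference parameters carry the model's defaults and validation rejects bad values", {
  p <- program_parameters()
  expect_equal(p$total_population, 5000)
  expect_equal(p$exposure_rate, 150)
  expect_equal(p$steps_per_year, 12)
  expect_equal(p$horizon_years, 50)
  expect_equal(
    c(p$p_initial_reach, p$p_disengage, p$p_delayed_reach, p$p_reengage),
    c(0, 0, 0, 0)
  )

  expect_error(program_parameters(p_disengage = 1.5), "p_disengage")
  expect_error(program_parameters(p_reengage = -0.1), "p_reengage")
  expect_error(program_parameters(total_population = 0), "total_population")
  expect_error(program_parameters(steps_per_year = 2.5), "steps_per_year")
  expect_error(program_parameters(horizon_years = 0), "horizon_years")
  expect_error(program_parameters(exposure_rate = -1), "exposure_rate")
})

test_that("annual-to-step conversion compounds back to the annual effective fraction", {
  expect_identical(annual_to_step_fraction(0, 12), 0)
  expect_identical(annual_to_step_fraction(1, 12), 1)

  # closed form: q solves (1-q)^12 = 1 - 0.94
  q <- annual_to_step_fraction(0.94, 12)
  expect_equal(q, 0.2089949, tolerance = 1e-6)
  expect_equal((1 - q)^12, 0.06, tolerance = 1e-12)

  # compounding identity across a range of fractions and step counts
  for (p in seq(0, 1, by = 0.1)) {
    for (spy in c(1, 4, 12, 52)) {
      q <- annual_to_step_fraction(p, spy)
      expect_equal(1 - (1 - q)^spy, p, tolerance = 1e-9)
    }
  }

  expect_error(annual_to_step_fraction(1.2, 12), "\\[0, 1\\]")
  expect_error(annual_to_step_fraction(-0.01, 12), "\\[0, 1\\]")
})

test_that("a single step moves the right head-counts and conserves the population", {
  p <- program_parameters()
  s0 <- initial_state(p)

  # pure exposure: 150/12 = 12.5 persons move into the transit stock
  out <- engagement_step(s0, p)
  expect_equal(out$state[["unaware"]], 5000 - 150 / 12)
  expect_equal(out$flows[["exposure"]], 12.5)
  expect_equal(sum(out$state), sum(s0))

  # inert model: nothing moves
  p0 <- program_parameters(exposure_rate = 0)
  s <- stock_state(
    unaware = 3500, not_initially_participating = 500,
    participating = 900, disengaged = 100
  )
  out0 <- engagement_step(s, p0)
  expect_equal(as.numeric(out0$state), as.numeric(s))
  expect_true(all(out0$flows == 0))

  # the transit stock empties completely every step
  pr <- program_parameters(p_initial_reach = 0.3)
  out1 <- engagement_step(initial_state(pr), pr)
  expect_equal(out1$state[["not_engaged"]], 0)
  expect_equal(out1$flows[["initial_reach"]], 0.3 * 12.5)
  expect_equal(out1$flows[["non_uptake"]], 0.7 * 12.5)

  expect_error(engagement_step(stock_state(unaware = 1), p), "total_population")
})

test_that("step agrees with an independently coded one-step oracle on random states", {
  set.seed(42)
  for (i in 1:25) {
    params <- random_parameters()
    shares <- as.vector(stats::rmultinom(1, 5000, runif(5)))
    s <- stock_state(
      unaware = shares[1], not_engaged = shares[2],
      not_initially_participating = shares[3],
      participating = shares[4], disengaged = shares[5],
      params = params
    )
    got <- engagement_step(s, params)
    want <- naive_step(s, params)
    expect_equal(as.numeric(got$state), as.numeric(want[names(got$state)]),
      tolerance = 1e-12
    )
    expect_true(all(got$flows >= 0))
    # no flow exceeds its source stock at step start (transit pool for the split)
    expect_lte(got$flows[["exposure"]], s[["unaware"]] + 1e-12)
    expect_lte(
      got$flows[["delayed_reach"]],
      s[["not_initially_participating"]] + 1e-12
    )
    expect_lte(got$flows[["disengagement"]], s[["participating"]] + 1e-12)
    expect_lte(got$flows[["reengagement"]], s[["disengaged"]] + 1e-12)
  }
})

test_that("trajectories conserve the population, stay non-negative, and are step-reproducible", {
  set.seed(7)
  for (i in 1:10) {
    params <- random_parameters()
    traj <- simulate_program(params)
    n_steps <- params$horizon_years * params$steps_per_year
    expect_equal(length(traj$times), n_steps + 1)
    expect_equal(nrow(traj$flows), n_steps)
    expect_true(all(abs(rowSums(traj$states) - 5000) <= 1e-9 * 5000))
    expect_true(all(traj$states >= -1e-9))
    # re-applying the public single-step map reproduces each recorded state
    for (j in sample(n_steps, 5)) {
      s <- stock_state(
        unaware = traj$states[j, "unaware"],
        not_engaged = traj$states[j, "not_engaged"],
        not_initially_participating =
          traj$states[j, "not_initially_participating"],
        participating = traj$states[j, "participating"],
        disengaged = traj$states[j, "disengaged"]
      )
      out <- engagement_step(s, params)
      expect_equal(as.numeric(out$state), as.numeric(traj$states[j + 1, ]),
        tolerance = 1e-9
      )
      expect_equal(as.numeric(out$flows), as.numeric(traj$flows[j, ]),
        tolerance = 1e-9
      )
    }
  }
})

test_that("degenerate settings reproduce closed-form trajectories", {
  # no exposure: the state never changes
  p <- program_parameters(exposure_rate = 0, p_disengage = 0.5)
  traj <- simulate_program(p)
  expect_true(all(traj$states[, "unaware"] == 5000))
  expect_true(all(traj$states[, c(2:5)] == 0))

  # full immediate uptake: unaware depletes linearly, everyone participates
  # (5000 / 150 = 33.3 years < 50-year horizon)
  pf <- program_parameters(p_initial_reach = 1)
  trajf <- simulate_program(pf)
  expect_equal(participation_proportion(trajf), 1)
  expect_equal(trajf$states[[13, "unaware"]], 5000 - 150)

  # isolated cohort decay: source stock after t whole years = n0 * (1-p)^t
  for (prob in c(0.2, 0.94)) {
    pd <- program_parameters(exposure_rate = 0, p_disengage = prob,
                             horizon_years = 5)
    trajd <- simulate_program(pd, init = stock_state(participating = 1000))
    for (t in 1:5) {
      expect_equal(
        trajd$states[[t * 12 + 1, "participating"]],
        1000 * (1 - prob)^t,
        tolerance = 1e-9
      )
    }
  }
})

test_that("per-step decay compounds to the annual fraction over one year of steps", {
  for (prob in c(0.1, 0.5, 0.94)) {
    q <- annual_to_step_fraction(prob, 12)
    remaining <- 1000
    for (i in 1:12) remaining <- remaining * (1 - q)
    expect_equal(remaining, 1000 * (1 - prob), tolerance = 1e-9)
  }
})

test_that("participation proportion is the participating share of the population", {
  p <- program_parameters()
  expect_equal(participation_proportion(initial_state(p), p), 0)
  s <- stock_state(unaware = 3750, participating = 1250, params = p)
  expect_equal(participation_proportion(s, p), 0.25)
  expect_error(participation_proportion(s), "params")
})

test_that("final participation responds monotonically to reach, disengagement and re-engagement", {
  grid <- seq(0, 1, by = 0.1)
  # no-support setting: more initial reach can only add participants
  up_reach <- vapply(grid, function(r) {
    participation_proportion(simulate_program(
      program_parameters(p_initial_reach = r, p_disengage = 0.3)
    ))
  }, numeric(1))
  expect_true(all(diff(up_reach) >= -1e-12))

  # more disengagement can only lose them
  down_diseng <- vapply(grid, function(x) {
    participation_proportion(simulate_program(
      program_parameters(p_initial_reach = 0.5, p_disengage = x)
    ))
  }, numeric(1))
  expect_true(all(diff(down_diseng) <= 1e-12))

  # stronger re-engagement support can only recover more of the disengaged
  up_reeng <- vapply(grid, function(e) {
    participation_proportion(simulate_program(
      program_parameters(p_initial_reach = 0.5, p_disengage = 0.5,
                         p_reengage = e)
    ))
  }, numeric(1))
  expect_true(all(diff(up_reeng) >= -1e-12))
})
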