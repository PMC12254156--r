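---
title: "Engagement dynamics, support strategies and the cost of delivering a public health program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engagement dynamics, support strategies and the cost of delivering a public health program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reaimsd)
```

## The model

`reaimsd` simulates how a closed population engages with a public health
program, viewed through the individual-level domains of the RE-AIM framework
(reach and maintenance) and the implementation domain's cost of delivery.
The population moves along a one-way awareness pathway with a
two-way engagement cycle at its end, through five stocks:

* **unaware** — has not yet heard of the program;
* **not engaged** — just exposed, decision pending (a transit stock, see
  below);
* **not initially participating** — declined at first contact, but reachable
  later through a supported *delayed reach* pathway;
* **participating** — actively engaged (the reach outcome is this stock
  divided by the population);
* **disengaged** — dropped out, recoverable through a supported
  *re-engagement* pathway.

Six flows connect the stocks: constant-rate exposure, the initial-reach /
non-uptake split, delayed reach, disengagement, and re-engagement. The state
is integrated with explicit fixed-step difference equations — by default 12
updates per simulated year over a 50-year horizon — which mirrors how
stock-and-flow engines advance a model, rather than solving a continuous-time
ODE. There is no stochastic component anywhere: every result is exactly
reproducible.

### Annual effective fractions

All four transition proportions are **annual effective fractions**: the
share of a source stock that has left after one whole year, whatever the
step size. The per-step fraction is therefore

$$q = 1 - (1 - p)^{1/s},$$

with $s$ steps per year, so that twelve steps of isolated decay reproduce
$p$ exactly. Dividing by $s$ instead would badly understate fast flows: an
annual 94% split into $0.94/12$ per month would deplete only about 62% of
the stock in a year. The boundary $p = 1$ maps to $q = 1$ — the whole stock
moves in a single step — which is the degenerate corner of the sweep grid.

```{r}
q <- annual_to_step_fraction(0.94, 12)
c(per_step = q, check = 1 - (1 - q)^12)
```

### Within-step ordering and the transit stock

A fixed evaluation order makes every run bit-reproducible:

1. exposure moves `min(exposure_rate * dt, unaware)` persons into the
   not-engaged transit stock (exposure halts when nobody is left to reach —
   there is no refill mechanism);
2. the entire transit stock (arrivals included) is split immediately:
   fraction `p_initial_reach` starts participating, the rest move to the
   not-initially-participating pool;
3. delayed reach, disengagement and re-engagement each move a per-step
   fraction of their source stock, evaluated at its *step-start* value, so
   no outflow acts on a same-step inflow.

Treating "not engaged" as a one-step transit stock is a deliberate design
choice: its initial value is zero and the engagement narrative says newly
exposed individuals either participate or remain unengaged, so holding
people in it would require an undocumented dwell rate. The split fraction is
applied to the pool directly (not converted per step), because each person
faces the decision once, on arrival.

These choices imply exact conservation — the five stocks sum to the
population at every step, to machine precision — and non-negativity, both
enforced as invariants and covered by property tests.

## Cost curves

Each support activity has a per-person unit cost that grows with the
intensity the organisation targets, on the normalised exponential curve

$$c(\theta) = c_0\,\frac{e^{k\theta} - 1}{e^{k} - 1},$$

which is 0 at $\theta = 0$, $c_0$ at $\theta = 1$, and convex in between —
pushing a target towards 100% gets disproportionately expensive. Retention
(maintenance) support uses the mirrored, negative-exponential form
$c(1 - p_{\text{disengage}})$: driving disengagement to zero is the costly
extreme, while letting everyone go costs nothing. The normalisation to zero
at zero intensity matters: an unsupported pathway must accrue *no* cost, so
the no-support scenario is genuinely cheaper rather than cheaper by a
constant.

Accrual bases, chosen to reflect which pool each activity serves:

* **initial reach** — an event cost per person crossing the initial-reach
  flow;
* **delayed reach** and **re-engagement** — per person-year of the pool the
  support acts on (the not-initially-participating and disengaged stocks);
* **retention** — per participant-year.

The published description fixes the curve shapes but not their
coefficients, so the defaults ($c_0 = 1$ cost unit, $k = 3$) were chosen
once as the simplest visibly convex setting; every qualitative cost
ordering reported below is robust at that setting, and both coefficients
are configurable per activity. Costs are undiscounted.

## Scenarios and the grid sweep

Four presets fix the two supported pathways while initial reach and
disengagement sweep an inclusive, evenly spaced grid over [0, 1]:

```{r}
for (s in scenario_presets()) print(s)
```

The high-support value 0.94/year for delayed reach and re-engagement is the
study condition the presets encode. The grid resolution is an
implementation choice (the source material only says the two axes are swept
between 0 and 100%); the default 21 points per axis reproduces every
qualitative surface feature in about a second, and the sweep is vectorised
across grid cells so a 101-point grid remains cheap.

```{r}
grids <- lapply(names(scenario_presets()), run_grid, grid_resolution = 21)
names(grids) <- names(scenario_presets())
round(sapply(grids, function(g) mean(g$cost)))
```

Two summary metrics condense the surfaces. `dominance_ratio()` compares the
mean participation range across disengagement (reach fixed) with the mean
range across reach (disengagement fixed); above 1, disengagement is the
dominant axis. A constant surface returns 1 by convention (neither axis
dominates). `high_participation_cells()` counts grid cells at or above a
participation threshold.

```{r}
c(no_support = dominance_ratio(grids$no_support),
  reengagement = dominance_ratio(grids$reengagement_support))
sapply(grids, high_participation_cells, threshold = 0.8)
```

Without support, disengagement dominates and high participation survives
only in the high-reach/low-disengagement corner; re-engagement support
pulls the ratio back towards parity, and combining both strategies yields
by far the most high-participation combinations — at the highest overall
cost, because supported individuals cycle between engagement and
disengagement and each pass through a supported pathway is paid for.

## Design choices where the design was open

* **Overall scenario cost.** "Cheapest/dearest scenario" is compared by the
  *mean* cumulative cost over the grid. The grid *maximum* is uninformative
  here: every scenario's maximum sits at (reach = 1, disengagement = 0),
  where the delayed-reach and re-engagement pools are empty, so all four
  maxima coincide exactly.
* **Monotonicity of participation.** Final participation is provably
  non-decreasing in initial reach only when no delayed-reach pathway
  operates: with strong delayed reach and high disengagement, joining
  *earlier* means more time to disengage before the horizon, so higher
  initial reach can slightly lower participation at year 50. The
  monotonicity properties are therefore asserted under the no-support
  setting (and under re-engagement support for the re-engagement axis).
* **Retention vs. cycling costs.** At full reach, total cost under
  re-engagement support is U-shaped in disengagement: retention spending
  dominates at low disengagement, cycling costs at high disengagement. The
  cycling claim — more disengagement means more paid re-engagement — shows
  up cleanly in the re-engagement cost component, which rises monotonically
  with disengagement.
* **Low-reach cost elevation under enhanced reach** holds at every positive
  disengagement level; at exactly zero disengagement retention spending
  reverses the comparison (low reach delays entry into participation and so
  reduces participant-years).
* **Numerical tolerances.** Conservation and closed-form checks are held to
  1e-9 (relative for the population sum); the model itself involves no
  iterative numerics, so no looser tolerance is needed.

## What the simulations do and do not show

The population, rates and costs are hypothetical study conditions, not
calibrated to a real program: the model is a proof of concept for reasoning
about implementation dynamics, and the passing checks demonstrate internal
consistency (conservation, annual-fraction semantics, closed-form cohort
decay) and the qualitative surface shapes — not predictions for any real
program. Known structural limits, inherent to cohort-level stock-and-flow
modelling: individuals carry no memory, so every disengaged person is
equally likely to re-engage regardless of how often they have cycled;
effectiveness and adoption are held constant; costs are undiscounted; and
exposure simply stops when the unaware pool is exhausted.

## Problem sizes

The examples and tests use the reference configuration (5000 persons,
600 steps) and 21×21 grids — about a million stock updates for a four-
scenario sweep, which the vectorised sweep completes in roughly a second.
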