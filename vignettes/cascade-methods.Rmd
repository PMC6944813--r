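---
title: "Methods: cascade projection, programs and budget optimization in casckit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascade projection, programs and budget optimization in casckit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casckit)
```

## The model and its assumptions

`casckit` represents a care cascade as a deterministic discrete-time
compartmental model. The cascade's bars are *stages*; each stage is declared
as the sum of one or more *compartments*, the mutually exclusive states a
person can occupy. This decomposition is what lets a bar chart become a
dynamical model: transitions move people between compartments, and stage
values are recovered at any time as exact sums of compartment sizes.

The update rule is an explicit (forward) step. At each step all transition
flows are computed from the start-of-step state and applied simultaneously;
there is no within-step ordering of transitions, so results are independent
of the order in which transitions are declared. Two parameter formats govern
flows:

* `probability_per_year` — an annual risk `p`, converted to a per-step
  probability `1 - (1 - p)^dt` so sub-annual steps compound correctly. At
  the default `dt = 1` year the conversion is the identity and one step
  reproduces annual bookkeeping arithmetic exactly, which is why annual
  stepping is the default: cascade data are almost always annual, and the
  model's printed tables should be auditable by hand.
* `number_per_year` — an absolute event rate, scaled linearly by `dt`
  (events, not risks, accumulate linearly in time).

A third format, `proportion`, holds dimensionless inputs (such as an annual
retention fraction) that feed formulas or program effects but cannot govern
a transition directly.

Parameters either come from the databook as per-population annual time
series — linearly interpolated inside their data range and held constant
outside it, so a single observed year acts as a constant — or are derived by
formulas declared in the framework. The formula grammar is deliberately
minimal: identifiers (parameter and compartment codes), numeric literals,
`+ - * /`, parentheses, `min`, `max` and `exp`. Functional dependencies are
all the declarative files need; conditionals would turn a declarative model
description into a program. Formulas are compiled once into a topologically
ordered plan, and cycles are reported as validation errors naming the codes
involved.

Sources and sinks are explicit compartment roles rather than inferred from
topology, so conservation is assertable: at every step the change in total
population equals source inflows minus sink outflows to machine precision,
and the test suite checks this on randomized models. Transitions out of a
source must be `number_per_year` (a source has no size for a probability to
act on).

## Outflow capping

When a compartment's proposed outflows exceed what it can supply, all of its
outflows are rescaled by a common factor, preserving their ratios. The
supply is the compartment's starting size *plus its same-step inflows*, and
the rescaling iterates to a fixed point (scales only decrease, so the
iteration converges; 200 iterations and a 1e-13 change tolerance are far
beyond what any practical model needs). The inflow-inclusive convention
matters for number-format flows layered by programs: a counseling program
that moves 510 people out of a 525-person compartment in a year is feasible
when ~200 people also enter that compartment during the year, and annual
cohort arithmetic treats it as such. Capping on starting size alone would
spuriously throttle such programs at annual steps. With no inflows the rule
reduces to the simple one: two outflows proposing 60 + 60 from a compartment
of 100 are rescaled to 50 + 50 and the compartment empties without going
negative.

## Programs

Spending becomes coverage through a linear unit-cost function,
`covered = spending / unit_cost` (currency per person covered per year),
optionally truncated by a capacity cap. No curvature is modelled — unit-cost
data rarely support one, and linearity keeps every program table auditable.
Coverage for *blend* effects is additionally capped at the current size of
the program's eligible compartments, since a covered fraction above 1 is
meaningless. Conversion-flow coverage is deliberately not capped at the
eligible pool: screening programs routinely test more people than are
prevalent-and-undiagnosed, and the conversion chain's yield absorbs the
excess; the engine's outflow capping still protects the compartments
themselves.

Blend effects replace the target parameter with
`f * value_covered + (1 - f) * value_uncovered`, where `f` is the covered
fraction of the eligible pool at the current state. Multiple blend programs
on one parameter are treated as non-overlapping until their combined
fraction reaches 1, at which point it is capped with a warning — the
simplest auditable rule in the absence of overlap data. Retention-style
inputs are converted to the loss probabilities the transitions are defined
on (88%/96% retained becomes 12%/4% lost), which is why the demonstration
framework carries retention as a `proportion` databook parameter and derives
`loss_rate` by the formula `1 - retention`.

Conversion effects add `covered × Π(chain)` persons/year to a target
transition, unrounded; all rounding (half away from zero) happens only in
reporting. Efficacies quoted "within *k* months" are interpreted as applying
to the annual cohort covered — a program counseling 600 people per year with
30% attaining control moves 180 people per year.

## The demonstration projects

`build_hypertension_demo()` encodes a four-stage hypertension cascade with a
2016 baseline of 4096 prevalent cases (1708 diagnosed, 1183 treated, 440
controlled), 255 incident cases/year, annual mortality 18.8/1000 reduced to
13.3/1000 under blood-pressure control, 88% annual treatment retention, and
six programs. The three testing modalities deliver 2580 tests/year split
55% / 40% / 5% across pharmacies ($5/test, 3.5% yield, 20% immediate
treatment initiation), clinics ($20, 3.5%, 90%) and outreach ($15, 15%,
70%), so their baseline coverages are 1419, 1032 and 129 tests. That split
is the internally consistent basis: it is exactly consistent with the
published one-year projection of this cascade, whereas the rounded coverage
counts sometimes quoted alongside it (1430/1000/150) shift the projected
diagnosed stage by a few persons. Treatment counseling ($25, 110 counseled,
all initiate), adherence counseling ($25, 200 counseled, 30% attain
control) and retention enhancement ($25, 600 covered, retention 88%→96%)
complete the set. The demo spans 2016–2017 at `dt = 1`.

`build_generic_demo()` is the minimal three-compartment testing/treatment
cascade with testing ($10/test, 1000 tested), initiation ($18, 800) and
adherence ($30, 300 enrolled) programs. Its effect sizes (10% test yield,
loss probability 0.15/year reduced to 0.05 among enrollees) and initial
sizes (6000 / 1500 / 900) are illustrative package choices, chosen once to
give all three programs non-trivial marginal impact over a five-year
horizon.

These demonstrations emulate the *accounting* structure of real cascade
data: annual flows, program unit costs and coverages, blended efficacies.
They do not emulate measurement error, seasonality, multi-population mixing,
nonlinear cost curves, or behavioural feedback; tests passing on them show
the bookkeeping, program arithmetic and optimization machinery are correct,
not that any particular real cascade is well described by linear unit costs
or constant annual risks.

## Scenarios

A scenario perturbs program spending (absolute series, or deltas applied as
a step function from a start year) and is compared against the baseline
projection. The baseline always runs with programs at their program-book
spending, not with programs disabled — "no change" rows in a comparison
table are then genuinely the baseline. Percent improvements are
`(scenario - baseline)/baseline × 100`, rounded half away from zero, with
exactly unchanged values printed as `-` and nonpositive baselines reported
as undefined rather than raising.

## Optimization

An optimization combines three independent parts:

* **Objective** — maximize a stage at evaluation year(s); minimize losses;
  or minimize the funding needed to hit a stage target. All objectives are
  minimized internally (maximization is negated) so every algorithm sees one
  contract.
* **Adjustment** — immediate one-off reallocation; delayed (effective from a
  change year); time-varying (independent shares per breakpoint period); or
  start-year (search over the year a fixed reallocation happens). The
  start-year variable is a handful of discrete years, so it is scanned
  exhaustively rather than relaxed to a continuous variable.
* **Constraints** — per-program lower/upper spending bounds (constant or
  time-varying) and a total budget. Feasibility is restored by clipping to
  bounds and multiplicatively rescaling the unclamped entries to the budget,
  iterated to a fixed point; the projection is idempotent and hits the total
  to 1e-9 relative. Infeasible bound/budget combinations fail before any
  simulation runs.

Decision variables are spending levels per (program, period) — equivalently
budget shares scaled by the total — because "what share of the budget goes
to each intervention" is the question planners actually ask. A single
adjustable program is a degenerate case solved without search.

"Minimize losses" needs an operational definition, and two are provided.
*Endpoint drop-offs* are the gaps between adjacent stage sizes at the
evaluation year; with equal weights they telescope to first-stage minus
last-stage, which nearly duplicates maximizing the final stage, so equal
weights are rarely what a loss-minimizer means. *Cumulative flow* losses
count persons traversing transitions marked `loss` in the framework (loss to
follow-up) over the whole run; at short horizons this metric responds only
to programs that act on the loss probability itself. The demonstration's
loss objective therefore uses endpoint drop-offs weighted by the number of
downstream stages each gap forfeits (3/2/1 for a four-stage cascade) —
equivalently, it minimizes the total stage-attainment shortfall, crediting a
program for every stage boundary it helps people cross. Under that
objective the demonstration prioritizes treatment counseling, the cheapest
mover of people across a stage boundary, while pure loss-flow accounting
would always favour the retention program and stage-maximization would
favour adherence counseling; all three readings are exposed through
`objective_minimize_losses()`.

The native solver is Adaptive Stochastic Descent: sample one of the `2n`
signed coordinate directions with probability proportional to learned
weights; step, project to feasibility, and accept only improvements; grow
the accepted direction's step (×2) and weight (×2), shrink rejected ones
(×0.5), renormalizing weights with a 1e-6 floor. Defaults — initial step 10%
of each variable's range, growth 2, shrink 0.5 — are the standard settings
for this algorithm family and are exposed in `optimizer_config()`. Runs are
bit-reproducible given the seed. Stopping combines an evaluation budget with
a patience rule (consecutive evaluations without relative improvement above
a tolerance). Exhaustive grid search over budget compositions and uniform
random search share the projection hook and serve as cross-checks, and an
external-adapter slot accepts any third-party minimizer with the same
contract; particle-swarm and Bayesian backends are intentionally not
reimplemented.

Budget minimization for a target runs an outer bisection on a total-budget
multiplier in `[0, 1]`, with the inner optimizer maximizing the target stage
at each trial budget; the bracket closes below 0.1% of the upper budget,
attainability is verified at the full budget first (with the shortfall
reported if it fails), and an already-met target returns a zero budget
without search.

## Numerical conventions and degenerate inputs

* Internal state is continuous; stage counts and percent improvements are
  rounded half away from zero only at presentation (composing rounded values
  would accumulate error).
* Time grids require `dt` to divide the horizon (1e-9 tolerance); a
  zero-length run returns only the initial state.
* An empty compartment proposes zero outflows; negative parameter values
  are errors, not clamped.
* Validation returns a report of all errors and warnings rather than
  stopping at the first; non-nested cascade stages are warnings, not errors,
  because backward-moving and restart-at-beginning cascades are legitimate
  designs.
* Ties in grid search and the start-year scan resolve to the first (lowest)
  candidate.

## Problem sizes

The bundled analyses are desk-scale by design: the hypertension model has
four normal compartments, ten transitions and a one-year horizon; the
generic model three compartments over five years. The test suite's
optimizer comparisons use 2–3 program toys with grids of at most a few
hundred compositions and ASD budgets of a few hundred evaluations, and the
property suites use a few dozen randomized models — sizes chosen so the full
suite documents the machinery while running in well under a minute of
simulation time.

## Known limitations

No transmission dynamics or interaction between populations; no nonlinear
cost curves or program synergies; no discounting or cost-savings accounting;
no stochastic or agent-based simulation; optimization objectives are
cascade-shaped only (no deaths/DALY objectives). The delimited-table dialect
is the normative input format; spreadsheet workbooks would be an import
layer, not a semantic change.
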