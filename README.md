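# casckit

Care cascades (continuums of care) track the ordered stages of engagement on
the path to a successful health outcome — e.g. *all people with hypertension →
diagnosed → on treatment → blood pressure controlled* — as successive bars of
the population attaining each stage. `casckit` is an R toolkit for analysts
and health-program planners who need to go beyond plotting those bars: it
projects how a cascade will evolve over time, quantifies how intervention
budgets move people through it, and finds the budget allocation that best
serves a chosen cascade objective.

## The model

A cascade is expressed as a discrete-time compartmental model. Each cascade
stage is the sum of one or more **mutually exclusive compartments** (so
"Diagnosed" = "diagnosed, not treated" + "treated, not controlled" +
"controlled"). Transitions between compartments are governed by parameters in
one of two formats: an annual probability *p* moves `size × (1 − (1 − p)^dt)`
persons per step of length `dt` years, and an annual number *n* moves
`n × dt`. Parameters are entered per population in a databook, or derived from
other parameters and compartment sizes by formulas declared in the framework.
All flows in a step are drawn simultaneously from the start-of-step state; if
a compartment's proposed outflow exceeds what is available to it that step,
its outflows are rescaled proportionally so it can empty but never goes
negative. Persons are conserved exactly: sizes change only through
transitions, source inflows (e.g. incidence) and sink outflows (e.g. death).

Intervention **programs** sit on top of the dynamics. Spending is converted
to coverage through a linear unit-cost function, `covered = spending /
unit_cost` (truncated at capacity and, for blended effects, at the eligible
population), and coverage acts in one of two ways:

* **coverage blend** — the target parameter becomes the coverage-weighted
  mean `f·v_covered + (1 − f)·v_uncovered`, e.g. a retention program lowering
  the loss-to-follow-up probability from 12%/year to 4%/year among those it
  covers;
* **conversion flow** — `covered × Π(chain)` persons/year are moved along a
  target transition, e.g. a screening program whose tests have a 3.5%
  diagnosis yield, 20% of positives starting treatment immediately.

**Scenarios** perturb program budgets against a baseline projection.
**Optimizations** combine an objective (maximize a stage; minimize cascade
losses; minimize funding to hit a target), an adjustment (what may change,
and when) and constraints (per-program bounds plus a total budget), solved
with a native Adaptive Stochastic Descent (ASD) optimizer behind a
clip-rescale feasibility projection, with exhaustive grid search and random
search as cross-checking backends and an adapter for external minimizers.

## Worked example

The bundled hypertension demonstration encodes a four-stage cascade observed
in 2016 — 4096 prevalent cases, 1708 diagnosed, 1183 treated, 440 controlled
— with 255 new cases/year, mortality of 18.8/1000 (13.3/1000 once
controlled), 88% annual treatment retention, and six programs (three testing
modalities, treatment counseling, adherence counseling, retention
enhancement).

```r
library(casckit)
project <- build_hypertension_demo()
sim <- run_project(project)                      # programs at baseline budgets
report_cascade(extract_cascade(sim, project$framework, 2017))
#> all_hypertension        diagnosed          treated       controlled
#>             4276             1783             1235              459

scen <- run_scenario(project,
  scenario_spec("more_adherence",
                list(adherence_counseling = list(delta = 10000))),
  baseline = sim)
scenario_comparison(scen, 2017)[4, c("stage", "scenario_report", "improvement")]
#>        stage scenario_report improvement
#> 4 controlled             579         26%
```

The projection says the cascade grows to 4276 prevalent cases in 2017 (4.4%
net growth: 255 incident cases against 75 deaths), with 459 people controlled
under baseline budgets; adding $10,000/year to adherence counseling lifts
that to 579, a 26% improvement. Priorities depend on the objective:

```r
rank_single_program_increments(project,
  hypertension_demo_objectives()$maximize_diagnosed, 10000)$program[1]
#> [1] "outreach_testing"
```

Adherence counseling ranks first for maximizing control, outreach testing for
maximizing diagnoses, and treatment counseling for minimizing cascade losses
— both by exhaustive single-program grid and by ASD.

A command-line interface wraps the same functions (see `?cli_main`):

```sh
inst/cli/casckit demo --name hypertension --out proj/
inst/cli/casckit simulate --project proj/ --t0 2016 --t1 2017
```

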