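#' Build the hypertension demonstration project
#'
#' A four-stage hypertension care cascade (all prevalent cases, diagnosed,
#' on treatment, controlled) over four mutually exclusive compartments plus
#' an incidence source and a death sink, with 2016 initial conditions from a
#' large Malawi community study: 4096 prevalent cases, of whom 1708
#' diagnosed, 1183 on treatment and 440 with controlled blood pressure.
#' Incidence contributes 255 new cases/year; annual mortality is 18.8/1000,
#' reduced to 13.3/1000 with blood-pressure control; baseline treatment
#' retention is 88%/year (the loss-to-follow-up probability is derived by
#' formula as `1 - retention`).
#'
#' Six programs operate on the cascade. 2580 blood-pressure tests/year are
#' delivered through pharmacies (55% of tests, $5/test, 3.5% yield, 20% of
#' positives start treatment immediately), clinics (40%, $20, 3.5% yield,
#' 90% immediate initiation) and outreach (5%, $15, 15% yield, 70%
#' immediate initiation); treatment & lifestyle counseling ($25/person, 110
#' counseled, all start treatment); adherence & lifestyle counseling
#' ($25/person, 200 counseled, 30% attain control within the year); and
#' retention enhancement ($25/person, 600 covered, raising retention from
#' 88% to 96% among those covered).
#'
#' @return A [cascade_project()] spanning 2016-2017 at `dt = 1`.
#' @export
build_hypertension_demo <- function() {
  fw <- cascade_framework(
    name = "hypertension",
    compartments = data.frame(
      code = c("new_cases", "undx", "dx", "tx", "ctrl", "dead"),
      label = c("Incident cases", "Undiagnosed", "Diagnosed, not treated",
                "Treated, not controlled", "Controlled", "Deceased"),
      role = c("source", "normal", "normal", "normal", "normal", "sink"),
      stringsAsFactors = FALSE),
    transitions = data.frame(
      from = c("new_cases", "undx", "dx", "tx", "tx", "ctrl",
               "undx", "dx", "tx", "ctrl"),
      to = c("undx", "dx", "tx", "ctrl", "dx", "dx",
             "dead", "dead", "dead", "dead"),
      parameter = c("incidence", "testing_rate", "initiation_rate",
                    "control_rate", "loss_rate", "loss_rate",
                    "death_std", "death_std", "death_std", "death_ctrl"),
      loss = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
               FALSE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE),
    parameters = data.frame(
      code = c("incidence", "testing_rate", "initiation_rate", "control_rate",
               "retention", "loss_rate", "death_std", "death_ctrl"),
      label = c("New cases per year", "Background diagnoses per year",
                "Background treatment initiations per year",
                "Background control attainment per year",
                "Annual treatment retention",
                "Annual probability of loss to follow-up",
                "Annual death probability (uncontrolled)",
                "Annual death probability (controlled)"),
      format = c("number_per_year", "number_per_year", "number_per_year",
                 "number_per_year", "proportion", "probability_per_year",
                 "probability_per_year", "probability_per_year"),
      formula = c("", "", "", "", "", "1 - retention", "", ""),
      databook_entry = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE),
    stages = data.frame(
      name = c("all_hypertension", "diagnosed", "treated", "controlled"),
      constituents = c("undx;dx;tx;ctrl", "dx;tx;ctrl", "tx;ctrl", "ctrl"),
      stringsAsFactors = FALSE))

  pop <- "adults"
  parset <- cascade_parset(pop, stats::setNames(list(list(
    incidence = 255, testing_rate = 0, initiation_rate = 0, control_rate = 0,
    retention = 0.88, death_std = 0.0188, death_ctrl = 0.0133)), pop))
  initial <- cascade_state(2016, matrix(
    c(2388, 525, 743, 440), nrow = 1,
    dimnames = list(pop, c("undx", "dx", "tx", "ctrl"))))

  # 2580 tests/year split 55% / 40% / 5% across the delivery modalities
  tests <- 2580
  mk_test_prog <- function(code, label, share, unit_cost, yield, init_frac) {
    cascade_program(
      code, label, unit_cost, eligible = "undx",
      coverage_data = cascade_ts(2016, tests * share),
      spending_data = cascade_ts(2016, tests * share * unit_cost),
      effects = list(program_effect_conversion("undx", "dx", yield),
                     program_effect_conversion("dx", "tx",
                                               c(yield, init_frac))))
  }
  progset <- cascade_progset(list(
    mk_test_prog("pharmacy_testing", "Pharmacy testing", 0.55, 5, 0.035, 0.20),
    mk_test_prog("clinic_testing", "Clinic testing", 0.40, 20, 0.035, 0.90),
    mk_test_prog("outreach_testing", "Outreach testing", 0.05, 15, 0.15, 0.70),
    cascade_program(
      "treatment_counseling", "Treatment & lifestyle counseling", 25,
      eligible = "dx",
      coverage_data = cascade_ts(2016, 110),
      spending_data = cascade_ts(2016, 2750),
      effects = list(program_effect_conversion("dx", "tx", 1.0))),
    cascade_program(
      "adherence_counseling", "Adherence & lifestyle counseling", 25,
      eligible = "tx",
      coverage_data = cascade_ts(2016, 200),
      spending_data = cascade_ts(2016, 5000),
      effects = list(program_effect_conversion("tx", "ctrl", 0.30))),
    cascade_program(
      "retention_program", "Retention enhancement initiatives", 25,
      eligible = c("tx", "ctrl"),
      coverage_data = cascade_ts(2016, 600),
      spending_data = cascade_ts(2016, 15000),
      effects = list(program_effect_blend("loss_rate",
                                          value_covered = 1 - 0.96,
                                          value_uncovered = 1 - 0.88)))))

  cascade_project(fw, parset, initial, progset,
                  settings = list(t0 = 2016, t1 = 2017, dt = 1))
}

#' Build the generic testing/treatment demonstration project
#'
#' The minimal three-compartment treatment cascade (undiagnosed; diagnosed,
#' not on treatment; currently treated) with testing, treatment-initiation
#' and loss-to-follow-up transitions and three programs: a testing program
#' at $10/test covering 1000 tests/year, a treatment-initiation program at
#' $18/person covering 800 initiations/year, and an adherence program at
#' $30/person covering 300 enrollees/year that reduces the probability of
#' loss to follow-up among those enrolled. Illustrative effect sizes (10%
#' test yield; loss probability 0.15/year reduced to 0.05 among adherence
#' enrollees) and initial compartment sizes are package choices for the
#' demonstration.
#'
#' @return A [cascade_project()] spanning 2020-2025 at `dt = 1`.
#' @export
build_generic_demo <- function() {
  fw <- cascade_framework(
    name = "generic_treatment",
    compartments = data.frame(
      code = c("undx", "dx", "tx"),
      label = c("Undiagnosed", "Diagnosed, not treated", "Currently treated"),
      role = "normal", stringsAsFactors = FALSE),
    transitions = data.frame(
      from = c("undx", "dx", "tx"),
      to = c("dx", "tx", "dx"),
      parameter = c("testing_rate", "initiation_rate", "loss_rate"),
      loss = c(FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE),
    parameters = data.frame(
      code = c("testing_rate", "initiation_rate", "loss_rate"),
      label = c("Background diagnoses per year",
                "Background initiations per year",
                "Annual probability of loss to follow-up"),
      format = c("number_per_year", "number_per_year",
                 "probability_per_year"),
      formula = "", databook_entry = TRUE, stringsAsFactors = FALSE),
    stages = data.frame(
      name = c("all_cases", "diagnosed", "treated"),
      constituents = c("undx;dx;tx", "dx;tx", "tx"),
      stringsAsFactors = FALSE))

  pop <- "population"
  parset <- cascade_parset(pop, stats::setNames(list(list(
    testing_rate = 0, initiation_rate = 0, loss_rate = 0.15)), pop))
  initial <- cascade_state(2020, matrix(
    c(6000, 1500, 900), nrow = 1,
    dimnames = list(pop, c("undx", "dx", "tx"))))

  progset <- cascade_progset(list(
    cascade_program(
      "testing", "Testing program", 10, eligible = "undx",
      coverage_data = cascade_ts(2020, 1000),
      spending_data = cascade_ts(2020, 10000),
      effects = list(program_effect_conversion("undx", "dx", 0.10))),
    cascade_program(
      "initiation", "Treatment initiation program", 18, eligible = "dx",
      coverage_data = cascade_ts(2020, 800),
      spending_data = cascade_ts(2020, 14400),
      effects = list(program_effect_conversion("dx", "tx", 1.0))),
    cascade_program(
      "adherence", "Adherence program", 30, eligible = "tx",
      coverage_data = cascade_ts(2020, 300),
      spending_data = cascade_ts(2020, 9000),
      effects = list(program_effect_blend("loss_rate",
                                          value_covered = 0.05,
                                          value_uncovered = 0.15)))))

  cascade_project(fw, parset, initial, progset,
                  settings = list(t0 = 2020, t1 = 2025, dt = 1))
}

#' Demonstration optimization objectives for the hypertension project
#'
#' The three default objectives configured for the hypertension demo:
#' maximize the controlled stage, maximize the diagnosed stage, and
#' minimize cascade losses as endpoint drop-offs weighted by the number of
#' downstream stages each gap forfeits (3/2/1 for the four-stage cascade),
#' i.e. the total stage-attainment shortfall.
#'
#' @param year Evaluation year (default 2017).
#' @return Named list of `cascade_objective` objects.
#' @export
hypertension_demo_objectives <- function(year = 2017) {
  list(
    maximize_controlled = objective_maximize_stage("controlled", years = year),
    maximize_diagnosed = objective_maximize_stage("diagnosed", years = year),
    minimize_losses = objective_minimize_losses("endpoint_dropoff",
                                                weights = c(3, 2, 1),
                                                years = year))
}
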