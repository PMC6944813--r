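#' Specify a budget / coverage scenario
#'
#' A scenario perturbs program spending (or coverage) relative to the
#' baseline allocation and is compared against the baseline projection.
#' Changes are either absolute spending series or deltas applied as a step
#' function from a start year onward.
#'
#' @param name Scenario name.
#' @param changes Named list, program code -> either a [cascade_ts()] of
#'   absolute spending, or `list(delta = <currency/year>, start_year =
#'   <year>)`.
#' @param coverage_overrides Optional named list program -> persons-covered
#'   [cascade_ts()]; converted to spending via the program's unit cost.
#' @param horizon Optional `c(t0, t1)` overriding the project horizon.
#' @return An object of class `cascade_scenario_spec`.
#' @export
scenario_spec <- function(name, changes = list(), coverage_overrides = NULL,
                          horizon = NULL) {
  structure(list(name = name, changes = changes,
                 coverage_overrides = coverage_overrides, horizon = horizon),
            class = "cascade_scenario_spec")
}

scenario_allocation <- function(project, spec) {
  progset <- project$progset
  if (is.null(progset)) stop_ck("project has no programs; cannot run scenarios")
  alloc <- baseline_allocation(progset)
  for (pcode in names(spec$changes)) {
    if (!pcode %in% names(progset$programs)) {
      stop_ck("scenario '%s' references unknown program '%s'", spec$name, pcode)
    }
    ch <- spec$changes[[pcode]]
    if (is_cascade_ts(ch)) {
      alloc[[pcode]] <- ch
    } else if (is.list(ch) && !is.null(ch$delta)) {
      start <- ch$start_year %||% project$settings$t0
      alloc[[pcode]] <- ts_add_delta(alloc[[pcode]], ch$delta, start)
    } else if (is.numeric(ch) && length(ch) == 1L) {
      alloc[[pcode]] <- ts_add_delta(alloc[[pcode]], ch, project$settings$t0)
    } else {
      stop_ck("scenario '%s': unsupported change for program '%s'", spec$name,
              pcode)
    }
    if (any(alloc[[pcode]]$values < -1e-9)) {
      stop_ck("scenario '%s' drives spending on '%s' negative", spec$name,
              pcode)
    }
  }
  for (pcode in names(spec$coverage_overrides %||% list())) {
    prog <- progset$programs[[pcode]]
    if (is.null(prog)) {
      stop_ck("scenario '%s' references unknown program '%s'", spec$name, pcode)
    }
    cov <- as_cascade_ts(spec$coverage_overrides[[pcode]])
    alloc[[pcode]] <- cascade_ts(cov$years, cov$values * prog$unit_cost,
                                 cov$interpolation)
  }
  alloc
}

#' Run a scenario against the baseline projection
#'
#' The baseline is always simulated with baseline spending from the program
#' book (programs running, not disabled), so scenario improvements isolate
#' the allocation change. Supply a precomputed `baseline` to share one
#' baseline run across many scenarios.
#'
#' @param project A [cascade_project()] with programs.
#' @param spec A [scenario_spec()].
#' @param baseline Optional precomputed baseline `cascade_sim`.
#' @return An object of class `cascade_scenario_result` holding the spec,
#'   the scenario and baseline simulations, and the scenario allocation.
#' @export
run_scenario <- function(project, spec, baseline = NULL) {
  t0 <- (spec$horizon %||% c(project$settings$t0, project$settings$t1))[1]
  t1 <- (spec$horizon %||% c(project$settings$t0, project$settings$t1))[2]
  if (is.null(baseline)) {
    baseline <- run_project(project, t0 = t0, t1 = t1)
  }
  alloc <- scenario_allocation(project, spec)
  scen <- run_project(project, allocation = alloc, t0 = t0, t1 = t1)
  structure(list(spec = spec, baseline = baseline, scenario = scen,
                 allocation = alloc, framework = project$framework),
            class = "cascade_scenario_result")
}

#' @export
print.cascade_scenario_result <- function(x, ...) {
  cat(sprintf("<cascade_scenario_result '%s'>\n", x$spec$name))
  print(scenario_comparison(x, max(x$scenario$times)))
  invisible(x)
}

#' Percent improvement over baseline
#'
#' `(scenario - baseline) / baseline x 100`, rounded half-away-from-zero to
#' integer precision. An exactly unchanged value is reported as `"-"` by the
#' table formatters; a nonpositive baseline yields `NA` (undefined) rather
#' than an error.
#'
#' @param baseline,scenario Persons at a stage under each run.
#' @return Rounded percent (numeric; `NA` if baseline is not positive).
#' @export
percent_improvement <- function(baseline, scenario) {
  out <- ifelse(baseline > 0,
                round_half_out((scenario - baseline) / baseline * 100),
                NA_real_)
  as.numeric(out)
}

format_improvement <- function(baseline, scenario, tol = 1e-9) {
  ifelse(abs(scenario - baseline) <= tol * pmax(1, abs(baseline)), "-",
         ifelse(baseline > 0,
                sprintf("%d%%",
                        as.integer(percent_improvement(baseline, scenario))),
                "NA"))
}

#' Cascade comparison for one scenario
#'
#' @param result A `cascade_scenario_result`.
#' @param year Evaluation year.
#' @return `data.frame` with stage, baseline and scenario values (continuous
#'   and reported), and percent improvement.
#' @export
scenario_comparison <- function(result, year) {
  fw <- result$framework
  b <- extract_cascade(result$baseline, fw, year)
  s <- extract_cascade(result$scenario, fw, year)
  data.frame(stage = names(b), baseline = as.numeric(b),
             scenario = as.numeric(s),
             baseline_report = report_cascade(as.numeric(b)),
             scenario_report = report_cascade(as.numeric(s)),
             improvement = format_improvement(as.numeric(b), as.numeric(s)),
             stringsAsFactors = FALSE)
}

#' Scenario comparison table
#'
#' One row per scenario: the scenario's scaled budgets (for programs whose
#' allocation changed), and per-stage cascade values with percent
#' improvements over the shared baseline, shaped like a scale-up options
#' table.
#'
#' @param results List of `cascade_scenario_result` sharing one baseline.
#' @param year Evaluation year.
#' @return A `data.frame` (zero rows for an empty list).
#' @export
scenario_table <- function(results, year) {
  if (!length(results)) {
    return(data.frame(scenario = character(), scaled_budget = numeric(),
                      stringsAsFactors = FALSE))
  }
  b0 <- results[[1]]$baseline
  for (r in results) {
    if (!isTRUE(all.equal(r$baseline$sizes, b0$sizes))) {
      stop_ck("scenario results do not share a common baseline")
    }
  }
  fw <- results[[1]]$framework
  base <- extract_cascade(b0, fw, year)
  rows <- lapply(results, function(r) {
    changed <- names(r$spec$changes)
    budget <- sum(vapply(
      if (length(changed)) changed else names(r$allocation),
      function(p) ts_interpolate(r$allocation[[p]], year), 0))
    s <- extract_cascade(r$scenario, fw, year)
    row <- data.frame(scenario = r$spec$name, scaled_budget = budget,
                      stringsAsFactors = FALSE)
    for (st in names(base)) {
      row[[st]] <- report_cascade(s[[st]])
      row[[paste0(st, "_improvement")]] <- format_improvement(base[[st]],
                                                              s[[st]])
    }
    row
  })
  do.call(rbind, rows)
}
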