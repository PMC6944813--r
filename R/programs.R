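#' Define an intervention program
#'
#' A program converts spending into coverage through a linear unit-cost
#' function and converts coverage into model impact through its effects:
#' either a *coverage blend* (the target parameter becomes the
#' coverage-weighted mean of its covered and uncovered values, e.g. a
#' retention program lowering the loss-to-follow-up probability among those
#' covered) or a *conversion flow* (covered persons times a chain of
#' conversion fractions are moved along a target transition, e.g. a
#' screening program whose tests yield diagnoses, a fraction of which start
#' treatment immediately).
#'
#' @param code,label Program identifier and human-readable name.
#' @param unit_cost Currency per person covered per year; must be positive.
#' @param eligible Character vector of compartment codes the program reaches.
#' @param effects List of effects from [program_effect_blend()] /
#'   [program_effect_conversion()].
#' @param coverage_data,spending_data Optional [cascade_ts()] of persons
#'   covered and of currency spent per year. Where both are given they must
#'   be consistent (`spending = coverage x unit_cost` within 0.5%).
#' @param capacity Optional cap on persons covered per year.
#' @return An object of class `cascade_program`.
#' @export
cascade_program <- function(code, label, unit_cost, eligible, effects,
                            coverage_data = NULL, spending_data = NULL,
                            capacity = Inf) {
  if (!is_identifier(code)) stop_ck("program code '%s' is not a valid identifier", code)
  assert_number(unit_cost, "unit_cost", lower = .Machine$double.eps)
  if (!is.null(coverage_data)) coverage_data <- as_cascade_ts(coverage_data)
  if (!is.null(spending_data)) spending_data <- as_cascade_ts(spending_data)
  if (!is.null(coverage_data) && !is.null(spending_data)) {
    yrs <- intersect(coverage_data$years, spending_data$years)
    for (y in yrs) {
      cv <- ts_interpolate(coverage_data, y)
      sp <- ts_interpolate(spending_data, y)
      if (abs(sp - cv * unit_cost) > 0.005 * max(sp, cv * unit_cost, 1e-12)) {
        stop_ck("program '%s': spending %g inconsistent with coverage %g x unit cost %g in %g",
                code, sp, cv, unit_cost, y)
      }
    }
  }
  if (is.null(coverage_data) && is.null(spending_data)) {
    stop_ck("program '%s' needs coverage_data or spending_data", code)
  }
  for (e in effects) {
    if (!inherits(e, "cascade_effect")) stop_ck("effects must be program effects")
  }
  structure(list(code = code, label = label, unit_cost = unit_cost,
                 eligible = eligible, effects = effects,
                 coverage_data = coverage_data, spending_data = spending_data,
                 capacity = capacity),
            class = "cascade_program")
}

#' Program effects
#'
#' @param target_parameter Parameter code whose value the blend overrides.
#' @param value_covered,value_uncovered Parameter value among covered /
#'   uncovered persons, in the parameter's own format.
#' @return An object of class `cascade_effect`.
#' @rdname program_effect
#' @export
program_effect_blend <- function(target_parameter, value_covered,
                                 value_uncovered) {
  structure(list(mode = "coverage_blend", target_parameter = target_parameter,
                 value_covered = value_covered,
                 value_uncovered = value_uncovered),
            class = "cascade_effect")
}

#' @param from,to Compartment codes of the transition receiving the
#'   conversion flow.
#' @param chain Numeric vector of conversion fractions in `[0, 1]`,
#'   multiplied along the chain (e.g. test yield, then the fraction of
#'   positives initiating treatment).
#' @rdname program_effect
#' @export
program_effect_conversion <- function(from, to, chain) {
  if (any(chain < 0) || any(chain > 1)) {
    stop_ck("conversion fractions must lie in [0, 1]")
  }
  structure(list(mode = "conversion_flow", from = from, to = to,
                 chain = as.numeric(chain)),
            class = "cascade_effect")
}

#' Bundle programs into a program set
#'
#' @param programs List of [cascade_program()] objects.
#' @return An object of class `cascade_progset`.
#' @export
cascade_progset <- function(programs) {
  codes <- vapply(programs, `[[`, "", "code")
  if (anyDuplicated(codes)) stop_ck("duplicate program codes")
  names(programs) <- codes
  structure(list(programs = programs), class = "cascade_progset")
}

#' @export
print.cascade_progset <- function(x, ...) {
  cat(sprintf("<cascade_progset: %d program(s): %s>\n", length(x$programs),
              paste(names(x$programs), collapse = ", ")))
  invisible(x)
}

progset_check <- function(progset, fw) {
  for (p in progset$programs) {
    miss <- setdiff(p$eligible, fw$compartments$code)
    if (length(miss)) {
      stop_ck("program '%s' eligible compartment(s) unknown: %s", p$code,
              paste(miss, collapse = ", "))
    }
    for (e in p$effects) {
      if (e$mode == "coverage_blend") {
        if (!e$target_parameter %in% fw$parameters$code) {
          stop_ck("program '%s' targets unknown parameter '%s'", p$code,
                  e$target_parameter)
        }
      } else {
        tmatch <- fw$transitions$from == e$from & fw$transitions$to == e$to
        if (!any(tmatch)) {
          stop_ck("program '%s' targets unknown transition %s->%s", p$code,
                  e$from, e$to)
        }
      }
    }
  }
  invisible(TRUE)
}

#' Baseline budget allocation of a program set
#'
#' @param progset A [cascade_progset()].
#' @return Named list mapping program code to a spending [cascade_ts()],
#'   taken from the program book's spending data (or coverage times unit
#'   cost where only coverage was entered).
#' @export
baseline_allocation <- function(progset) {
  out <- lapply(progset$programs, function(p) {
    if (!is.null(p$spending_data)) return(p$spending_data)
    cascade_ts(p$coverage_data$years, p$coverage_data$values * p$unit_cost,
               p$coverage_data$interpolation)
  })
  structure(out, class = "cascade_budget")
}

allocation_spending <- function(allocation, program, year) {
  ts <- allocation[[program]]
  if (is.null(ts)) return(NA_real_)
  ts_interpolate(as_cascade_ts(ts), year)
}

#' Convert spending into persons covered
#'
#' Linear cost-coverage: `covered = spending / unit_cost`, truncated at an
#' optional capacity cap and at the eligible population (the latter applies
#' to coverage-blend effects, where a covered fraction above 1 is
#' meaningless; conversion-flow coverage is left uncapped because the
#' conversion chain's yield absorbs over-screening).
#'
#' @param spending Currency per year (nonnegative).
#' @param unit_cost Currency per person covered per year (positive).
#' @param eligible Eligible persons (default unbounded).
#' @param cap Capacity in persons per year (default unbounded).
#' @return Persons covered per year.
#' @export
coverage_from_budget <- function(spending, unit_cost, eligible = Inf,
                                 cap = Inf) {
  assert_number(unit_cost, "unit_cost", lower = .Machine$double.eps)
  if (any(spending < 0)) stop_ck("spending must be nonnegative")
  pmin(spending / unit_cost, cap, eligible)
}

#' Coverage-weighted parameter blend
#'
#' Effective parameter value when a fraction `f` of the eligible population
#' is covered: `f x value_covered + (1 - f) x value_uncovered`.
#'
#' @param value_covered,value_uncovered Parameter values among covered and
#'   uncovered persons.
#' @param fraction_covered Covered fraction in `[0, 1]`.
#' @return Effective parameter value.
#' @export
blend_parameter <- function(value_covered, value_uncovered, fraction_covered) {
  if (any(fraction_covered < 0) || any(fraction_covered > 1)) {
    stop_ck("fraction_covered must lie in [0, 1]")
  }
  fraction_covered * value_covered + (1 - fraction_covered) * value_uncovered
}

#' Persons transitioned by a conversion chain
#'
#' @param covered Persons covered per year.
#' @param chain Conversion fractions in `[0, 1]`, multiplied along the chain.
#' @return Persons transitioned per year (unrounded; rounding happens only
#'   in reporting).
#' @export
conversion_flow <- function(covered, chain) {
  if (any(chain < 0) || any(chain > 1)) {
    stop_ck("conversion fractions must lie in [0, 1]")
  }
  covered * prod(chain)
}

#' Apply programs to parameter values
#'
#' For each program, spending at `year` is read from the allocation
#' (falling back to baseline spending), converted to coverage, and turned
#' into effects: coverage-blend effects override the target parameter via
#' [blend_parameter()] with the eligible population equal to the current
#' size of the program's eligible compartments; conversion-flow effects add
#' number-format flows (persons/year) on their target transitions. Multiple
#' blend programs acting on one parameter combine by summing covered
#' fractions (capped at 1, with a warning if the cap binds) and taking the
#' coverage-weighted mean of their covered values.
#'
#' @param values Matrix (population x parameter) of evaluated parameter
#'   values before program effects.
#' @param fw The framework.
#' @param progset A [cascade_progset()].
#' @param allocation Named list program -> spending [cascade_ts()] (or
#'   single numbers); missing programs run at baseline spending.
#' @param state Current [cascade_state()] (eligible compartment sizes).
#' @param year Decimal year at which spending is evaluated.
#' @param index Internal engine index.
#' @return List with `values` (overridden matrix), `added_flows`
#'   (population x transition matrix, persons/year) and `coverage` (named
#'   persons covered per program).
#' @export
apply_programs <- function(values, fw, progset, allocation, state, year,
                           index = NULL) {
  if (is.null(index)) index <- fw_engine_index(fw)
  if (is.null(allocation)) allocation <- baseline_allocation(progset)
  pops <- rownames(state$sizes)
  added <- matrix(0, length(pops), length(index$from),
                  dimnames = list(pops, index$labels))
  blends <- list() # per target parameter: list of (f, value_covered, value_uncovered)
  coverage <- stats::setNames(numeric(length(progset$programs)),
                              names(progset$programs))

  for (p in progset$programs) {
    sp <- allocation_spending(allocation, p$code, year)
    if (is.na(sp)) sp <- ts_interpolate(baseline_allocation(progset)[[p$code]],
                                        year)
    elig_comps <- intersect(p$eligible, index$normal)
    elig_n <- sum(state$sizes[, elig_comps, drop = FALSE])
    cov_flow <- coverage_from_budget(sp, p$unit_cost, cap = p$capacity)
    cov_blend <- coverage_from_budget(sp, p$unit_cost, eligible = elig_n,
                                      cap = p$capacity)
    coverage[p$code] <- if (any(vapply(p$effects, `[[`, "", "mode") ==
                                "coverage_blend")) cov_blend else cov_flow
    for (e in p$effects) {
      if (e$mode == "coverage_blend") {
        f <- if (elig_n > 0) cov_blend / elig_n else 0
        blends[[e$target_parameter]] <-
          c(blends[[e$target_parameter]],
            list(list(f = f, vc = e$value_covered, vu = e$value_uncovered)))
      } else {
        persons <- conversion_flow(cov_flow, e$chain)
        j <- which(index$from == e$from & index$to == e$to)
        if (!length(j)) {
          stop_ck("program '%s': no transition %s->%s", p$code, e$from, e$to)
        }
        j <- j[1]
        # split across populations in proportion to the source compartment
        if (e$from %in% index$normal) {
          w <- state$sizes[, e$from]
          w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(pops), length(pops))
        } else {
          w <- rep(1 / length(pops), length(pops))
        }
        added[, j] <- added[, j] + persons * w
      }
    }
  }

  for (pcode in names(blends)) {
    parts <- blends[[pcode]]
    fs <- vapply(parts, `[[`, 0, "f")
    ftot <- sum(fs)
    if (ftot > 1) {
      warn_ck("combined covered fraction for parameter '%s' exceeds 1; capped",
              pcode)
      ftot <- 1
    }
    vc_bar <- if (sum(fs) > 0) sum(fs * vapply(parts, `[[`, 0, "vc")) / sum(fs)
              else 0
    vu_bar <- if (sum(fs) > 0) sum(fs * vapply(parts, `[[`, 0, "vu")) / sum(fs)
              else vapply(parts, `[[`, 0, "vu")[1]
    values[, pcode] <- blend_parameter(vc_bar, vu_bar, ftot)
  }
  list(values = values, added_flows = added, coverage = coverage)
}

#' Program summary table
#'
#' A program-book-shaped summary at a given year and allocation: spending,
#' persons covered, and each effect's impact in persons/year (conversion
#' chains multiplied out; blend effects reported as effective parameter
#' value and implied persons moved from the eligible pool).
#'
#' @param project A [cascade_project()].
#' @param allocation Optional allocation (default baseline).
#' @param year Evaluation year (default project start).
#' @return A `data.frame` with one row per (program, effect).
#' @export
program_summary <- function(project, allocation = NULL,
                            year = project$settings$t0) {
  fw <- project$framework
  progset <- project$progset
  if (is.null(allocation)) allocation <- baseline_allocation(progset)
  index <- fw_engine_index(fw)
  state <- project$initial
  values <- evaluate_parameters(fw, project$parset, state)
  eff <- apply_programs(values, fw, progset, allocation, state, year, index)
  rows <- list()
  for (p in progset$programs) {
    sp <- allocation_spending(allocation, p$code, year)
    for (e in p$effects) {
      if (e$mode == "conversion_flow") {
        impact <- conversion_flow(coverage_from_budget(sp, p$unit_cost,
                                                       cap = p$capacity),
                                  e$chain)
        rows[[length(rows) + 1L]] <- data.frame(
          program = p$code, spending = sp, covered = eff$coverage[[p$code]],
          unit_cost = p$unit_cost, effect = sprintf("%s->%s", e$from, e$to),
          impact_persons = impact, effective_value = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        elig_n <- sum(state$sizes[, intersect(p$eligible, index$normal),
                                  drop = FALSE])
        v <- eff$values[1, e$target_parameter]
        fmt <- fw$parameters$format[fw$parameters$code == e$target_parameter]
        impact <- if (fmt == "probability_per_year") v * elig_n else v
        rows[[length(rows) + 1L]] <- data.frame(
          program = p$code, spending = sp, covered = eff$coverage[[p$code]],
          unit_cost = p$unit_cost,
          effect = sprintf("param:%s", e$target_parameter),
          impact_persons = impact, effective_value = v,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
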