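#' Parameter set: databook values per population
#'
#' Holds one [cascade_ts()] per (population, databook parameter). Formula
#' parameters are not stored; they are evaluated at run time from the
#' compiled plan.
#'
#' @param populations Character vector of population codes.
#' @param data Nested list: `data[[population]][[parameter]]` is a
#'   `cascade_ts` (a single number is promoted to a constant series).
#' @return An object of class `cascade_parset`.
#' @export
cascade_parset <- function(populations, data) {
  if (!length(populations)) stop_ck("need at least one population")
  data <- data[populations]
  for (pop in populations) {
    if (is.null(data[[pop]])) stop_ck("no parameter data for population '%s'", pop)
    data[[pop]] <- lapply(data[[pop]], as_cascade_ts)
  }
  structure(list(populations = populations, data = data),
            class = "cascade_parset")
}

# Every databook parameter must be present for every population.
parset_check <- function(parset, fw) {
  needed <- fw$parameters$code[fw$parameters$databook_entry]
  for (pop in parset$populations) {
    miss <- setdiff(needed, names(parset$data[[pop]]))
    if (length(miss)) {
      stop_ck("population '%s' lacks databook parameter(s): %s", pop,
              paste(miss, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Model state: compartment sizes at one point in time
#'
#' @param year Decimal year of the state.
#' @param sizes Numeric matrix of nonnegative compartment sizes with
#'   populations as rows and *normal* compartments as columns (sources and
#'   sinks are tracked as cumulative tallies by the engine, not as sizes).
#' @return An object of class `cascade_state`.
#' @export
cascade_state <- function(year, sizes) {
  sizes <- as.matrix(sizes)
  if (any(sizes < 0)) stop_ck("compartment sizes must be nonnegative")
  if (is.null(rownames(sizes)) || is.null(colnames(sizes))) {
    stop_ck("'sizes' needs population rownames and compartment colnames")
  }
  structure(list(year = year, sizes = sizes), class = "cascade_state")
}

# Interpolated databook values + formula evaluation for one state.
# Returns matrix [population x parameter] covering every parameter code.
evaluate_parameters <- function(fw, parset, state, plan = NULL) {
  if (is.null(plan)) plan <- compile_formulas(fw)
  pops <- parset$populations
  pcodes <- fw$parameters$code
  out <- matrix(NA_real_, length(pops), length(pcodes),
                dimnames = list(pops, pcodes))
  dbk <- fw$parameters$code[fw$parameters$databook_entry]
  for (pop in pops) {
    for (code in dbk) {
      out[pop, code] <- ts_interpolate(parset$data[[pop]][[code]], state$year)
    }
    if (length(plan$order)) {
      env <- as.list(out[pop, , drop = TRUE])
      comp <- colnames(state$sizes)
      env[comp] <- state$sizes[pop, comp]
      for (code in plan$order) {
        env[[code]] <- eval_formula(plan$compiled[[code]], env)
        out[pop, code] <- env[[code]]
      }
    }
  }
  out
}
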