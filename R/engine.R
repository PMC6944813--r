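#' Convert an annual probability to a per-step probability
#'
#' Compounds an annual transition probability down (or up) to a time step of
#' `dt` years: `1 - (1 - p)^dt`. At `dt = 1` this is the identity, so annual
#' bookkeeping is reproduced exactly; at sub-annual steps probabilities
#' compound correctly instead of scaling linearly.
#'
#' @param p Annual probability (vectorized), in `[0, 1]`.
#' @param dt Step length in years, `> 0`.
#' @return Per-step probability.
#' @export
annual_prob_to_step <- function(p, dt) {
  assert_number(dt, "dt", lower = .Machine$double.eps)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_ck("annual probabilities must lie in [0, 1]")
  }
  1 - (1 - p)^dt
}

# Precomputed transition bookkeeping shared by the stepping functions.
fw_engine_index <- function(fw) {
  cmp <- fw$compartments
  normal <- cmp$code[cmp$role == "normal"]
  trn <- fw$transitions
  list(
    normal = normal,
    sources = cmp$code[cmp$role == "source"],
    sinks = cmp$code[cmp$role == "sink"],
    from = trn$from, to = trn$to, par = trn$parameter,
    loss = trn$loss,
    from_normal = trn$from %in% normal,
    to_normal = trn$to %in% normal,
    fmt = stats::setNames(fw$parameters$format, fw$parameters$code),
    labels = sprintf("%s->%s", trn$from, trn$to)
  )
}

#' Compute one step's transition flows
#'
#' Proposes flows for every transition from the start-of-step state:
#' probability-format parameters move `size x (1 - (1 - p)^dt)` persons,
#' number-format parameters move `value x dt` persons, and program-added
#' conversion flows (persons/year) are added on their target transitions.
#' If a compartment's proposed outflow exceeds what is available to it this
#' step (its starting size plus its same-step inflows), all its outflows are
#' rescaled proportionally, iterating to a fixed point so that no
#' compartment is driven negative while flow ratios are preserved.
#'
#' @param state A [cascade_state()].
#' @param fw A validated [cascade_framework()].
#' @param values Matrix of evaluated parameter values
#'   (population x parameter), e.g. from the engine's evaluation pipeline.
#' @param dt Step length in years.
#' @param added_flows Optional matrix (population x transition, persons/year)
#'   of program conversion flows.
#' @param index Internal precomputed index (for repeated stepping).
#' @return Matrix (population x transition) of persons moved this step.
#' @export
compute_flows <- function(state, fw, values, dt, added_flows = NULL,
                          index = NULL) {
  if (is.null(index)) index <- fw_engine_index(fw)
  pops <- rownames(state$sizes)
  ntr <- length(index$from)
  flows <- matrix(0, length(pops), ntr, dimnames = list(pops, index$labels))
  if (!ntr) return(flows)

  for (j in seq_len(ntr)) {
    pcode <- index$par[j]
    v <- values[, pcode]
    if (any(is.na(v))) stop_ck("parameter '%s' has no value", pcode)
    if (any(v < 0)) stop_ck("negative value for parameter '%s'", pcode)
    fmt <- index$fmt[[pcode]]
    if (index$from_normal[j]) {
      size <- state$sizes[, index$from[j]]
      if (fmt == "probability_per_year") {
        flows[, j] <- size * annual_prob_to_step(v, dt)
      } else if (fmt == "number_per_year") {
        flows[, j] <- v * dt
      } else {
        stop_ck("parameter '%s' (proportion) cannot govern a transition", pcode)
      }
    } else {
      # out of a source: number-format only (validated)
      flows[, j] <- v * dt
    }
  }
  if (!is.null(added_flows)) flows <- flows + added_flows * dt

  # Proportional rescaling against availability = size + same-step inflows.
  norm <- index$normal
  for (pop in pops) {
    fl <- flows[pop, ]
    prop_out <- vapply(norm, function(cc) sum(fl[index$from == cc]), 0)
    scale <- stats::setNames(rep(1, length(norm)), norm)
    for (iter in seq_len(200L)) {
      scaled <- fl
      has_scale <- index$from_normal
      scaled[has_scale] <- fl[has_scale] * scale[index$from[has_scale]]
      inflow <- vapply(norm, function(cc) sum(scaled[index$to == cc]), 0)
      avail <- state$sizes[pop, norm] + inflow
      new_scale <- scale
      over <- prop_out > 0 & prop_out * scale > avail + 1e-12
      new_scale[over] <- pmax(0, avail[over]) / prop_out[over]
      if (max(abs(new_scale - scale)) < 1e-13) { scale <- new_scale; break }
      scale <- pmin(scale, new_scale)
    }
    fl[index$from_normal] <- fl[index$from_normal] *
      scale[index$from[index$from_normal]]
    flows[pop, ] <- fl
  }
  flows
}

#' Advance the model by one time step
#'
#' Explicit update: all flows are computed simultaneously from the
#' start-of-step state via [compute_flows()], then applied, and the year is
#' advanced by `dt`. Persons entering sinks and arriving from sources are
#' returned so callers can keep cumulative tallies.
#'
#' @inheritParams compute_flows
#' @param progset,allocation Optional program set and budget allocation; when
#'   supplied the program layer overrides parameter values and adds
#'   conversion flows before flows are computed.
#' @param parset A [cascade_parset()] used to evaluate databook parameters at
#'   the state's year.
#' @param plan Optional precompiled formula plan.
#' @return List with `state` (next [cascade_state()]), `flows` (persons per
#'   transition), `source_in` and `sink_out` (persons per population).
#' @export
step_state <- function(state, fw, parset, dt, progset = NULL,
                       allocation = NULL, plan = NULL, index = NULL) {
  if (is.null(index)) index <- fw_engine_index(fw)
  values <- evaluate_parameters(fw, parset, state, plan)
  added <- NULL
  if (!is.null(progset)) {
    eff <- apply_programs(values, fw, progset, allocation, state, state$year,
                          index = index)
    values <- eff$values
    added <- eff$added_flows
  }
  flows <- compute_flows(state, fw, values, dt, added_flows = added,
                         index = index)
  apply_flows(state, fw, flows, dt, index)
}

apply_flows <- function(state, fw, flows, dt, index) {
  pops <- rownames(state$sizes)
  sizes <- state$sizes
  for (cc in index$normal) {
    outf <- rowSums(flows[, index$from == cc, drop = FALSE])
    inf <- rowSums(flows[, index$to == cc, drop = FALSE])
    sizes[, cc] <- sizes[, cc] - outf + inf
  }
  if (any(sizes < -1e-8)) {
    stop_ck("negative compartment size after step at year %g", state$year)
  }
  sizes[sizes < 0] <- 0
  src <- rowSums(flows[, !index$from_normal, drop = FALSE])
  snk <- rowSums(flows[, !index$to_normal, drop = FALSE])
  list(state = cascade_state(state$year + dt, sizes), flows = flows,
       source_in = src, sink_out = snk)
}

#' Project a cascade model over time
#'
#' Deterministic discrete-time projection with explicit stepping: all flows
#' are drawn from the start-of-step state, applied simultaneously, and
#' recorded in a full per-step flow ledger.
#'
#' @param fw A validated [cascade_framework()].
#' @param parset A [cascade_parset()].
#' @param initial Initial [cascade_state()] (its year is `t0`).
#' @param t0,t1 Start and end decimal years; `t1 >= t0` and `dt` must divide
#'   `t1 - t0`.
#' @param dt Step length in years (default 1, reproducing annual
#'   bookkeeping).
#' @param progset,allocation Optional [cascade_progset()] and budget
#'   allocation (named list of spending [cascade_ts()] per program; defaults
#'   to the program set's baseline spending).
#' @return An object of class `cascade_sim`: times, a
#'   `[time x population x compartment]` size array, the per-step flow
#'   ledger `[step x population x transition]`, and cumulative source
#'   inflows / sink outflows per time point.
#' @export
run_simulation <- function(fw, parset, initial, t0 = initial$year, t1, dt = 1,
                           progset = NULL, allocation = NULL) {
  fw_assert_valid(fw)
  parset_check(parset, fw)
  if (t1 < t0) stop_ck("t1 must be >= t0")
  nstep <- round((t1 - t0) / dt)
  if (!near(t0 + nstep * dt, t1, 1e-9)) {
    stop_ck("dt = %g does not divide the horizon [%g, %g]", dt, t0, t1)
  }
  if (!near(initial$year, t0)) initial <- cascade_state(t0, initial$sizes)
  if (!is.null(progset) && is.null(allocation)) {
    allocation <- baseline_allocation(progset)
  }
  plan <- compile_formulas(fw)
  index <- fw_engine_index(fw)
  pops <- rownames(initial$sizes)
  times <- t0 + dt * seq.int(0L, nstep)
  sizes <- array(NA_real_, c(nstep + 1L, length(pops), length(index$normal)),
                 dimnames = list(NULL, pops, index$normal))
  flows <- array(0, c(max(nstep, 0L), length(pops), length(index$from)),
                 dimnames = list(NULL, pops, index$labels))
  src <- matrix(0, nstep + 1L, length(pops), dimnames = list(NULL, pops))
  snk <- matrix(0, nstep + 1L, length(pops), dimnames = list(NULL, pops))
  state <- initial
  sizes[1L, , ] <- state$sizes[, index$normal]
  if (nstep > 0L) for (k in seq_len(nstep)) {
    stepped <- step_state(state, fw, parset, dt, progset, allocation,
                          plan = plan, index = index)
    state <- stepped$state
    sizes[k + 1L, , ] <- state$sizes[, index$normal]
    flows[k, , ] <- stepped$flows
    src[k + 1L, ] <- src[k, ] + stepped$source_in
    snk[k + 1L, ] <- snk[k, ] + stepped$sink_out
  }
  structure(list(times = times, dt = dt, populations = pops,
                 compartments = index$normal, sizes = sizes, flows = flows,
                 transitions = fw$transitions, source_in = src,
                 sink_out = snk, framework_name = fw$name),
            class = "cascade_sim")
}

#' @export
print.cascade_sim <- function(x, ...) {
  cat(sprintf("<cascade_sim '%s': %g-%g (dt=%g), %d population(s), %d compartments>\n",
              x$framework_name, min(x$times), max(x$times), x$dt,
              length(x$populations), length(x$compartments)))
  invisible(x)
}

sim_time_index <- function(result, year) {
  if (year < min(result$times) - 1e-9 || year > max(result$times) + 1e-9) {
    stop_ck("year %g outside the simulated range [%g, %g]", year,
            min(result$times), max(result$times))
  }
  which.min(abs(result$times - year))
}

#' Extract cascade stage sizes from a simulation
#'
#' Stage value = sum of the sizes of the stage's constituent compartments at
#' the grid point nearest the requested year, aggregated over populations or
#' disaggregated with `by_population = TRUE`.
#'
#' @param result A `cascade_sim` from [run_simulation()].
#' @param fw The framework the simulation was run with.
#' @param year Decimal year within the simulated range.
#' @param by_population Return a stage x population matrix instead of the
#'   aggregated vector.
#' @return Named numeric vector of persons per stage (continuous; see
#'   [report_cascade()] for presentation rounding), or a matrix if
#'   disaggregated.
#' @export
extract_cascade <- function(result, fw, year, by_population = FALSE) {
  ti <- sim_time_index(result, year)
  stages <- fw$stages$name
  sl <- result$sizes[ti, , , drop = FALSE] # 1 x pop x comp
  m <- vapply(stages, function(s) {
    cons <- fw$stage_constituents[[s]]
    apply(sl[, , cons, drop = FALSE], 2, sum)
  }, numeric(length(result$populations)))
  m <- matrix(m, nrow = length(result$populations),
              dimnames = list(result$populations, stages))
  if (by_population) return(t(m))
  colSums(m)
}

#' Round cascade values for presentation
#'
#' Internal state is continuous; printed stage counts are rounded
#' half-away-from-zero only at presentation.
#'
#' @param x Numeric vector of stage values.
#' @return Rounded integer-valued vector.
#' @export
report_cascade <- function(x) round_half_out(x)

#' Loss accounting
#'
#' Two notions of "people lost from each stage": (a) endpoint drop-offs,
#' the gaps `S_k(T) - S_(k+1)(T)` between adjacent stage sizes at a final
#' (or given) year, which telescope to first minus last stage; and (b)
#' cumulative flow losses, the total persons moved along transitions marked
#' `loss` in the framework (e.g. loss to follow-up) over the whole run.
#'
#' @param result A `cascade_sim`.
#' @param fw The framework.
#' @param mode `"endpoint_dropoff"` or `"cumulative_flow"`.
#' @param year Evaluation year for endpoint mode (default: end of run).
#' @return Named numeric vector: per adjacent stage pair (endpoint mode) or
#'   per loss-marked transition (cumulative mode; zero-length designation
#'   yields an empty vector summing to 0).
#' @export
loss_accounting <- function(result, fw,
                            mode = c("endpoint_dropoff", "cumulative_flow"),
                            year = max(result$times)) {
  mode <- match.arg(mode)
  if (mode == "endpoint_dropoff") {
    casc <- extract_cascade(result, fw, year)
    if (length(casc) < 2L) return(stats::setNames(numeric(0), character(0)))
    drop <- casc[-length(casc)] - casc[-1L]
    names(drop) <- paste(fw$stages$name[-nrow(fw$stages)],
                         fw$stages$name[-1L], sep = " -> ")
    drop
  } else {
    idx <- which(result$transitions$loss)
    if (!length(idx)) return(stats::setNames(numeric(0), character(0)))
    tot <- vapply(idx, function(j) sum(result$flows[, , j]), 0)
    names(tot) <- sprintf("%s->%s", result$transitions$from[idx],
                          result$transitions$to[idx])
    tot
  }
}
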