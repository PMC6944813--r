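#' Optimization objectives
#'
#' The three default cascade objectives. Internally every objective is
#' minimized; maximization objectives are negated, so one solver contract
#' covers all of them.
#'
#' @param stage Cascade stage name.
#' @param years Evaluation year(s); default is the end of the horizon.
#' @return An object of class `cascade_objective`.
#' @rdname cascade_objective
#' @export
objective_maximize_stage <- function(stage, years = NULL) {
  structure(list(kind = "maximize_stage", stage = stage, years = years),
            class = "cascade_objective")
}

#' @param mode `"endpoint_dropoff"` (gaps between adjacent stage sizes at the
#'   evaluation year) or `"cumulative_flow"` (persons traversing loss-marked
#'   transitions over the whole run).
#' @param weights Nonnegative weights, one per adjacent stage pair (endpoint
#'   mode) or per loss transition (cumulative mode); default equal. Equal
#'   endpoint weights telescope to first-stage minus last-stage; weighting
#'   each gap by the number of downstream stages it forfeits measures the
#'   total stage-attainment shortfall instead.
#' @rdname cascade_objective
#' @export
objective_minimize_losses <- function(mode = c("endpoint_dropoff",
                                               "cumulative_flow"),
                                      weights = NULL, years = NULL) {
  mode <- match.arg(mode)
  if (!is.null(weights) && any(weights < 0)) {
    stop_ck("loss weights must be nonnegative")
  }
  structure(list(kind = "minimize_losses", loss_mode = mode,
                 weights = weights, years = years),
            class = "cascade_objective")
}

#' @param threshold Target value for the stage.
#' @param threshold_type `"persons"` or `"fraction"` (of the first stage).
#' @param year Year by which the target must be met.
#' @rdname cascade_objective
#' @export
objective_minimize_funding <- function(stage, threshold, year,
                                       threshold_type = c("persons",
                                                          "fraction")) {
  structure(list(kind = "minimize_funding_for_target", stage = stage,
                 threshold = threshold, year = year,
                 threshold_type = match.arg(threshold_type)),
            class = "cascade_objective")
}

objective_check <- function(objective, fw) {
  if (!is.null(objective$stage) &&
      !objective$stage %in% fw$stages$name) {
    stop_ck("objective references unknown stage '%s'", objective$stage)
  }
  invisible(TRUE)
}

#' Evaluate an objective under a budget allocation
#'
#' Runs the project's simulation under `allocation` and scores it in
#' minimization sense: maximize-stage returns minus the stage size at the
#' evaluation year(s); minimize-losses returns the weighted loss total in
#' its configured mode.
#'
#' @param project A [cascade_project()] with programs.
#' @param allocation Named list program -> spending (numbers or
#'   [cascade_ts()]).
#' @param objective A `cascade_objective`.
#' @return Scalar objective value (lower is better).
#' @export
objective_value <- function(project, allocation, objective) {
  objective_check(objective, project$framework)
  sim <- run_project(project, allocation = allocation)
  score_simulation(sim, project$framework, objective)
}

score_simulation <- function(sim, fw, objective) {
  years <- objective$years %||% max(sim$times)
  if (objective$kind == "maximize_stage") {
    -sum(vapply(years, function(y) {
      extract_cascade(sim, fw, y)[[objective$stage]]
    }, 0))
  } else if (objective$kind == "minimize_losses") {
    if (objective$loss_mode == "endpoint_dropoff") {
      sum(vapply(years, function(y) {
        d <- loss_accounting(sim, fw, "endpoint_dropoff", year = y)
        w <- objective$weights %||% rep(1, length(d))
        sum(w * d)
      }, 0))
    } else {
      d <- loss_accounting(sim, fw, "cumulative_flow")
      w <- objective$weights %||% rep(1, length(d))
      sum(w * d)
    }
  } else {
    stop_ck("objective '%s' is handled by minimize_budget_for_target",
            objective$kind)
  }
}

# ---------------------------------------------------------------------------
# Constraints and the feasibility projection
# ---------------------------------------------------------------------------

#' Spending constraints for an optimization
#'
#' @param total_budget Total spending per year across the adjustable
#'   programs: a single number or a [cascade_ts()].
#' @param lower,upper Optional named per-program bounds (numbers or
#'   [cascade_ts()]); unnamed programs are bounded by `[0, Inf)`.
#' @return An object of class `cascade_constraints`.
#' @export
constraint_set <- function(total_budget, lower = NULL, upper = NULL) {
  structure(list(total_budget = total_budget, lower = lower, upper = upper),
            class = "cascade_constraints")
}

constraint_at <- function(x, name, year, default) {
  v <- x[[name]]
  if (is.null(v)) return(default)
  if (is_cascade_ts(v)) return(ts_interpolate(v, year))
  as.numeric(v)
}

constraint_bounds <- function(constraints, programs, year) {
  lo <- vapply(programs, function(p) constraint_at(constraints$lower, p, year, 0), 0)
  hi <- vapply(programs, function(p) constraint_at(constraints$upper, p, year, Inf), 0)
  bud <- if (is_cascade_ts(constraints$total_budget)) {
    ts_interpolate(constraints$total_budget, year)
  } else as.numeric(constraints$total_budget)
  list(lower = lo, upper = hi, budget = bud)
}

#' Project a raw allocation onto the feasible set
#'
#' Clips each program's spending to its bounds, rescales the unclamped
#' entries multiplicatively so the total matches the budget, and iterates
#' clip-rescale to a fixed point (at most one pass per program). The result
#' satisfies all bounds and hits the total exactly (1e-9 relative).
#'
#' @param raw Named numeric vector of proposed spending per program.
#' @param constraints A [constraint_set()].
#' @param year Decision year at which time-varying bounds are evaluated.
#' @return Feasible named numeric vector.
#' @export
constrain_allocation <- function(raw, constraints, year = NULL) {
  programs <- names(raw)
  if (is.null(programs)) stop_ck("'raw' must be a named vector")
  year <- year %||% 0
  b <- constraint_bounds(constraints, programs, year)
  if (sum(b$lower) > b$budget + 1e-9) {
    stop_ck("infeasible constraints: lower bounds (%s) sum to %g > budget %g",
            paste(sprintf("%s>=%g", programs, b$lower), collapse = ", "),
            sum(b$lower), b$budget)
  }
  if (sum(b$upper) < b$budget - 1e-9) {
    stop_ck("infeasible constraints: upper bounds sum to %g < budget %g",
            sum(b$upper), b$budget)
  }
  x <- pmin(pmax(raw, b$lower), b$upper)
  for (iter in seq_len(length(raw) + 1L)) {
    delta <- b$budget - sum(x)
    if (abs(delta) <= 1e-9 * max(1, b$budget)) break
    if (delta < 0) {
      free <- x > b$lower + 1e-15
      slack <- x[free] - b$lower[free]
      if (!sum(slack)) break
      target <- sum(x[free]) + delta
      # multiplicative rescale of the unclamped entries
      fac <- max(0, target / sum(x[free]))
      x[free] <- x[free] * fac
    } else {
      free <- x < b$upper - 1e-15
      if (!any(free)) break
      if (sum(x[free]) > 0) {
        fac <- (sum(x[free]) + delta) / sum(x[free])
        x[free] <- x[free] * fac
      } else {
        x[free] <- x[free] + delta / sum(free)
      }
    }
    x <- pmin(pmax(x, b$lower), b$upper)
  }
  x
}

# ---------------------------------------------------------------------------
# Adjustments and the decision-vector codec
# ---------------------------------------------------------------------------

#' Specify what an optimization may change, and when
#'
#' @param kind One of `"immediate"` (one constant budget share per program),
#'   `"delayed"` (baseline until `change_year`, optimized shares after),
#'   `"time_varying"` (shares re-optimized at each breakpoint year) or
#'   `"start_year"` (search the year at which a given reallocation happens).
#' @param programs Adjustable program codes.
#' @param change_year Year a delayed change takes effect.
#' @param breakpoint_years Strictly increasing breakpoint years for
#'   time-varying adjustments.
#' @param pre_allocation,post_allocation Named spending vectors before/after
#'   the switch (start-year kind).
#' @param candidate_years Integer years scanned by the start-year kind.
#' @return An object of class `cascade_adjustment`.
#' @export
adjustment <- function(kind = c("immediate", "delayed", "time_varying",
                                "start_year"),
                       programs, change_year = NULL, breakpoint_years = NULL,
                       pre_allocation = NULL, post_allocation = NULL,
                       candidate_years = NULL) {
  kind <- match.arg(kind)
  if (kind == "time_varying") {
    if (is.null(breakpoint_years) || any(diff(breakpoint_years) <= 0)) {
      stop_ck("time_varying adjustments need strictly increasing breakpoint years")
    }
  }
  if (kind == "delayed" && is.null(change_year)) {
    stop_ck("delayed adjustments need a change_year")
  }
  if (kind == "start_year" &&
      (is.null(pre_allocation) || is.null(post_allocation) ||
       is.null(candidate_years))) {
    stop_ck("start_year adjustments need pre/post allocations and candidate years")
  }
  structure(list(kind = kind, programs = programs, change_year = change_year,
                 breakpoint_years = breakpoint_years,
                 pre_allocation = pre_allocation,
                 post_allocation = post_allocation,
                 candidate_years = candidate_years),
            class = "cascade_adjustment")
}

# Decision years: when each block of the decision vector applies.
adjustment_periods <- function(adj, project) {
  switch(adj$kind,
         immediate = project$settings$t0,
         delayed = adj$change_year,
         time_varying = adj$breakpoint_years,
         start_year = numeric(0))
}

# Expand a decision vector into a full allocation (named list of ts).
expand_decision <- function(x, adj, project, constraints) {
  base <- baseline_allocation(project$progset)
  periods <- adjustment_periods(adj, project)
  n <- length(adj$programs)
  stopifnot(length(x) == n * length(periods))
  alloc <- base
  if (adj$kind == "immediate") {
    for (i in seq_len(n)) {
      alloc[[adj$programs[i]]] <- cascade_ts(project$settings$t0, x[i],
                                             "previous")
    }
  } else if (adj$kind == "delayed") {
    for (i in seq_len(n)) {
      p <- adj$programs[i]
      base_val <- ts_interpolate(base[[p]], adj$change_year)
      alloc[[p]] <- cascade_ts(c(project$settings$t0, adj$change_year),
                               c(ts_interpolate(base[[p]],
                                                project$settings$t0), x[i]),
                               "previous")
    }
  } else if (adj$kind == "time_varying") {
    for (i in seq_len(n)) {
      p <- adj$programs[i]
      vals <- x[i + n * (seq_along(periods) - 1L)]
      alloc[[p]] <- cascade_ts(periods, vals, "previous")
    }
  }
  alloc
}

# Projection of a decision vector onto feasibility, period by period.
project_decision <- function(x, adj, project, constraints) {
  periods <- adjustment_periods(adj, project)
  n <- length(adj$programs)
  out <- x
  for (k in seq_along(periods)) {
    idx <- (k - 1L) * n + seq_len(n)
    v <- stats::setNames(x[idx], adj$programs)
    out[idx] <- constrain_allocation(v, constraints, periods[k])
  }
  out
}

# ---------------------------------------------------------------------------
# Adaptive Stochastic Descent
# ---------------------------------------------------------------------------

#' Optimizer configuration
#'
#' @param algorithm `"asd"`, `"random_search"`, `"grid"` or
#'   `"external_adapter"` (supply the minimizer callable as `minimizer`).
#' @param seed Integer seed; runs are bit-reproducible given the seed.
#' @param max_evaluations Evaluation budget.
#' @param tolerance Relative objective improvement below which an evaluation
#'   counts as stalled.
#' @param patience Consecutive stalled evaluations before stopping.
#' @param step_init Initial step as a fraction of each variable's range.
#' @param step_grow,step_shrink Step multipliers on success / failure
#'   (`grow > 1 > shrink > 0`).
#' @param prob_grow,prob_shrink Direction-probability multipliers on
#'   success / failure.
#' @param grid_step Spending resolution of the `"grid"` algorithm.
#' @param minimizer Callable `function(f, x0, project_fn, config)` for the
#'   external adapter; must return `list(x, value)`.
#' @return An object of class `cascade_optconfig`.
#' @export
optimizer_config <- function(algorithm = c("asd", "random_search", "grid",
                                           "external_adapter"),
                             seed = 1L, max_evaluations = 1000L,
                             tolerance = 1e-8, patience = 200L,
                             step_init = 0.1, step_grow = 2, step_shrink = 0.5,
                             prob_grow = 2, prob_shrink = 0.5,
                             grid_step = 500, minimizer = NULL) {
  algorithm <- match.arg(algorithm)
  if (step_grow <= 1 || step_shrink >= 1 || step_shrink <= 0) {
    stop_ck("need step_grow > 1 > step_shrink > 0")
  }
  structure(list(algorithm = algorithm, seed = as.integer(seed),
                 max_evaluations = as.integer(max_evaluations),
                 tolerance = tolerance, patience = as.integer(patience),
                 step_init = step_init, step_grow = step_grow,
                 step_shrink = step_shrink, prob_grow = prob_grow,
                 prob_shrink = prob_shrink, grid_step = grid_step,
                 minimizer = minimizer),
            class = "cascade_optconfig")
}

#' Adaptive Stochastic Descent
#'
#' Derivative-free coordinate-wise stochastic minimizer. Each round samples
#' one of the `2n` signed coordinate directions with probability
#' proportional to learned weights, proposes a step of the direction's
#' current size, projects the proposal onto the feasible set and accepts it
#' iff the objective improves; accepted directions have their step size and
#' selection weight grown, rejected ones shrunk. Stops at the evaluation
#' budget or after `patience` consecutive evaluations without relative
#' improvement above `tolerance`.
#'
#' @param f Objective callable mapping a numeric vector to a finite scalar
#'   (minimization sense).
#' @param x0 Starting vector (projected before the first evaluation).
#' @param project_fn Feasibility projection applied to every proposal.
#' @param config An [optimizer_config()].
#' @param ranges Per-variable scale used for the initial step size; default
#'   `max(abs(x0), 1)`.
#' @return An object of class `cascade_optresult`: `x` (best point),
#'   `value`, `trace` (per-evaluation best values), `evaluations`, `seed`.
#' @export
asd_minimize <- function(f, x0, project_fn = identity,
                         config = optimizer_config(), ranges = NULL) {
  set.seed(config$seed)
  n <- length(x0)
  ranges <- ranges %||% pmax(abs(x0), 1)
  x <- project_fn(x0)
  fx <- f(x)
  if (!is.finite(fx)) stop_ck("objective not finite at the starting point")
  steps <- rep(config$step_init * ranges, 2L) # +direction then -direction
  probs <- rep(1 / (2 * n), 2L * n)
  trace <- data.frame(evaluation = 1L, value = fx, best = fx,
                      accepted = TRUE)
  evals <- 1L
  stalled <- 0L
  while (evals < config$max_evaluations && stalled < config$patience) {
    d <- sample.int(2L * n, 1L, prob = probs)
    i <- ((d - 1L) %% n) + 1L
    sgn <- if (d <= n) 1 else -1
    prop <- x
    prop[i] <- prop[i] + sgn * steps[d]
    prop <- project_fn(prop)
    fp <- f(prop)
    evals <- evals + 1L
    improved <- is.finite(fp) && fp < fx
    rel_gain <- if (improved) (fx - fp) / max(abs(fx), 1e-12) else 0
    if (improved) {
      x <- prop; fx <- fp
      steps[d] <- steps[d] * config$step_grow
      probs[d] <- probs[d] * config$prob_grow
    } else {
      steps[d] <- steps[d] * config$step_shrink
      probs[d] <- probs[d] * config$prob_shrink
    }
    probs <- pmax(probs, 1e-6)
    probs <- probs / sum(probs)
    stalled <- if (rel_gain > config$tolerance) 0L else stalled + 1L
    trace <- rbind(trace, data.frame(evaluation = evals, value = fp,
                                     best = fx, accepted = improved))
  }
  structure(list(x = x, value = fx, trace = trace, evaluations = evals,
                 seed = config$seed),
            class = "cascade_optresult")
}

#' @export
print.cascade_optresult <- function(x, ...) {
  cat(sprintf("<cascade_optresult: best value %g after %d evaluation(s)>\n",
              x$value, x$evaluations))
  invisible(x)
}

random_search_minimize <- function(f, x0, project_fn, config, ranges = NULL) {
  set.seed(config$seed)
  ranges <- ranges %||% pmax(abs(x0), 1)
  x <- project_fn(x0)
  fx <- f(x)
  trace <- data.frame(evaluation = 1L, value = fx, best = fx, accepted = TRUE)
  for (k in seq_len(config$max_evaluations - 1L)) {
    prop <- project_fn(x0 + stats::runif(length(x0), -1, 1) * ranges)
    fp <- f(prop)
    acc <- is.finite(fp) && fp < fx
    if (acc) { x <- prop; fx <- fp }
    trace <- rbind(trace, data.frame(evaluation = k + 1L, value = fp,
                                     best = fx, accepted = acc))
  }
  structure(list(x = x, value = fx, trace = trace,
                 evaluations = config$max_evaluations, seed = config$seed),
            class = "cascade_optresult")
}

#' Enumerate budget compositions on a grid
#'
#' All ways of splitting `total` across `n` programs in multiples of `step`
#' (exhaustive simplex grid, used as the brute-force comparator for the
#' stochastic optimizer).
#'
#' @param total Total budget.
#' @param n Number of programs.
#' @param step Grid resolution in currency units; must divide `total`.
#' @return Matrix with `n` columns, one row per composition.
#' @export
allocation_compositions <- function(total, n, step) {
  units <- round(total / step)
  if (!near(units * step, total)) stop_ck("step must divide the total budget")
  rec <- function(k, left) {
    if (k == 1L) return(matrix(left, ncol = 1L))
    out <- lapply(0:left, function(u) cbind(u, rec(k - 1L, left - u)))
    do.call(rbind, out)
  }
  rec(n, units) * step
}

# ---------------------------------------------------------------------------
# The full optimization entry points
# ---------------------------------------------------------------------------

#' Optimize a budget allocation
#'
#' Builds the decision vector for the adjustment kind, runs the configured
#' algorithm with the clip-rescale feasibility projection, and returns the
#' best allocation expanded to full time-series form. A single adjustable
#' program needs no search: it receives the whole budget. The start-year
#' kind scans its candidate years exhaustively (the variable is small and
#' discrete).
#'
#' @param project A [cascade_project()] with programs.
#' @param objective A `cascade_objective` (not the funding objective; see
#'   [minimize_budget_for_target()]).
#' @param adjustment A [adjustment()].
#' @param constraints A [constraint_set()].
#' @param config An [optimizer_config()].
#' @return A `cascade_optresult` with `allocation` (named list of
#'   [cascade_ts()]), `value`, `trace`, `evaluations`.
#' @export
optimize_allocation <- function(project, objective, adjustment, constraints,
                                config = optimizer_config()) {
  objective_check(objective, project$framework)
  miss <- setdiff(adjustment$programs, names(project$progset$programs))
  if (length(miss)) {
    stop_ck("adjustable program(s) not in the project: %s",
            paste(miss, collapse = ", "))
  }

  if (adjustment$kind == "start_year") {
    return(optimize_start_year(project, objective, adjustment, config))
  }

  periods <- adjustment_periods(adjustment, project)
  # fail fast on infeasible constraints, before any simulation
  for (y in periods) constraint_bounds_check(constraints, adjustment$programs, y)

  n <- length(adjustment$programs)
  f <- function(x) {
    alloc <- expand_decision(x, adjustment, project, constraints)
    objective_value(project, alloc, objective)
  }
  proj_fn <- function(x) project_decision(x, adjustment, project, constraints)

  b0 <- constraint_bounds(constraints, adjustment$programs, periods[1])
  if (n == 1L) {
    x <- proj_fn(rep(b0$budget, length(periods)))
    res <- structure(list(x = x, value = f(x),
                          trace = data.frame(evaluation = 1L, value = NA,
                                             best = NA, accepted = TRUE),
                          evaluations = 1L, seed = config$seed),
                     class = "cascade_optresult")
    res$trace$value <- res$trace$best <- res$value
  } else if (config$algorithm == "grid") {
    if (length(periods) > 1L) {
      stop_ck("grid search supports single-period adjustments only")
    }
    grid <- allocation_compositions(b0$budget, n, config$grid_step)
    best <- NULL
    vals <- apply(grid, 1L, function(row) {
      x <- stats::setNames(row, adjustment$programs)
      ok <- all(x >= b0$lower - 1e-9) && all(x <= b0$upper + 1e-9)
      if (!ok) return(Inf)
      f(x)
    })
    k <- which.min(vals)
    res <- structure(list(x = stats::setNames(grid[k, ], adjustment$programs),
                          value = vals[k],
                          trace = data.frame(evaluation = seq_along(vals),
                                             value = vals,
                                             best = cummin(vals),
                                             accepted = vals == cummin(vals)),
                          evaluations = length(vals), seed = config$seed),
                     class = "cascade_optresult")
  } else {
    x0 <- unlist(lapply(periods, function(y) {
      base <- vapply(adjustment$programs, function(p) {
        ts_interpolate(baseline_allocation(project$progset)[[p]], y)
      }, 0)
      constrain_allocation(stats::setNames(base, adjustment$programs),
                           constraints, y)
    }))
    ranges <- rep(b0$budget, length(x0))
    res <- switch(config$algorithm,
                  asd = asd_minimize(f, x0, proj_fn, config, ranges),
                  random_search = random_search_minimize(f, x0, proj_fn,
                                                         config, ranges),
                  external_adapter = {
                    if (is.null(config$minimizer)) {
                      stop_ck("external_adapter needs a 'minimizer' callable")
                    }
                    out <- config$minimizer(f, x0, proj_fn, config)
                    structure(list(x = out$x, value = out$value,
                                   trace = out$trace %||% NULL,
                                   evaluations = out$evaluations %||% NA,
                                   seed = config$seed),
                              class = "cascade_optresult")
                  })
    res$x <- stats::setNames(res$x, rep(adjustment$programs,
                                        length(periods)))
  }
  res$allocation <- expand_decision(as.numeric(res$x), adjustment, project,
                                    constraints)
  res$objective <- objective
  res
}

constraint_bounds_check <- function(constraints, programs, year) {
  b <- constraint_bounds(constraints, programs, year)
  if (sum(b$lower) > b$budget + 1e-9) {
    stop_ck("infeasible constraints at %g: lower bounds sum to %g > budget %g",
            year, sum(b$lower), b$budget)
  }
  if (sum(b$upper) < b$budget - 1e-9) {
    stop_ck("infeasible constraints at %g: upper bounds sum to %g < budget %g",
            year, sum(b$upper), b$budget)
  }
  invisible(b)
}

optimize_start_year <- function(project, objective, adj, config) {
  base <- baseline_allocation(project$progset)
  vals <- vapply(adj$candidate_years, function(y) {
    alloc <- base
    for (p in union(names(adj$pre_allocation), names(adj$post_allocation))) {
      pre <- adj$pre_allocation[[p]] %||%
        ts_interpolate(base[[p]], project$settings$t0)
      post <- adj$post_allocation[[p]] %||% pre
      alloc[[p]] <- cascade_ts(c(project$settings$t0, y), c(pre, post),
                               "previous")
    }
    objective_value(project, alloc, objective)
  }, 0)
  k <- which.min(vals)
  best_year <- adj$candidate_years[k]
  alloc <- base
  for (p in union(names(adj$pre_allocation), names(adj$post_allocation))) {
    pre <- adj$pre_allocation[[p]] %||%
      ts_interpolate(base[[p]], project$settings$t0)
    post <- adj$post_allocation[[p]] %||% pre
    alloc[[p]] <- cascade_ts(c(project$settings$t0, best_year), c(pre, post),
                             "previous")
  }
  structure(list(x = best_year, value = vals[k],
                 trace = data.frame(evaluation = seq_along(vals),
                                    value = vals, best = cummin(vals),
                                    accepted = vals == cummin(vals)),
                 evaluations = length(vals), seed = config$seed,
                 allocation = alloc, objective = objective,
                 start_year = best_year),
            class = "cascade_optresult")
}

#' Rank single-program budget increments
#'
#' Scores, for each program, adding the whole increment to that program
#' alone (all other budgets at baseline) — the exhaustive single-program
#' grid used to prioritize interventions under a small incremental budget.
#'
#' @param project A [cascade_project()] with programs.
#' @param objective A `cascade_objective`.
#' @param increment Currency per year added to one program at a time.
#' @param programs Programs to consider (default all).
#' @return `data.frame` with `program` and `value` (minimization sense),
#'   ordered best first.
#' @export
rank_single_program_increments <- function(project, objective, increment,
                                           programs =
                                             names(project$progset$programs)) {
  base <- baseline_allocation(project$progset)
  vals <- vapply(programs, function(p) {
    alloc <- base
    alloc[[p]] <- ts_add_delta(alloc[[p]], increment, project$settings$t0)
    objective_value(project, alloc, objective)
  }, 0)
  out <- data.frame(program = programs, value = as.numeric(vals),
                    stringsAsFactors = FALSE)
  out[order(out$value), , drop = FALSE]
}

#' Minimize the budget required to meet a cascade target
#'
#' Outer bisection on a scalar multiplier of the total budget; at each trial
#' budget the inner optimizer allocates that budget to maximize the target
#' stage, and the smallest budget whose optimized outcome meets the target
#' is returned (bracket width below 0.1% of the upper bracket). Errors if
#' the target is unattainable at the full budget, reporting the shortfall.
#'
#' @param project A [cascade_project()] with programs.
#' @param target An [objective_minimize_funding()] objective.
#' @param adjustment,constraints,config As in [optimize_allocation()];
#'   `constraints$total_budget` is the upper bracket.
#' @return List with `budget`, `allocation`, `achieved` (stage value) and
#'   `multiplier`.
#' @export
minimize_budget_for_target <- function(project, target, adjustment,
                                       constraints,
                                       config = optimizer_config()) {
  if (target$kind != "minimize_funding_for_target") {
    stop_ck("'target' must come from objective_minimize_funding()")
  }
  inner_obj <- objective_maximize_stage(target$stage, years = target$year)
  thr <- target$threshold
  b_at <- function(m) {
    tb <- constraints$total_budget
    tb <- if (is_cascade_ts(tb)) cascade_ts(tb$years, tb$values * m,
                                            tb$interpolation) else tb * m
    constraint_set(tb, constraints$lower, constraints$upper)
  }
  achieved_at <- function(m) {
    res <- optimize_allocation(project, inner_obj, adjustment, b_at(m), config)
    sim <- run_project(project, allocation = res$allocation)
    val <- extract_cascade(sim, project$framework, target$year)[[target$stage]]
    if (target$threshold_type == "fraction") {
      val <- val / extract_cascade(sim, project$framework,
                                   target$year)[[project$framework$stages$name[1]]]
    }
    list(value = val, allocation = res$allocation)
  }
  top <- achieved_at(1)
  if (top$value < thr) {
    stop_ck("target unattainable at the full budget: achieved %g, short of %g by %g",
            top$value, thr, thr - top$value)
  }
  bottom <- achieved_at(0)
  if (bottom$value >= thr) {
    return(list(budget = 0, allocation = bottom$allocation,
                achieved = bottom$value, multiplier = 0))
  }
  lo <- 0; hi <- 1; best <- top
  while (hi - lo > 0.001) {
    mid <- (lo + hi) / 2
    got <- achieved_at(mid)
    if (got$value >= thr) { hi <- mid; best <- got } else lo <- mid
  }
  budget_hi <- if (is_cascade_ts(constraints$total_budget)) {
    max(constraints$total_budget$values)
  } else constraints$total_budget
  list(budget = hi * budget_hi, allocation = best$allocation,
       achieved = best$value, multiplier = hi)
}
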