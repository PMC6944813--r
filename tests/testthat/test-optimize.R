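test_that("the feasibility projection clips, rescales and is idempotent", {
  cons <- constraint_set(total_budget = 100)
  x <- constrain_allocation(c(p1 = 90, p2 = 30), cons)
  expect_equal(unname(x), c(75, 25)) # multiplicative rescale 100/120

  cons_b <- constraint_set(100, upper = list(p1 = 40))
  x <- constrain_allocation(c(p1 = 90, p2 = 30), cons_b)
  expect_equal(unname(x), c(40, 60)) # clip then rescale the remainder

  feas <- c(p1 = 70, p2 = 30)
  expect_equal(constrain_allocation(feas, cons), feas) # already feasible

  expect_error(constrain_allocation(c(p1 = 1, p2 = 1),
                                    constraint_set(10, lower = list(p1 = 8,
                                                                    p2 = 5))),
               "infeasible")
})

test_that("projection always satisfies bounds and total on random inputs", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(2:6, 1)
    budget <- stats::runif(1, 50, 500)
    lo <- stats::runif(n, 0, budget / (2 * n))
    hi <- lo + stats::runif(n, budget / n, budget)
    names(lo) <- names(hi) <- paste0("p", seq_len(n))
    cons <- constraint_set(budget, lower = as.list(lo), upper = as.list(hi))
    raw <- stats::setNames(stats::runif(n, 0, budget), names(lo))
    x <- try(constrain_allocation(raw, cons), silent = TRUE)
    if (inherits(x, "try-error")) {
      expect_true(sum(lo) > budget || sum(hi) < budget)
      next
    }
    expect_true(all(x >= lo - 1e-7) && all(x <= hi + 1e-7))
    expect_equal(sum(x), budget, tolerance = 1e-9)
    expect_equal(constrain_allocation(x, cons), x, tolerance = 1e-9)
  }
})

test_that("identical allocations score identically and better targets win", {
  p <- build_hypertension_demo()
  obj <- objective_maximize_stage("controlled", years = 2017)
  alloc <- baseline_allocation(p$progset)
  expect_identical(objective_value(p, alloc, obj),
                   objective_value(p, alloc, obj))
  plus <- function(prog) {
    a <- baseline_allocation(p$progset)
    a[[prog]] <- casckit::cascade_ts(2016,
                                     a[[prog]]$values[1] + 10000, "previous")
    a
  }
  # adherence scale-up beats pharmacy testing for blood-pressure control
  expect_lt(objective_value(p, plus("adherence_counseling"), obj),
            objective_value(p, plus("pharmacy_testing"), obj))
  # outreach beats all other single-program allocations for diagnoses
  obj_dx <- objective_maximize_stage("diagnosed", years = 2017)
  vals <- vapply(names(p$progset$programs), function(pr) {
    objective_value(p, plus(pr), obj_dx)
  }, 0)
  expect_identical(names(which.min(vals)), "outreach_testing")
  expect_error(objective_value(p, alloc,
                               objective_maximize_stage("nope")),
               "unknown stage")
})

test_that("ASD converges to the analytic minimum of a quadratic", {
  centre <- c(0.3, 0.7)
  f <- function(x) sum((x - centre)^2)
  res <- asd_minimize(f, c(0, 0),
                      config = optimizer_config(seed = 7,
                                                max_evaluations = 2000))
  expect_lte(res$evaluations, 2000)
  expect_lt(sqrt(sum((res$x - centre)^2)), 1e-3)
  # best-value trace is nonincreasing
  expect_true(all(diff(res$trace$best) <= 0))
})

test_that("ASD is bit-reproducible given the seed and handles flat objectives", {
  f <- function(x) sum((x - 3)^2)
  cfg <- optimizer_config(seed = 42, max_evaluations = 300)
  r1 <- asd_minimize(f, c(1, 1), config = cfg)
  r2 <- asd_minimize(f, c(1, 1), config = cfg)
  expect_identical(r1$x, r2$x)
  expect_identical(r1$trace, r2$trace)

  const <- function(x) 5
  rc <- asd_minimize(const, c(2, 2),
                     config = optimizer_config(seed = 1, patience = 25,
                                               max_evaluations = 500))
  expect_equal(rc$x, c(2, 2)) # stays at the (projected) start
  expect_equal(rc$value, 5)
  expect_lt(rc$evaluations, 500) # patience cuts the run short

  expect_error(asd_minimize(function(x) NaN, c(1), config = cfg), "finite")
})

test_that("ASD matches exhaustive grid search on toy budget problems", {
  # 3-program generic demo, fixed total budget, maximize final stage
  p <- build_generic_demo()
  obj <- objective_maximize_stage("treated", years = 2025)
  progs <- names(p$progset$programs)
  adj <- adjustment("immediate", programs = progs)
  cons <- constraint_set(total_budget = 30000)
  grid <- optimize_allocation(p, obj, adj, cons,
                              optimizer_config(algorithm = "grid",
                                               grid_step = 1500))
  asd <- optimize_allocation(p, obj, adj, cons,
                             optimizer_config(seed = 3,
                                              max_evaluations = 500))
  expect_equal(asd$value, grid$value, tolerance = 0.05)

  # 2-program subproblem on the hypertension demo
  p2 <- build_hypertension_demo()
  obj2 <- objective_maximize_stage("controlled", years = 2017)
  adj2 <- adjustment("immediate", programs = c("adherence_counseling",
                                               "retention_program"))
  cons2 <- constraint_set(total_budget = 30000)
  grid2 <- optimize_allocation(p2, obj2, adj2, cons2,
                               optimizer_config(algorithm = "grid",
                                                grid_step = 1500))
  asd2 <- optimize_allocation(p2, obj2, adj2, cons2,
                              optimizer_config(seed = 3,
                                               max_evaluations = 300))
  expect_equal(asd2$value, grid2$value, tolerance = 0.05)
})

test_that("a single adjustable program receives the whole budget unsearched", {
  p <- build_generic_demo()
  obj <- objective_maximize_stage("treated", years = 2025)
  res <- optimize_allocation(p, obj, adjustment("immediate", "adherence"),
                             constraint_set(12000))
  expect_identical(res$evaluations, 1L)
  expect_equal(unname(res$x), 12000)
  expect_equal(ts_interpolate(res$allocation$adherence, 2025), 12000)
})

test_that("start-year optimization scans its grid; identical pre/post is flat", {
  p <- build_generic_demo()
  obj <- objective_maximize_stage("treated", years = 2025)
  adj <- adjustment("start_year", programs = "adherence",
                    pre_allocation = list(adherence = 9000),
                    post_allocation = list(adherence = 9000),
                    candidate_years = 2021:2024)
  res <- optimize_allocation(p, obj, adj, constraint_set(1))
  expect_equal(max(res$trace$value) - min(res$trace$value), 0)

  adj2 <- adjustment("start_year", programs = "adherence",
                     pre_allocation = list(adherence = 0),
                     post_allocation = list(adherence = 20000),
                     candidate_years = 2021:2024)
  res2 <- optimize_allocation(p, obj, adj2, constraint_set(1))
  expect_identical(res2$start_year, 2021L) # earlier scale-up is never worse
})

test_that("delayed and time-varying adjustments shape the allocation in time", {
  p <- build_generic_demo()
  obj <- objective_maximize_stage("treated", years = 2025)
  progs <- names(p$progset$programs)
  res <- optimize_allocation(p, obj,
                             adjustment("delayed", progs, change_year = 2023),
                             constraint_set(33400),
                             optimizer_config(seed = 2,
                                              max_evaluations = 120))
  # before the change year, spending stays at baseline
  expect_equal(ts_interpolate(res$allocation$testing, 2022), 10000)
  expect_equal(sum(vapply(progs, function(pr) {
    ts_interpolate(res$allocation[[pr]], 2024)
  }, 0)), 33400, tolerance = 1e-6)

  res2 <- optimize_allocation(p, obj,
                              adjustment("time_varying", progs,
                                         breakpoint_years = c(2020, 2023)),
                              constraint_set(33400),
                              optimizer_config(seed = 2,
                                               max_evaluations = 120))
  for (y in c(2021, 2024)) {
    expect_equal(sum(vapply(progs, function(pr) {
      ts_interpolate(res2$allocation[[pr]], y)
    }, 0)), 33400, tolerance = 1e-6)
  }
  expect_error(adjustment("time_varying", progs,
                          breakpoint_years = c(2023, 2020)),
               "increasing")
})

test_that("budget minimization matches the closed form on a linear toy", {
  # one program moving people a -> b at 100% conversion, $20 per person:
  # budget needed = shortfall x unit_cost / efficacy
  fw <- cascade_framework(
    "toy",
    compartments = data.frame(code = c("a", "b"), label = c("a", "b"),
                              role = "normal"),
    transitions = data.frame(from = "a", to = "b", parameter = "move"),
    parameters = data.frame(code = "move", label = "move",
                            format = "number_per_year", formula = "",
                            databook_entry = TRUE),
    stages = data.frame(name = c("all", "reached"),
                        constituents = c("a;b", "b")))
  parset <- cascade_parset("pop", list(pop = list(move = 0)))
  init <- cascade_state(2020, matrix(c(900, 100), 1,
                                     dimnames = list("pop", c("a", "b"))))
  prog <- cascade_program("mover", "Mover", 20, eligible = "a",
                          spending_data = cascade_ts(2020, 0),
                          effects = list(program_effect_conversion("a", "b",
                                                                   0.5)))
  proj <- cascade_project(fw, parset, init, cascade_progset(list(prog)),
                          settings = list(t0 = 2020, t1 = 2021, dt = 1))
  target <- objective_minimize_funding("reached", threshold = 300,
                                       year = 2021)
  res <- minimize_budget_for_target(proj, target,
                                    adjustment("immediate", "mover"),
                                    constraint_set(20000))
  closed_form <- (300 - 100) * 20 / 0.5
  expect_equal(res$budget, closed_form, tolerance = 0.002 * 20000)
  expect_gte(res$achieved, 300 - 1e-6)

  # already-met target needs zero budget
  easy <- objective_minimize_funding("reached", threshold = 50, year = 2021)
  res0 <- minimize_budget_for_target(proj, easy,
                                     adjustment("immediate", "mover"),
                                     constraint_set(20000))
  expect_equal(res0$budget, 0)

  # unattainable target errors with the shortfall
  expect_error(
    minimize_budget_for_target(proj,
                               objective_minimize_funding("reached", 5000,
                                                          2021),
                               adjustment("immediate", "mover"),
                               constraint_set(20000)),
    "unattainable")

  # required budget is nonincreasing as the target loosens
  budgets <- vapply(c(400, 300, 200), function(thr) {
    minimize_budget_for_target(proj,
                               objective_minimize_funding("reached", thr,
                                                          2021),
                               adjustment("immediate", "mover"),
                               constraint_set(20000))$budget
  }, 0)
  expect_true(all(diff(budgets) <= 1e-6))
})

test_that("infeasible optimization constraints fail before any simulation", {
  p <- build_generic_demo()
  obj <- objective_maximize_stage("treated", years = 2025)
  progs <- names(p$progset$programs)
  expect_error(
    optimize_allocation(p, obj, adjustment("immediate", progs),
                        constraint_set(100, lower = list(testing = 200))),
    "infeasible")
  expect_error(
    optimize_allocation(p, obj, adjustment("immediate", c("testing", "nope")),
                        constraint_set(100)),
    "not in the project")
})
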