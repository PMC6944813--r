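test_that("annual probabilities compound correctly to sub-annual steps", {
  expect_equal(annual_prob_to_step(0, 0.25), 0)
  expect_equal(annual_prob_to_step(0, 3), 0)
  expect_equal(annual_prob_to_step(0.37, 1), 0.37) # identity at dt = 1
  expect_equal(annual_prob_to_step(0.12, 0.25), 0.0314530718830988,
               tolerance = 1e-12) # 1 - 0.88^0.25
  expect_error(annual_prob_to_step(1.2, 1), "\\[0, 1\\]")
  expect_error(annual_prob_to_step(-0.1, 1), "\\[0, 1\\]")
})

test_that("flows follow probability and number semantics", {
  p <- build_hypertension_demo()
  fw <- p$framework
  values <- casckit:::evaluate_parameters(fw, p$parset, p$initial)
  # without any program, the loss probability is the databook 12%/year
  flows <- compute_flows(p$initial, fw, values, dt = 1)
  expect_equal(flows[1, "tx->dx"], 1183 * 0.12 * 743 / 1183) # from tx pool
  expect_equal(flows[1, "tx->dx"] + flows[1, "ctrl->dx"], 141.96)
  # empty compartment: all its outflows are zero
  sizes <- p$initial$sizes; sizes[, "tx"] <- 0
  st0 <- cascade_state(2016, sizes)
  flows0 <- compute_flows(st0, fw, values, dt = 1)
  expect_equal(unname(flows0[1, c("tx->dx", "tx->ctrl", "tx->dead")]),
               c(0, 0, 0))
  # negative parameter value is an error
  values[, "incidence"] <- -1
  expect_error(compute_flows(p$initial, fw, values, dt = 1), "negative")
})

test_that("excess outflows are rescaled proportionally and never go negative", {
  # two number-format outflows proposing 60 + 60 from a compartment of 100
  fw <- cascade_framework(
    "cap",
    compartments = data.frame(code = c("a", "b", "c"),
                              label = c("a", "b", "c"), role = "normal"),
    transitions = data.frame(from = c("a", "a"), to = c("b", "c"),
                             parameter = c("n_ab", "n_ac")),
    parameters = data.frame(code = c("n_ab", "n_ac"),
                            label = c("ab", "ac"),
                            format = "number_per_year", formula = "",
                            databook_entry = TRUE),
    stages = data.frame(name = "all", constituents = "a;b;c"))
  parset <- cascade_parset("pop", list(pop = list(n_ab = 60, n_ac = 60)))
  st <- cascade_state(2020, matrix(c(100, 0, 0), 1,
                                   dimnames = list("pop", c("a", "b", "c"))))
  values <- casckit:::evaluate_parameters(fw, parset, st)
  flows <- compute_flows(st, fw, values, dt = 1)
  expect_equal(unname(flows[1, ]), c(50, 50))
  stepped <- casckit:::apply_flows(st, fw, flows, 1, casckit:::fw_engine_index(fw))
  expect_equal(unname(stepped$state$sizes[1, ]), c(0, 50, 50))

  # same-step inflows count towards availability before capping bites
  fw2 <- cascade_framework(
    "cap2",
    compartments = data.frame(code = c("a", "b", "c"),
                              label = c("a", "b", "c"), role = "normal"),
    transitions = data.frame(from = c("a", "b"), to = c("b", "c"),
                             parameter = c("n_ab", "n_bc")),
    parameters = data.frame(code = c("n_ab", "n_bc"),
                            label = c("ab", "bc"),
                            format = "number_per_year", formula = "",
                            databook_entry = TRUE),
    stages = data.frame(name = "all", constituents = "a;b;c"))
  parset2 <- cascade_parset("pop", list(pop = list(n_ab = 80, n_bc = 90)))
  st2 <- cascade_state(2020, matrix(c(100, 20, 0), 1,
                                    dimnames = list("pop", c("a", "b", "c"))))
  values2 <- casckit:::evaluate_parameters(fw2, parset2, st2)
  flows2 <- compute_flows(st2, fw2, values2, dt = 1)
  expect_equal(unname(flows2[1, ]), c(80, 90)) # 20 + 80 inflow covers 90
  nxt <- casckit:::apply_flows(st2, fw2, flows2, 1,
                               casckit:::fw_engine_index(fw2))
  expect_true(all(nxt$state$sizes >= 0))
})

test_that("stepping conserves persons and zero parameters freeze the state", {
  proj <- make_chain_project(p_ab = 0, p_bc = 0, inflow = 0, exit = 0)
  sim <- run_simulation(proj$framework, proj$parset, proj$initial,
                        t1 = 2025, dt = 1)
  expect_equal(sim$sizes[6, , ], sim$sizes[1, , ])

  proj <- make_chain_project()
  sim <- run_simulation(proj$framework, proj$parset, proj$initial,
                        t1 = 2025, dt = 1)
  expect_lt(conservation_error(sim), 1e-9)
})

test_that("conservation and nonnegativity hold for random inputs", {
  for (seed in 1:12) {
    proj <- make_random_project(n_comp = sample(3:5, 1), seed = seed)
    sim <- run_simulation(proj$framework, proj$parset, proj$initial,
                          t1 = 2024, dt = 0.5)
    expect_lt(conservation_error(sim), 1e-9)
    expect_true(all(sim$sizes >= 0), info = sprintf("seed %d", seed))
  }
})

test_that("simulation grid handling: zero-length runs and dt divisibility", {
  proj <- make_chain_project()
  sim <- run_simulation(proj$framework, proj$parset, proj$initial,
                        t1 = 2020, dt = 1)
  expect_identical(sim$times, 2020)
  expect_equal(sim$sizes[1, , ], proj$initial$sizes[1, ])
  expect_error(run_simulation(proj$framework, proj$parset, proj$initial,
                              t1 = 2021.5, dt = 1), "divide")
  expect_error(run_simulation(proj$framework, proj$parset, proj$initial,
                              t1 = 2019, dt = 1), "t1")
})

test_that("halving dt changes demo stage values by under 2 percent", {
  p <- build_hypertension_demo()
  s1 <- extract_cascade(run_project(p, dt = 1), p$framework, 2017)
  s2 <- extract_cascade(run_project(p, dt = 0.5), p$framework, 2017)
  expect_true(all(abs(s2 - s1) / s1 < 0.02))
})

test_that("cascade extraction sums constituents and is additive over populations", {
  p <- build_hypertension_demo()
  sim <- run_project(p)
  casc <- extract_cascade(sim, p$framework, 2016)
  expect_equal(unname(casc), c(4096, 1708, 1183, 440))
  expect_error(extract_cascade(sim, p$framework, 2030), "outside")

  # two-population chain: aggregate equals the sum of the per-population rows
  fw <- make_chain_framework()
  parset <- cascade_parset(c("m", "f"), list(
    m = list(p_ab = 0.3, p_bc = 0.2, inflow = 10, exit = 0.05),
    f = list(p_ab = 0.1, p_bc = 0.4, inflow = 5, exit = 0.02)))
  init <- cascade_state(2020, matrix(c(100, 20, 5, 200, 50, 10), 2,
                                     byrow = TRUE,
                                     dimnames = list(c("m", "f"),
                                                     c("a", "b", "c"))))
  sim2 <- run_simulation(fw, parset, init, t1 = 2023, dt = 1)
  agg <- extract_cascade(sim2, fw, 2023)
  per <- extract_cascade(sim2, fw, 2023, by_population = TRUE)
  expect_equal(agg, rowSums(per))
  # exact stage sums from the state
  expect_equal(agg[["all"]], sum(sim2$sizes[4, , ]))

  # all-in-first-compartment state
  init3 <- cascade_state(2020, matrix(c(500, 0, 0), 1,
                                      dimnames = list("pop",
                                                      c("a", "b", "c"))))
  parset3 <- cascade_parset("pop", list(pop = list(
    p_ab = 0, p_bc = 0, inflow = 0, exit = 0)))
  sim3 <- run_simulation(fw, parset3, init3, t1 = 2021, dt = 1)
  expect_equal(unname(extract_cascade(sim3, fw, 2021)), c(500, 0, 0))
})

test_that("loss accounting: endpoint drop-offs and cumulative loss flows", {
  p <- build_hypertension_demo()
  sim <- run_project(p)
  drops16 <- loss_accounting(sim, p$framework, "endpoint_dropoff",
                             year = 2016)
  expect_equal(unname(drops16), c(2388, 525, 743))
  # drop-offs telescope to first minus last stage
  drops17 <- loss_accounting(sim, p$framework, "endpoint_dropoff",
                             year = 2017)
  casc <- extract_cascade(sim, p$framework, 2017)
  expect_equal(sum(drops17), casc[[1]] - casc[[length(casc)]])

  # cumulative flow mode totals the loss-marked transitions: 93.96 persons
  flows <- loss_accounting(sim, p$framework, "cumulative_flow")
  expect_equal(sum(flows), 93.96, tolerance = 1e-9)

  # no loss-marked transitions -> zero
  proj <- make_chain_project()
  sim2 <- run_simulation(proj$framework, proj$parset, proj$initial,
                         t1 = 2022, dt = 1)
  expect_equal(sum(loss_accounting(sim2, proj$framework, "cumulative_flow")),
               0)
})
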