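# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# Minimal linear chain framework a -> b -> c with probability-governed
# transitions, optional source inflow into a and sink outflow from every
# normal compartment.
make_chain_framework <- function(with_source_sink = TRUE) {
  comps <- data.frame(
    code = c("a", "b", "c"),
    label = c("Stage A", "Stage B", "Stage C"),
    role = "normal", stringsAsFactors = FALSE)
  trans <- data.frame(
    from = c("a", "b"), to = c("b", "c"),
    parameter = c("p_ab", "p_bc"), stringsAsFactors = FALSE)
  pars <- data.frame(
    code = c("p_ab", "p_bc"),
    label = c("A to B", "B to C"),
    format = "probability_per_year", formula = "",
    databook_entry = TRUE, stringsAsFactors = FALSE)
  if (with_source_sink) {
    comps <- rbind(comps, data.frame(code = c("born", "gone"),
                                     label = c("Inflow", "Outflow"),
                                     role = c("source", "sink")))
    trans <- rbind(trans,
                   data.frame(from = c("born", "a", "b", "c"),
                              to = c("a", "gone", "gone", "gone"),
                              parameter = c("inflow", "exit", "exit", "exit")))
    pars <- rbind(pars,
                  data.frame(code = c("inflow", "exit"),
                             label = c("Arrivals", "Departure"),
                             format = c("number_per_year",
                                        "probability_per_year"),
                             formula = "", databook_entry = TRUE))
  }
  cascade_framework(
    "chain",
    compartments = comps, transitions = trans, parameters = pars,
    stages = data.frame(name = c("all", "reached_b", "reached_c"),
                        constituents = c("a;b;c", "b;c", "c"),
                        stringsAsFactors = FALSE))
}

make_chain_project <- function(p_ab = 0.3, p_bc = 0.2, inflow = 10,
                               exit = 0.05, sizes = c(a = 1000, b = 200,
                                                      c = 50),
                               t0 = 2020, t1 = 2025) {
  fw <- make_chain_framework()
  parset <- cascade_parset("pop", list(pop = list(
    p_ab = p_ab, p_bc = p_bc, inflow = inflow, exit = exit)))
  initial <- cascade_state(t0, matrix(sizes, nrow = 1,
                                      dimnames = list("pop", names(sizes))))
  cascade_project(fw, parset, initial,
                  settings = list(t0 = t0, t1 = t1, dt = 1))
}

# Random single-population framework + inputs for conservation property
# tests: a chain of n compartments with random forward/backward transitions.
make_random_project <- function(n_comp = 4, seed = 1) {
  set.seed(seed)
  codes <- paste0("c", seq_len(n_comp))
  trans <- data.frame(from = character(), to = character(),
                      parameter = character(), stringsAsFactors = FALSE)
  pars <- data.frame(code = character(), label = character(),
                     format = character(), formula = character(),
                     databook_entry = logical(), stringsAsFactors = FALSE)
  k <- 0
  for (i in seq_len(n_comp)) for (j in seq_len(n_comp)) {
    if (i != j && stats::runif(1) < 0.5) {
      k <- k + 1
      pc <- paste0("p", k)
      trans <- rbind(trans, data.frame(from = codes[i], to = codes[j],
                                       parameter = pc))
      pars <- rbind(pars, data.frame(code = pc, label = pc,
                                     format = "probability_per_year",
                                     formula = "", databook_entry = TRUE))
    }
  }
  # guarantee at least one transition
  if (!nrow(trans)) {
    trans <- data.frame(from = codes[1], to = codes[2], parameter = "p1")
    pars <- data.frame(code = "p1", label = "p1",
                       format = "probability_per_year", formula = "",
                       databook_entry = TRUE)
  }
  trans <- rbind(trans, data.frame(from = "src", to = codes[1],
                                   parameter = "inflow"),
                 data.frame(from = codes, to = "snk", parameter = "death"))
  pars <- rbind(pars,
                data.frame(code = c("inflow", "death"),
                           label = c("inflow", "death"),
                           format = c("number_per_year",
                                      "probability_per_year"),
                           formula = "", databook_entry = TRUE))
  comps <- data.frame(code = c(codes, "src", "snk"),
                      label = c(codes, "src", "snk"),
                      role = c(rep("normal", n_comp), "source", "sink"),
                      stringsAsFactors = FALSE)
  stages <- data.frame(
    name = paste0("s", seq_len(n_comp)),
    constituents = vapply(seq_len(n_comp), function(i) {
      paste(codes[i:n_comp], collapse = ";")
    }, ""), stringsAsFactors = FALSE)
  fw <- cascade_framework("random", comps, trans, pars, stages)
  vals <- as.list(stats::setNames(stats::runif(nrow(pars), 0, 0.9),
                                  pars$code))
  vals$inflow <- stats::runif(1, 0, 100)
  parset <- cascade_parset("pop", list(pop = vals))
  initial <- cascade_state(2020, matrix(stats::runif(n_comp, 0, 1000),
                                        nrow = 1,
                                        dimnames = list("pop", codes)))
  cascade_project(fw, parset, initial,
                  settings = list(t0 = 2020, t1 = 2024, dt = 1))
}

# Conservation check for a simulation with cumulative source/sink tallies.
conservation_error <- function(sim) {
  tot <- apply(sim$sizes, 1, sum)
  expected <- tot[1] + sim$source_in[, 1] - sim$sink_out[, 1]
  max(abs(tot - expected) / pmax(1, abs(expected)))
}
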