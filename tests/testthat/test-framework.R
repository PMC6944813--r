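test_that("the hypertension demo framework validates with zero errors", {
  fw <- build_hypertension_demo()$framework
  rep <- validate_framework(fw)
  expect_s3_class(rep, "cascade_validation")
  expect_identical(nrow(rep$errors), 0L)
  expect_true(fw_is_valid(fw))
  # validation is idempotent and side-effect free
  rep2 <- validate_framework(fw)
  expect_identical(rep$errors, rep2$errors)
  expect_identical(rep$warnings, rep2$warnings)
})

test_that("referential and structural problems are reported, not raised", {
  fw <- make_chain_framework()
  fw$transitions$to[1] <- "tx" # unknown compartment
  rep <- validate_framework(fw)
  expect_true(any(rep$errors$code == "unknown_compartment"))

  fw <- make_chain_framework()
  fw$transitions$from[2] <- "b"
  fw$transitions$to[2] <- "b"
  rep <- validate_framework(fw)
  expect_true(any(rep$errors$code == "self_transition"))

  fw <- make_chain_framework()
  fw$transitions <- rbind(fw$transitions,
                          data.frame(from = "a", to = "born",
                                     parameter = "p_ab", loss = FALSE))
  rep <- validate_framework(fw)
  expect_true(any(rep$errors$code == "source_inflow"))

  fw <- make_chain_framework()
  fw$transitions <- rbind(fw$transitions,
                          data.frame(from = "gone", to = "a",
                                     parameter = "p_ab", loss = FALSE))
  rep <- validate_framework(fw)
  expect_true(any(rep$errors$code == "sink_outflow"))

  fw <- make_chain_framework()
  fw$parameters$code[1] <- "Bad-Name"
  rep <- validate_framework(fw)
  expect_true(any(rep$errors$code == "bad_identifier"))

  fw <- make_chain_framework()
  fw$stage_constituents[["reached_c"]] <- c("c", "gone")
  rep <- validate_framework(fw)
  expect_true(any(rep$errors$code == "stage_role"))
})

test_that("formula dependency cycles are a single validation error", {
  fw <- make_chain_framework(with_source_sink = FALSE)
  fw$parameters <- rbind(fw$parameters, data.frame(
    code = c("par_a", "par_b"), label = c("A", "B"),
    format = "proportion", formula = c("2 * par_b", "par_a + 1"),
    databook_entry = FALSE, stringsAsFactors = FALSE))
  rep <- validate_framework(fw)
  cyc <- rep$errors[rep$errors$code == "formula_error", ]
  expect_identical(nrow(cyc), 1L)
  expect_match(cyc$message, "cycle")
  expect_match(cyc$message, "par_a")
  expect_error(compile_formulas(fw), "cycle")
})

test_that("formula plans are topologically ordered and grammar-checked", {
  fw <- make_chain_framework(with_source_sink = FALSE)
  fw$parameters <- rbind(fw$parameters, data.frame(
    code = c("base_rate", "derived_b", "derived_c"),
    label = c("base", "b", "c"), format = "proportion",
    formula = c("", "base_rate / 2", "min(derived_b + 1, 2) * exp(0)"),
    databook_entry = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE))
  plan <- compile_formulas(fw)
  expect_lt(match("derived_b", plan$order), match("derived_c", plan$order))

  # chain c = f(b), b = f(a): order must be (b, c)
  fw2 <- make_chain_framework(with_source_sink = FALSE)
  fw2$parameters <- rbind(fw2$parameters, data.frame(
    code = c("pa", "pb", "pc"), label = c("a", "b", "c"),
    format = "proportion", formula = c("", "pa * 2", "pb + 1"),
    databook_entry = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE))
  expect_identical(compile_formulas(fw2)$order, c("pb", "pc"))

  # empty formula set -> empty plan
  expect_length(compile_formulas(make_chain_framework())$order, 0L)

  # unknown function and unknown code are rejected
  fw3 <- make_chain_framework(with_source_sink = FALSE)
  fw3$parameters$formula[1] <- "sqrt(p_bc)"
  fw3$parameters$databook_entry[1] <- FALSE
  expect_error(compile_formulas(fw3), "unknown function")
  fw3$parameters$formula[1] <- "p_bc + nonexistent"
  expect_error(compile_formulas(fw3), "undefined")
})

test_that("cycle detection agrees with an independent oracle on random digraphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(2:6, 1)
    codes <- paste0("v", seq_len(n))
    edges <- which(matrix(stats::runif(n * n) < 0.35, n, n) &
                     !diag(n), arr.ind = TRUE)
    fw <- make_chain_framework(with_source_sink = FALSE)
    deps_text <- vapply(seq_len(n), function(i) {
      src <- codes[edges[edges[, 2] == i, 1]]
      if (!length(src)) "" else paste(src, collapse = " + ")
    }, "")
    fw$parameters <- rbind(fw$parameters, data.frame(
      code = codes, label = codes, format = "proportion",
      formula = deps_text, databook_entry = deps_text == "",
      stringsAsFactors = FALSE))
    ours_acyclic <- !inherits(try(compile_formulas(fw), silent = TRUE),
                              "try-error")
    g <- igraph::make_graph(t(edges), n = n, directed = TRUE)
    expect_identical(ours_acyclic, igraph::is_dag(g),
                     info = sprintf("seed %d", seed))
  }
})

test_that("stage membership reports nesting and flags non-classic cascades", {
  fw <- build_hypertension_demo()$framework
  mem <- stage_membership(fw)
  expect_identical(mem$diagnosed, c("dx", "tx", "ctrl"))
  expect_identical(mem$controlled, "ctrl")
  expect_true(all(attr(mem, "nested")))

  expect_error(stage_membership(fw, "nope"), "unknown stage")
  expect_identical(stage_membership(fw, "treated")$treated, c("tx", "ctrl"))

  fw2 <- make_chain_framework()
  fw2$stage_constituents <- list(first = "a", second = c("b", "c"))
  fw2$stages <- data.frame(name = c("first", "second"), index = 1:2)
  expect_warning(stage_membership(fw2), "not nested")
  rep <- validate_framework(fw2)
  expect_true(any(rep$warnings$code == "non_nested_stages"))
  expect_identical(nrow(rep$errors), 0L) # warning, never an error

  # single-stage cascade is trivially nested
  fw3 <- make_chain_framework()
  fw3$stage_constituents <- list(only = c("a", "b", "c"))
  fw3$stages <- data.frame(name = "only", index = 1L)
  expect_silent(stage_membership(fw3))
})

test_that("a framework with no transitions warns about isolation", {
  fw <- make_chain_framework(with_source_sink = FALSE)
  fw$transitions <- fw$transitions[0, ]
  rep <- validate_framework(fw)
  expect_identical(nrow(rep$errors), 0L)
  expect_true(any(rep$warnings$code == "isolated_compartment"))
})
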