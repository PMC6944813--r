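#' Declarative definition of a cascade model
#'
#' A framework holds everything about the *structure* of a care cascade:
#' the mutually exclusive compartments people can occupy, the transitions
#' between them, the parameters that govern those transitions (entered in a
#' databook or derived by formula), and the cascade stages, each defined as
#' a sum of compartments. It contains no context-specific data; those live
#' in the databook and program book.
#'
#' @param name Framework name.
#' @param compartments `data.frame` with columns `code`, `label`, `role`;
#'   `role` is one of `"normal"`, `"source"` (houses inflow such as disease
#'   incidence; no in-transitions) or `"sink"` (houses outflow such as death;
#'   no out-transitions).
#' @param transitions `data.frame` with columns `from`, `to`, `parameter` and
#'   an optional logical column `loss` marking transitions that count as
#'   cascade losses (e.g. loss to follow-up) for loss accounting.
#' @param parameters `data.frame` with columns `code`, `label`, `format`
#'   (one of `"probability_per_year"`, `"number_per_year"`, `"proportion"`),
#'   `formula` (expression text, or `""`/`NA` for none) and `databook_entry`
#'   (logical). A parameter either carries a formula or is databook-entered,
#'   never both.
#' @param stages `data.frame` with columns `name` and `constituents`, the
#'   latter a `";"`-separated list of compartment codes (or a list column of
#'   character vectors). Stage order is row order.
#'
#' @return An object of class `cascade_framework`.
#' @seealso [validate_framework()], [compile_formulas()], [stage_membership()]
#' @export
cascade_framework <- function(name, compartments, transitions, parameters,
                              stages) {
  compartments <- as.data.frame(compartments, stringsAsFactors = FALSE)
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  parameters <- as.data.frame(parameters, stringsAsFactors = FALSE)
  stages_in <- stages

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop_ck("framework %s table lacks column(s): %s", what,
              paste(miss, collapse = ", "))
    }
  }
  need(compartments, c("code", "label", "role"), "compartments")
  if (nrow(transitions)) need(transitions, c("from", "to", "parameter"),
                              "transitions")
  if (!nrow(transitions)) {
    transitions <- data.frame(from = character(), to = character(),
                              parameter = character(), loss = logical(),
                              stringsAsFactors = FALSE)
  }
  if (is.null(transitions$loss)) transitions$loss <- FALSE
  transitions$loss <- as.logical(transitions$loss)
  transitions$loss[is.na(transitions$loss)] <- FALSE
  need(parameters, c("code", "label", "format"), "parameters")
  if (is.null(parameters$formula)) parameters$formula <- ""
  parameters$formula[is.na(parameters$formula)] <- ""
  parameters$formula <- trimws(as.character(parameters$formula))
  if (is.null(parameters$databook_entry)) {
    parameters$databook_entry <- parameters$formula == ""
  }
  parameters$databook_entry <- as.logical(parameters$databook_entry)

  if (is.data.frame(stages_in)) {
    need(stages_in, c("name", "constituents"), "cascade")
    cons <- stages_in$constituents
    if (!is.list(cons)) {
      cons <- lapply(strsplit(as.character(cons), ";", fixed = TRUE), trimws)
    }
    stage_names <- as.character(stages_in$name)
  } else {
    stage_names <- names(stages_in)
    cons <- stages_in
  }
  cons <- lapply(cons, function(x) x[nzchar(x)])
  names(cons) <- stage_names

  structure(
    list(name = name, compartments = compartments, transitions = transitions,
         parameters = parameters,
         stages = data.frame(name = stage_names,
                             index = seq_along(stage_names),
                             stringsAsFactors = FALSE),
         stage_constituents = cons),
    class = "cascade_framework"
  )
}

#' @export
print.cascade_framework <- function(x, ...) {
  cat(sprintf(
    "<cascade_framework '%s': %d compartments, %d transitions, %d parameters, %d stages>\n",
    x$name, nrow(x$compartments), nrow(x$transitions), nrow(x$parameters),
    nrow(x$stages)))
  invisible(x)
}

fw_comp_codes <- function(fw, roles = c("normal", "source", "sink")) {
  fw$compartments$code[fw$compartments$role %in% roles]
}

fw_param_row <- function(fw, code) {
  fw$parameters[match(code, fw$parameters$code), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Formula expression grammar
#
# Formulas may reference parameter and compartment codes and use numeric
# literals, + - * /, parentheses and the functions min, max, exp. Text is
# parsed with R's parser and the syntax tree is checked against this
# whitelist, so anything outside the grammar (other functions, indexing,
# assignment, control flow) is rejected before evaluation.
# ---------------------------------------------------------------------------

.formula_funs <- c("+", "-", "*", "/", "(", "min", "max", "exp")

parse_formula <- function(text) {
  expr <- tryCatch(str2lang(text), error = function(e) {
    stop_ck("cannot parse formula '%s': %s", text, conditionMessage(e))
  })
  vars <- character()
  walk <- function(e) {
    if (is.numeric(e)) return(invisible())
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (!is_identifier(nm)) {
        stop_ck("formula '%s': invalid identifier '%s'", text, nm)
      }
      vars <<- c(vars, nm)
      return(invisible())
    }
    if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (!fn %in% .formula_funs) {
        stop_ck("formula '%s': unknown function or operator '%s'", text, fn)
      }
      for (i in seq_along(e)[-1]) walk(e[[i]])
      return(invisible())
    }
    stop_ck("formula '%s': unsupported element", text)
  }
  walk(expr)
  list(expr = expr, vars = unique(vars))
}

eval_formula <- function(compiled, values) {
  eval(compiled$expr, envir = as.list(values), enclos = baseenv())
}

# Kahn's algorithm over the formula dependency digraph. Returns the
# evaluation order, or the codes on a cycle as an error condition.
topo_sort_formulas <- function(codes, deps) {
  indeg <- stats::setNames(integer(length(codes)), codes)
  fwd <- stats::setNames(vector("list", length(codes)), codes)
  for (code in codes) {
    for (d in intersect(deps[[code]], codes)) {
      indeg[[code]] <- indeg[[code]] + 1L
      fwd[[d]] <- c(fwd[[d]], code)
    }
  }
  queue <- names(indeg)[indeg == 0L]
  order <- character()
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]
    order <- c(order, n)
    for (m in fwd[[n]]) {
      indeg[[m]] <- indeg[[m]] - 1L
      if (indeg[[m]] == 0L) queue <- c(queue, m)
    }
  }
  if (length(order) < length(codes)) {
    cyc <- setdiff(codes, order)
    stop_ck("formula dependency cycle involving: %s",
            paste(sort(cyc), collapse = ", "))
  }
  order
}

#' Compile parameter formulas into an ordered evaluation plan
#'
#' Parses every formula-bearing parameter, checks the expression grammar and
#' topologically orders the parameters so each formula is evaluated after
#' everything it references.
#'
#' @param fw A [cascade_framework()].
#' @return An object of class `cascade_plan`: a list with `order` (parameter
#'   codes in evaluation order), `compiled` (parsed expressions keyed by
#'   code) and `deps` (referenced codes per formula).
#' @export
compile_formulas <- function(fw) {
  prm <- fw$parameters
  fcodes <- prm$code[prm$formula != ""]
  compiled <- list()
  deps <- list()
  known <- c(prm$code, fw$compartments$code)
  for (code in fcodes) {
    cf <- parse_formula(prm$formula[prm$code == code])
    unknown <- setdiff(cf$vars, known)
    if (length(unknown)) {
      stop_ck("formula for '%s' references undefined code(s): %s",
              code, paste(unknown, collapse = ", "))
    }
    compiled[[code]] <- cf
    deps[[code]] <- cf$vars
  }
  order <- topo_sort_formulas(fcodes, deps)
  structure(list(order = order, compiled = compiled, deps = deps),
            class = "cascade_plan")
}

# ---------------------------------------------------------------------------
# Validation
# ---------------------------------------------------------------------------

vr_add <- function(rep, kind, code, message, location) {
  rep[[kind]] <- rbind(rep[[kind]],
                       data.frame(code = code, message = message,
                                  location = location,
                                  stringsAsFactors = FALSE))
  rep
}

#' Validate a framework
#'
#' Checks every structural invariant of the model definition and returns a
#' report rather than raising errors, so a file-based workflow can surface
#' all problems at once. A framework is usable iff the report has zero
#' errors ([fw_is_valid()]).
#'
#' Checked as errors: unique, well-formed codes; known roles and parameter
#' formats; transition endpoints exist, differ, and reference defined
#' parameters; sources have no in-transitions and sinks no out-transitions;
#' transitions out of a source are governed by `number_per_year` parameters
#' (a source has no size for a probability to act on); each parameter has a
#' formula or is databook-entered, not both; formulas parse, reference only
#' defined codes and form an acyclic dependency graph; stage constituents
#' exist and exclude sources/sinks. Non-nested cascade stages and isolated
#' compartments are warnings: backward-moving and restart-at-beginning
#' cascades are legitimate designs.
#'
#' @param fw A [cascade_framework()].
#' @return An object of class `cascade_validation` with `errors` and
#'   `warnings` data frames (columns `code`, `message`, `location`).
#' @export
validate_framework <- function(fw) {
  rep <- structure(list(
    errors = data.frame(code = character(), message = character(),
                        location = character(), stringsAsFactors = FALSE),
    warnings = data.frame(code = character(), message = character(),
                          location = character(), stringsAsFactors = FALSE)),
    class = "cascade_validation")

  cmp <- fw$compartments; trn <- fw$transitions; prm <- fw$parameters

  dup <- unique(cmp$code[duplicated(cmp$code)])
  for (d in dup) rep <- vr_add(rep, "errors", "duplicate_code",
                               sprintf("duplicate compartment code '%s'", d),
                               "compartments")
  dup <- unique(prm$code[duplicated(prm$code)])
  for (d in dup) rep <- vr_add(rep, "errors", "duplicate_code",
                               sprintf("duplicate parameter code '%s'", d),
                               "parameters")
  dup <- unique(fw$stages$name[duplicated(fw$stages$name)])
  for (d in dup) rep <- vr_add(rep, "errors", "duplicate_stage",
                               sprintf("duplicate stage name '%s'", d),
                               "cascade")

  bad <- cmp$code[!is_identifier(cmp$code)]
  for (b in bad) rep <- vr_add(rep, "errors", "bad_identifier",
                               sprintf("compartment code '%s' is not a valid identifier", b),
                               "compartments")
  bad <- prm$code[!is_identifier(prm$code)]
  for (b in bad) rep <- vr_add(rep, "errors", "bad_identifier",
                               sprintf("parameter code '%s' is not a valid identifier", b),
                               "parameters")

  bad <- cmp$code[!cmp$role %in% c("normal", "source", "sink")]
  for (b in bad) rep <- vr_add(rep, "errors", "bad_role",
                               sprintf("compartment '%s' has unknown role", b),
                               "compartments")
  ok_fmt <- c("probability_per_year", "number_per_year", "proportion")
  bad <- prm$code[!prm$format %in% ok_fmt]
  for (b in bad) rep <- vr_add(rep, "errors", "bad_format",
                               sprintf("parameter '%s' has unknown format", b),
                               "parameters")

  # transitions
  if (nrow(trn)) {
    for (i in seq_len(nrow(trn))) {
      loc <- sprintf("transitions[%d]", i)
      for (endp in c("from", "to")) {
        code <- trn[[endp]][i]
        if (!code %in% cmp$code) {
          rep <- vr_add(rep, "errors", "unknown_compartment",
                        sprintf("transition references unknown compartment '%s'", code),
                        loc)
        }
      }
      if (identical(trn$from[i], trn$to[i])) {
        rep <- vr_add(rep, "errors", "self_transition",
                      sprintf("transition from '%s' to itself", trn$from[i]), loc)
      }
      if (!trn$parameter[i] %in% prm$code) {
        rep <- vr_add(rep, "errors", "unknown_parameter",
                      sprintf("transition governed by unknown parameter '%s'",
                              trn$parameter[i]), loc)
      }
    }
    roles <- stats::setNames(cmp$role, cmp$code)
    for (i in seq_len(nrow(trn))) {
      loc <- sprintf("transitions[%d]", i)
      rfrom <- roles[trn$from[i]]; rto <- roles[trn$to[i]]
      if (isTRUE(rto == "source")) {
        rep <- vr_add(rep, "errors", "source_inflow",
                      sprintf("source compartment '%s' may not receive transitions",
                              trn$to[i]), loc)
      }
      if (isTRUE(rfrom == "sink")) {
        rep <- vr_add(rep, "errors", "sink_outflow",
                      sprintf("sink compartment '%s' may not have out-transitions",
                              trn$from[i]), loc)
      }
      if (isTRUE(rfrom == "source") && trn$parameter[i] %in% prm$code) {
        fmt <- prm$format[prm$code == trn$parameter[i]][1]
        if (fmt != "number_per_year") {
          rep <- vr_add(rep, "errors", "source_format",
                        sprintf("transition out of source '%s' must be governed by a number_per_year parameter",
                                trn$from[i]), loc)
        }
      }
    }
    normal_used <- cmp$code[cmp$role == "normal"] %in% c(trn$from, trn$to)
    for (b in cmp$code[cmp$role == "normal"][!normal_used]) {
      rep <- vr_add(rep, "warnings", "isolated_compartment",
                    sprintf("compartment '%s' has no transitions", b),
                    "transitions")
    }
  } else if (nrow(cmp)) {
    rep <- vr_add(rep, "warnings", "isolated_compartment",
                  "framework has no transitions; all compartments are isolated",
                  "transitions")
  }

  # parameters: formula XOR databook
  for (i in seq_len(nrow(prm))) {
    has_f <- prm$formula[i] != ""
    if (has_f && isTRUE(prm$databook_entry[i])) {
      rep <- vr_add(rep, "errors", "formula_and_databook",
                    sprintf("parameter '%s' both has a formula and is databook-entered",
                            prm$code[i]), "parameters")
    }
    if (!has_f && !isTRUE(prm$databook_entry[i])) {
      rep <- vr_add(rep, "errors", "no_value_source",
                    sprintf("parameter '%s' has neither formula nor databook entry",
                            prm$code[i]), "parameters")
    }
  }

  # formulas: grammar, references, cycles
  plan_err <- tryCatch({ compile_formulas(fw); NULL },
                       error = function(e) conditionMessage(e))
  if (!is.null(plan_err)) {
    rep <- vr_add(rep, "errors", "formula_error", plan_err, "parameters")
  }

  # stages
  ns_codes <- fw_comp_codes(fw, c("source", "sink"))
  for (i in seq_len(nrow(fw$stages))) {
    nm <- fw$stages$name[i]
    cons <- fw$stage_constituents[[i]]
    loc <- sprintf("cascade['%s']", nm)
    if (!length(cons)) {
      rep <- vr_add(rep, "errors", "empty_stage",
                    sprintf("stage '%s' has no constituents", nm), loc)
    }
    for (b in setdiff(cons, cmp$code)) {
      rep <- vr_add(rep, "errors", "unknown_compartment",
                    sprintf("stage '%s' references unknown compartment '%s'", nm, b),
                    loc)
    }
    for (b in intersect(cons, ns_codes)) {
      rep <- vr_add(rep, "errors", "stage_role",
                    sprintf("stage '%s' includes source/sink compartment '%s'", nm, b),
                    loc)
    }
  }
  if (nrow(fw$stages) > 1L) {
    for (i in seq_len(nrow(fw$stages) - 1L)) {
      a <- fw$stage_constituents[[i]]; b <- fw$stage_constituents[[i + 1L]]
      if (!all(b %in% a)) {
        rep <- vr_add(rep, "warnings", "non_nested_stages",
                      sprintf("stage '%s' is not a subset of stage '%s' (non-classic cascade)",
                              fw$stages$name[i + 1L], fw$stages$name[i]),
                      "cascade")
      }
    }
  }
  rep
}

#' @export
print.cascade_validation <- function(x, ...) {
  cat(sprintf("<cascade_validation: %d error(s), %d warning(s)>\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) print(x$errors)
  if (nrow(x$warnings)) print(x$warnings)
  invisible(x)
}

#' Is a framework usable?
#'
#' @param x A `cascade_validation` report or a `cascade_framework`.
#' @return `TRUE` iff validation produced zero errors.
#' @export
fw_is_valid <- function(x) {
  if (inherits(x, "cascade_framework")) x <- validate_framework(x)
  nrow(x$errors) == 0L
}

fw_assert_valid <- function(fw) {
  rep <- validate_framework(fw)
  if (nrow(rep$errors)) {
    stop_ck("framework '%s' is invalid: %s", fw$name,
            paste(rep$errors$message, collapse = "; "))
  }
  invisible(rep)
}

#' Stage membership map
#'
#' Returns the constituent compartments of each cascade stage (or of one
#' named stage) and warns whenever a later stage is not nested inside the
#' previous one, which signals a non-classic cascade rather than an error.
#'
#' @param fw A validated [cascade_framework()].
#' @param stage Optional stage name; default returns all stages in order.
#' @return Named list mapping stage name to character vector of compartment
#'   codes, with attribute `nested` (logical, one per adjacent stage pair).
#' @export
stage_membership <- function(fw, stage = NULL) {
  cons <- fw$stage_constituents
  if (!is.null(stage)) {
    if (!stage %in% names(cons)) stop_ck("unknown stage '%s'", stage)
    return(cons[stage])
  }
  nested <- logical(0)
  if (length(cons) > 1L) {
    nested <- vapply(seq_len(length(cons) - 1L), function(i) {
      all(cons[[i + 1L]] %in% cons[[i]])
    }, logical(1))
    if (!all(nested)) {
      warn_ck("cascade stages are not nested (non-classic cascade)")
    }
  }
  attr(cons, "nested") <- nested
  cons
}
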