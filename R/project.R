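#' Create a project
#'
#' A project encapsulates everything needed to analyze one context: the
#' framework (model structure), the databook content (populations, initial
#' compartment sizes, parameter time series), optionally a program set, and
#' the simulation settings (horizon and step size).
#'
#' @param framework A validated [cascade_framework()].
#' @param parset A [cascade_parset()].
#' @param initial Initial [cascade_state()].
#' @param progset Optional [cascade_progset()].
#' @param settings List with `t0`, `t1` (decimal years) and `dt` (years,
#'   default 1).
#' @return An object of class `cascade_project`.
#' @export
cascade_project <- function(framework, parset, initial, progset = NULL,
                            settings) {
  fw_assert_valid(framework)
  parset_check(parset, framework)
  if (!is.null(progset)) progset_check(progset, framework)
  settings$dt <- settings$dt %||% 1
  if (is.null(settings$t0) || is.null(settings$t1)) {
    stop_ck("settings must provide t0 and t1")
  }
  structure(list(framework = framework, parset = parset, initial = initial,
                 progset = progset, settings = settings),
            class = "cascade_project")
}

#' @export
print.cascade_project <- function(x, ...) {
  cat(sprintf("<cascade_project '%s': %g-%g dt=%g, %d population(s), %s>\n",
              x$framework$name, x$settings$t0, x$settings$t1, x$settings$dt,
              length(x$parset$populations),
              if (is.null(x$progset)) "no programs"
              else sprintf("%d program(s)", length(x$progset$programs))))
  invisible(x)
}

#' Run a project's projection
#'
#' Simulates the project over its horizon. By default programs run at their
#' baseline spending (the program book's allocation); pass `allocation` to
#' run under a different budget, or `use_programs = FALSE` to project from
#' databook values alone.
#'
#' @param project A [cascade_project()].
#' @param allocation Optional named list program -> spending
#'   ([cascade_ts()] or single numbers).
#' @param use_programs Apply the program layer (default `TRUE` when the
#'   project has programs).
#' @param t0,t1,dt Optional overrides of the project settings.
#' @return A `cascade_sim` (see [run_simulation()]).
#' @export
run_project <- function(project, allocation = NULL,
                        use_programs = !is.null(project$progset),
                        t0 = project$settings$t0, t1 = project$settings$t1,
                        dt = project$settings$dt) {
  run_simulation(project$framework, project$parset, project$initial,
                 t0 = t0, t1 = t1, dt = dt,
                 progset = if (use_programs) project$progset else NULL,
                 allocation = allocation)
}
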