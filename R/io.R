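# Normative file dialect: UTF-8, comma-delimited, header row, "." decimal,
# one table per file inside a named directory. Framework directories hold
# compartments.csv, transitions.csv, parameters.csv and cascade.csv;
# databooks hold populations.csv, initial_compartments.csv and
# parameter_values.csv; program books hold programs.csv, effects.csv and
# coverage_spending.csv. A project bundle nests all three plus settings.csv.

read_table_file <- function(path, file, required, optional = character()) {
  fp <- file.path(path, file)
  if (!file.exists(fp)) stop_ck("missing table file: %s", fp)
  df <- utils::read.csv(fp, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_ck("%s: missing column(s) %s", fp, paste(miss, collapse = ", "))
  }
  df
}

write_table_file <- function(df, path, file) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(df, file.path(path, file), row.names = FALSE)
}

#' Read / write a framework directory
#'
#' @param path Directory containing `compartments.csv`, `transitions.csv`,
#'   `parameters.csv` and `cascade.csv`.
#' @param name Framework name (default: the directory's base name).
#' @return [read_framework()] returns a [cascade_framework()];
#'   `write_framework` writes one and returns the path invisibly. Writing
#'   then reading round-trips to an equal framework.
#' @export
read_framework <- function(path, name = basename(normalizePath(path))) {
  cmp <- read_table_file(path, "compartments.csv", c("code", "label", "role"))
  if (anyDuplicated(cmp$code)) {
    stop_ck("%s/compartments.csv: duplicate compartment code(s): %s", path,
            paste(unique(cmp$code[duplicated(cmp$code)]), collapse = ", "))
  }
  trn <- read_table_file(path, "transitions.csv",
                         c("from", "to", "parameter"))
  prm <- read_table_file(path, "parameters.csv", c("code", "label", "format"))
  if (anyDuplicated(prm$code)) {
    stop_ck("%s/parameters.csv: duplicate parameter code(s): %s", path,
            paste(unique(prm$code[duplicated(prm$code)]), collapse = ", "))
  }
  csc <- read_table_file(path, "cascade.csv", c("name", "constituents"))
  cascade_framework(name, cmp, trn, prm, csc)
}

#' @param fw A [cascade_framework()].
#' @rdname read_framework
#' @export
write_framework <- function(fw, path) {
  write_table_file(fw$compartments, path, "compartments.csv")
  write_table_file(fw$transitions, path, "transitions.csv")
  write_table_file(fw$parameters, path, "parameters.csv")
  csc <- data.frame(
    name = fw$stages$name,
    constituents = vapply(fw$stage_constituents, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  write_table_file(csc, path, "cascade.csv")
  invisible(path)
}

#' Read / write a databook directory
#'
#' @param path Directory containing `populations.csv`,
#'   `initial_compartments.csv` and `parameter_values.csv`.
#' @param fw The validated framework the databook belongs to.
#' @return `read_databook` returns `list(parset, initial)`: a
#'   [cascade_parset()] and the initial [cascade_state()].
#' @export
read_databook <- function(path, fw) {
  pops <- read_table_file(path, "populations.csv", c("code", "label"))
  init <- read_table_file(path, "initial_compartments.csv",
                          c("population", "compartment", "size", "year"))
  vals <- read_table_file(path, "parameter_values.csv",
                          c("population", "parameter", "year", "value"))
  if (any(init$size < 0)) stop_ck("%s: negative initial compartment size", path)
  bad <- setdiff(init$compartment, fw$compartments$code)
  if (length(bad)) {
    stop_ck("%s: initial size for unknown compartment '%s'", path, bad[1])
  }
  bad <- setdiff(vals$parameter, fw$parameters$code)
  if (length(bad)) {
    stop_ck("%s: value for unknown parameter '%s'", path, bad[1])
  }
  normal <- fw_comp_codes(fw, "normal")
  sizes <- matrix(0, nrow(pops), length(normal),
                  dimnames = list(pops$code, normal))
  for (i in seq_len(nrow(init))) {
    if (init$compartment[i] %in% normal) {
      sizes[init$population[i], init$compartment[i]] <- init$size[i]
    }
  }
  year0 <- unique(init$year)[1]
  data <- lapply(pops$code, function(pc) {
    sub <- vals[vals$population == pc, , drop = FALSE]
    out <- list()
    for (pcode in unique(sub$parameter)) {
      rows <- sub[sub$parameter == pcode, , drop = FALSE]
      rows <- rows[order(rows$year), , drop = FALSE]
      interp <- if (!is.null(rows$interpolation) &&
                    nzchar(rows$interpolation[1])) rows$interpolation[1]
                else "linear"
      out[[pcode]] <- cascade_ts(rows$year, rows$value, interp)
    }
    out
  })
  names(data) <- pops$code
  parset <- cascade_parset(pops$code, data)
  parset_check(parset, fw)
  list(parset = parset, initial = cascade_state(year0, sizes),
       populations = pops)
}

#' @param parset,initial,populations Databook content as returned by
#'   `read_databook`.
#' @rdname read_databook
#' @export
write_databook <- function(parset, initial, path, populations = NULL) {
  pops <- populations %||% data.frame(code = parset$populations,
                                      label = parset$populations,
                                      stringsAsFactors = FALSE)
  write_table_file(pops, path, "populations.csv")
  init <- do.call(rbind, lapply(parset$populations, function(pc) {
    data.frame(population = pc, compartment = colnames(initial$sizes),
               size = initial$sizes[pc, ], year = initial$year,
               stringsAsFactors = FALSE)
  }))
  write_table_file(init, path, "initial_compartments.csv")
  vals <- do.call(rbind, lapply(parset$populations, function(pc) {
    do.call(rbind, lapply(names(parset$data[[pc]]), function(pcode) {
      ts <- parset$data[[pc]][[pcode]]
      data.frame(population = pc, parameter = pcode, year = ts$years,
                 value = ts$values, interpolation = ts$interpolation,
                 stringsAsFactors = FALSE)
    }))
  }))
  write_table_file(vals, path, "parameter_values.csv")
  invisible(path)
}

#' Read / write a program book directory
#'
#' @param path Directory containing `programs.csv`, `effects.csv` and
#'   `coverage_spending.csv`.
#' @param fw The validated framework.
#' @return `read_program_book` returns a [cascade_progset()].
#' @export
read_program_book <- function(path, fw) {
  prg <- read_table_file(path, "programs.csv",
                         c("code", "label", "unit_cost", "eligible"))
  eff <- read_table_file(path, "effects.csv", c("program", "mode"))
  cvs <- read_table_file(path, "coverage_spending.csv", c("program", "year"))
  bad <- setdiff(c(eff$program, cvs$program), prg$code)
  if (length(bad)) {
    stop_ck("%s: data for unknown program '%s'", path, bad[1])
  }
  programs <- lapply(seq_len(nrow(prg)), function(i) {
    code <- prg$code[i]
    effects <- lapply(which(eff$program == code), function(j) {
      if (eff$mode[j] == "coverage_blend") {
        program_effect_blend(eff$parameter[j],
                             as.numeric(eff$value_covered[j]),
                             as.numeric(eff$value_uncovered[j]))
      } else if (eff$mode[j] == "conversion_flow") {
        chain <- as.numeric(strsplit(as.character(eff$chain[j]), ";",
                                     fixed = TRUE)[[1]])
        program_effect_conversion(eff$from[j], eff$to[j], chain)
      } else {
        stop_ck("%s/effects.csv: unknown effect mode '%s'", path, eff$mode[j])
      }
    })
    rows <- cvs[cvs$program == code, , drop = FALSE]
    rows <- rows[order(rows$year), , drop = FALSE]
    cov_ts <- NULL; sp_ts <- NULL
    if (!is.null(rows$coverage) && any(!is.na(rows$coverage))) {
      keep <- !is.na(rows$coverage)
      cov_ts <- cascade_ts(rows$year[keep], rows$coverage[keep])
    }
    if (!is.null(rows$spending) && any(!is.na(rows$spending))) {
      keep <- !is.na(rows$spending)
      sp_ts <- cascade_ts(rows$year[keep], rows$spending[keep])
    }
    capacity <- if (!is.null(prg$capacity)) {
      v <- suppressWarnings(as.numeric(prg$capacity[i]))
      if (is.na(v)) Inf else v
    } else Inf
    cascade_program(code, prg$label[i], as.numeric(prg$unit_cost[i]),
                    eligible = trimws(strsplit(prg$eligible[i], ";",
                                               fixed = TRUE)[[1]]),
                    effects = effects, coverage_data = cov_ts,
                    spending_data = sp_ts, capacity = capacity)
  })
  progset <- cascade_progset(programs)
  progset_check(progset, fw)
  progset
}

#' @param progset A [cascade_progset()].
#' @rdname read_program_book
#' @export
write_program_book <- function(progset, path) {
  prg <- do.call(rbind, lapply(progset$programs, function(p) {
    data.frame(code = p$code, label = p$label, unit_cost = p$unit_cost,
               capacity = if (is.finite(p$capacity)) p$capacity else NA,
               eligible = paste(p$eligible, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  write_table_file(prg, path, "programs.csv")
  eff <- do.call(rbind, lapply(progset$programs, function(p) {
    do.call(rbind, lapply(p$effects, function(e) {
      if (e$mode == "coverage_blend") {
        data.frame(program = p$code, mode = e$mode,
                   parameter = e$target_parameter, from = "", to = "",
                   value_covered = e$value_covered,
                   value_uncovered = e$value_uncovered, chain = "",
                   stringsAsFactors = FALSE)
      } else {
        data.frame(program = p$code, mode = e$mode, parameter = "",
                   from = e$from, to = e$to, value_covered = NA,
                   value_uncovered = NA,
                   chain = paste(e$chain, collapse = ";"),
                   stringsAsFactors = FALSE)
      }
    }))
  }))
  write_table_file(eff, path, "effects.csv")
  cvs <- do.call(rbind, lapply(progset$programs, function(p) {
    yrs <- sort(unique(c(if (!is.null(p$coverage_data)) p$coverage_data$years,
                         if (!is.null(p$spending_data)) p$spending_data$years)))
    data.frame(program = p$code, year = yrs,
               coverage = if (!is.null(p$coverage_data)) {
                 ts_interpolate(p$coverage_data, yrs)
               } else NA,
               spending = if (!is.null(p$spending_data)) {
                 ts_interpolate(p$spending_data, yrs)
               } else NA,
               stringsAsFactors = FALSE)
  }))
  write_table_file(cvs, path, "coverage_spending.csv")
  invisible(path)
}

#' Read / write a project bundle
#'
#' A project bundle directory nests `framework/`, `databook/`, `programs/`
#' (optional) and `settings.csv` (keys `t0`, `t1`, `dt`).
#'
#' @param path Bundle directory.
#' @return `read_project` returns a [cascade_project()].
#' @export
read_project <- function(path) {
  fw <- read_framework(file.path(path, "framework"))
  fw_assert_valid(fw)
  db <- read_databook(file.path(path, "databook"), fw)
  progset <- NULL
  if (dir.exists(file.path(path, "programs"))) {
    progset <- read_program_book(file.path(path, "programs"), fw)
  }
  st <- read_table_file(path, "settings.csv", c("key", "value"))
  settings <- as.list(stats::setNames(as.numeric(st$value), st$key))
  cascade_project(fw, db$parset, db$initial, progset, settings)
}

#' @param project A [cascade_project()].
#' @rdname read_project
#' @export
write_project <- function(project, path) {
  write_framework(project$framework, file.path(path, "framework"))
  write_databook(project$parset, project$initial, file.path(path, "databook"))
  if (!is.null(project$progset)) {
    write_program_book(project$progset, file.path(path, "programs"))
  }
  st <- data.frame(key = c("t0", "t1", "dt"),
                   value = c(project$settings$t0, project$settings$t1,
                             project$settings$dt),
                   stringsAsFactors = FALSE)
  write_table_file(st, path, "settings.csv")
  invisible(path)
}

#' Export results to delimited text or structured records
#'
#' Writes the tables appropriate to the result type: simulations produce
#' `cascade.csv` (continuous and reporting-rounded stage values per year),
#' `trajectories.csv` and `flows.csv`; scenario results produce
#' `comparison.csv` plus the scenario tables; optimization results produce
#' `allocation.csv` and `trace.csv`. `format = "records"` additionally
#' writes `results.yaml` with the same content as structured records.
#'
#' @param result A `cascade_sim`, `cascade_scenario_result` or
#'   `cascade_optresult`.
#' @param path Output directory (created if needed).
#' @param fw Framework (needed for `cascade_sim` stage tables).
#' @param format `"delimited"` or `"records"`.
#' @return Invisibly, the paths written.
#' @export
export_results <- function(result, path, fw = NULL,
                           format = c("delimited", "records")) {
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(df, file) {
    utils::write.csv(df, file.path(path, file), row.names = FALSE)
    written <<- c(written, file.path(path, file))
  }
  records <- list()
  if (inherits(result, "cascade_sim")) {
    if (is.null(fw)) stop_ck("export of a simulation needs the framework")
    casc <- do.call(rbind, lapply(result$times, function(y) {
      v <- extract_cascade(result, fw, y)
      data.frame(year = y, stage = names(v), persons = as.numeric(v),
                 persons_report = report_cascade(as.numeric(v)),
                 stringsAsFactors = FALSE)
    }))
    emit(casc, "cascade.csv")
    traj <- do.call(rbind, lapply(seq_along(result$times), function(ti) {
      do.call(rbind, lapply(result$populations, function(pp) {
        data.frame(year = result$times[ti], population = pp,
                   compartment = result$compartments,
                   size = result$sizes[ti, pp, ], stringsAsFactors = FALSE)
      }))
    }))
    emit(traj, "trajectories.csv")
    if (dim(result$flows)[1] > 0) {
      fl <- do.call(rbind, lapply(seq_len(dim(result$flows)[1]), function(k) {
        do.call(rbind, lapply(result$populations, function(pp) {
          data.frame(step_start = result$times[k], population = pp,
                     transition = dimnames(result$flows)[[3]],
                     persons = result$flows[k, pp, ],
                     stringsAsFactors = FALSE)
        }))
      }))
      emit(fl, "flows.csv")
    }
    records$cascade <- casc
  } else if (inherits(result, "cascade_scenario_result")) {
    cmp <- scenario_comparison(result, max(result$scenario$times))
    emit(cmp, "comparison.csv")
    records$comparison <- cmp
  } else if (inherits(result, "cascade_optresult")) {
    if (!is.null(result$allocation)) {
      al <- do.call(rbind, lapply(names(result$allocation), function(p) {
        ts <- result$allocation[[p]]
        data.frame(program = p, year = ts$years, spending = ts$values,
                   stringsAsFactors = FALSE)
      }))
      emit(al, "allocation.csv")
      records$allocation <- al
    }
    if (!is.null(result$trace)) emit(result$trace, "trace.csv")
    records$best_value <- result$value
  } else {
    stop_ck("unsupported result type for export")
  }
  if (format == "records") {
    yaml::write_yaml(lapply(records, function(r) {
      if (is.data.frame(r)) as.list(r) else r
    }), file.path(path, "results.yaml"))
    written <- c(written, file.path(path, "results.yaml"))
  }
  invisible(written)
}

#' Re-import an exported allocation
#'
#' @param file Path to an `allocation.csv` written by [export_results()].
#' @return Named list of spending [cascade_ts()] per program.
#' @export
read_allocation <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$program), function(d) {
    d <- d[order(d$year), , drop = FALSE]
    cascade_ts(d$year, d$spending, "previous")
  })
  out[unique(df$program)]
}
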