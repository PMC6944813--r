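#' Annual time series of parameter, spending or coverage values
#'
#' A minimal container for the sparse annual data that drive the model:
#' a set of (year, value) points plus an interpolation method. Databook
#' parameter values, program spending and program coverage are all stored
#' as `cascade_ts` objects.
#'
#' @param years Numeric vector of strictly increasing decimal years.
#' @param values Numeric vector of the same length as `years`.
#' @param interpolation Either `"linear"` (piecewise linear between points)
#'   or `"previous"` (step function holding the last observed value).
#'
#' @details Outside the observed year range the endpoint value is held
#'   constant, so a series with a single data point behaves as a constant:
#'   sparse data entered for one year are assumed to apply to all years.
#'
#' @return An object of class `cascade_ts`.
#' @examples
#' ts <- cascade_ts(c(2016, 2018), c(0, 10))
#' ts_interpolate(ts, 2017) # 5
#' @export
cascade_ts <- function(years, values, interpolation = c("linear", "previous")) {
  interpolation <- match.arg(interpolation)
  if (length(years) < 1L) stop_ck("a time series needs at least one point")
  if (length(years) != length(values)) {
    stop_ck("'years' and 'values' must have equal length")
  }
  if (anyNA(years) || anyNA(values)) stop_ck("time series points must not be NA")
  if (length(years) > 1L && any(diff(years) <= 0)) {
    stop_ck("time series years must be strictly increasing")
  }
  structure(
    list(years = as.numeric(years), values = as.numeric(values),
         interpolation = interpolation),
    class = "cascade_ts"
  )
}

#' @export
print.cascade_ts <- function(x, ...) {
  cat(sprintf("<cascade_ts: %d point(s), %s interpolation>\n",
              length(x$years), x$interpolation))
  print(stats::setNames(x$values, x$years))
  invisible(x)
}

is_cascade_ts <- function(x) inherits(x, "cascade_ts")

#' Interpolate a time series at one or more years
#'
#' Linear interpolation inside the data range and constant (endpoint value)
#' extrapolation outside it; `"previous"` series hold the last observed value.
#'
#' @param series A [cascade_ts()] object.
#' @param year Numeric vector of decimal years.
#' @return Numeric vector of interpolated values, one per queried year.
#' @export
ts_interpolate <- function(series, year) {
  if (!is_cascade_ts(series)) stop_ck("'series' must be a cascade_ts")
  if (length(series$years) == 0L) stop_ck("cannot interpolate an empty series")
  if (length(series$years) == 1L) {
    return(rep(series$values, length(year)))
  }
  method <- if (series$interpolation == "linear") "linear" else "constant"
  stats::approx(series$years, series$values, xout = year,
                method = method, f = 0, rule = 2)$y
}

# Shift a spending series by a constant delta from a start year onward
# (step-function change used by scenario deltas).
ts_add_delta <- function(series, delta, start_year) {
  yrs <- sort(unique(c(series$years, start_year)))
  base <- ts_interpolate(series, yrs)
  vals <- base + ifelse(yrs >= start_year - 1e-9, delta, 0)
  # keep the step sharp for linear series: insert a point just before the jump
  if (series$interpolation == "linear" && any(yrs < start_year - 1e-9)) {
    eps <- 1e-6
    pre <- start_year - eps
    if (!any(near(yrs, pre))) {
      yrs2 <- sort(c(yrs, pre))
      vals <- stats::approx(yrs, base, xout = yrs2, rule = 2)$y +
        ifelse(yrs2 >= start_year - 1e-9, delta, 0)
      yrs <- yrs2
    }
  }
  cascade_ts(yrs, vals, series$interpolation)
}

# Coerce a constant or a cascade_ts to a cascade_ts.
as_cascade_ts <- function(x, interpolation = "linear") {
  if (is_cascade_ts(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(cascade_ts(2000, x, "previous"))
  stop_ck("expected a single number or a cascade_ts")
}
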