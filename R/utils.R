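# Internal helpers shared across modules.

# Round half away from zero. Stage counts and percent improvements are
# presented this way; base round() is half-to-even.
round_half_out <- function(x) sign(x) * floor(abs(x) + 0.5)

# Identifier rule for compartment/parameter/program/stage codes: unambiguous
# inside formula text and file tables.
is_identifier <- function(x) {
  is.character(x) & !is.na(x) & grepl("^[a-z][a-z0-9_]*$", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ck <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

warn_ck <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_ck("'%s' must be a single number", name)
  }
  if (x < lower || x > upper) {
    stop_ck("'%s' = %g outside [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

# Near-equality used for grid/time arithmetic.
near <- function(a, b, tol = 1e-9) abs(a - b) <= tol * pmax(1, abs(a), abs(b))
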