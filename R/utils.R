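# Internal validation helpers. Every user-facing check routes through these so
# that failures always name the offending field.

abort_field <- function(name, msg, class = "bdscreen_validation_error") {
  rlang::abort(sprintf("`%s` %s", name, msg), class = class)
}

check_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(name, "must be a single finite number")
  }
  invisible(x)
}

check_prob <- function(x, name) {
  check_number(x, name)
  if (x < 0 || x > 1) abort_field(name, "must lie in [0, 1]")
  invisible(x)
}

check_positive <- function(x, name) {
  check_number(x, name)
  if (x <= 0) abort_field(name, "must be positive")
  invisible(x)
}

check_nonneg <- function(x, name) {
  check_number(x, name)
  if (x < 0) abort_field(name, "must be non-negative")
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  check_number(x, name)
  if (x < min || x != trunc(x)) {
    abort_field(name, sprintf("must be an integer >= %s", min))
  }
  invisible(as.integer(x))
}

# Presentation rounding: persons round half-up (15000 * 0.894^4 = 9581.67 -> 9582).
round_half_up <- function(x) floor(x + 0.5)
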