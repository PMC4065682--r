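# Internal input checks shared across modules.

stop_input <- function(msg, class = "pkbioeq_input_error") {
  rlang::abort(msg, class = class)
}

check_numeric <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_input(sprintf("`%s` must be numeric with no missing values.", name))
  }
  if (positive && any(x <= 0)) {
    stop_input(sprintf("`%s` must be strictly positive.", name))
  }
  if (nonneg && any(x < 0)) {
    stop_input(sprintf("`%s` must be nonnegative.", name))
  }
  invisible(x)
}

check_times <- function(times, name = "times", strict = TRUE) {
  check_numeric(times, name, nonneg = TRUE)
  if (strict && length(times) > 1 && any(diff(times) <= 0)) {
    stop_input(sprintf("`%s` must be strictly increasing.", name))
  }
  invisible(times)
}

check_cols <- function(data, cols, name = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop_input(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Linear interpolation of a release curve at one time; caller guarantees
# coverage of `at` by the profile's range.
interp_at <- function(times, values, at) {
  stats::approx(times, values, xout = at, method = "linear", ties = "ordered")$y
}
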