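#' @keywords internal
"_PACKAGE"

# Internal input checkers. All user-facing errors name the offending field so
# that failures in a pipeline point at the measurement, not the call site.

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid input `%s`: %s", field, msg), call. = FALSE)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop_invalid(field, "must be numeric and >= 0")
  }
  invisible(x)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop_invalid(field, "must be numeric and > 0")
  }
  invisible(x)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_invalid(field, "must lie in [0, 1]")
  }
  invisible(x)
}

#' Average a measurement over consecutive cardiac cycles
#'
#' Doppler-derived quantities are averaged over several consecutive cardiac
#' cycles before use (3-5 cycles for caval diameters, 5-10 for the caval
#' velocity-time integral, 3 for the aortic velocity-time integral). This
#' helper performs that arithmetic mean so that an echo exam record stores a
#' single already-averaged value per measurement.
#'
#' @param values numeric vector of per-cycle measurements, all non-negative.
#' @return the arithmetic mean of `values`.
#' @examples
#' cycle_mean(c(0.34, 0.36, 0.35))
#' @export
cycle_mean <- function(values) {
  check_nonneg(values, "values")
  if (length(values) == 0L) stop_invalid("values", "must be non-empty")
  mean(values)
}
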