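# Shared condition classes and small numeric helpers.

stop_dermakin <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "dermakin_error")))
}

#' @noRd
format_error <- function(msg) stop_dermakin(msg, "dermakin_format_error")
#' @noRd
validation_error <- function(msg) stop_dermakin(msg, "dermakin_validation_error")
#' @noRd
domain_error <- function(msg) stop_dermakin(msg, "dermakin_domain_error")
#' @noRd
numeric_error <- function(msg) stop_dermakin(msg, "dermakin_numeric_error")
#' @noRd
estimation_error <- function(msg) stop_dermakin(msg, "dermakin_estimation_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trapezoidal quadrature of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Cumulative trapezoid, same length as x, starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# Evaluate a function with a temporary RNG seed, restoring global state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Minutes are the I/O time unit; the PDE works in hours. All conversions
# go through these two helpers so the factor lives in exactly one place.
minutes_to_hours <- function(t_min) t_min / 60
hours_to_minutes <- function(t_h) t_h * 60
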