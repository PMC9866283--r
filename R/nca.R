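# Non-compartmental PK summaries. Time unit is minutes throughout (the
# sampling-grid unit); lambda_z is 1/min and AUCs are ng*min/mL.

#' Maximum concentration and its time
#'
#' @param series a [timeseries_table].
#' @return list with `cmax` and `tmax` (earliest sample time on ties).
#' @export
cmax_tmax <- function(series) {
  stopifnot(inherits(series, "timeseries_table"))
  if (nrow(series) == 0L) validation_error("empty series")
  i <- which.max(series$value)  # which.max returns the first maximum
  list(cmax = series$value[i], tmax = series$time[i])
}

#' Terminal half-life by log-linear regression
#'
#' Ordinary least squares of log concentration on time over the last
#' `n_points` samples; `lambda_z` is minus the slope and
#' `t_half = ln(2)/lambda_z`. The terminal window must lie after Tmax and
#' contain strictly positive concentrations, and the fitted slope must be
#' negative.
#'
#' @param series a [timeseries_table].
#' @param n_points number of terminal samples, default 3.
#' @return list with `lambda_z` (1/min), `t_half` (min), `r_squared`,
#'   `n_points`.
#' @export
#' @examples
#' ts <- timeseries_table(seq(300, 660, 60), 100 * exp(-0.01 * seq(300, 660, 60)))
#' terminal_halflife(ts)$t_half  # ~69.31
terminal_halflife <- function(series, n_points = 3L) {
  stopifnot(inherits(series, "timeseries_table"))
  n_points <- as.integer(n_points)
  if (n_points < 2L) validation_error("n_points must be >= 2")
  n <- nrow(series)
  if (n < n_points)
    estimation_error(sprintf("series has %d points; %d needed", n, n_points))
  idx <- seq.int(n - n_points + 1L, n)
  tmax <- cmax_tmax(series)$tmax
  if (series$time[idx[1]] <= tmax)
    estimation_error("terminal window must start after Tmax")
  y <- series$value[idx]
  if (any(y <= 0))
    estimation_error("terminal concentrations must be strictly positive")
  t <- series$time[idx]
  fit <- stats::lm.fit(cbind(1, t), log(y))
  slope <- unname(fit$coefficients[2])
  lambda <- -slope
  # require a resolvable decay over the window, not just a sign bit
  if (!is.finite(lambda) || lambda * diff(range(t)) < 1e-10)
    estimation_error(sprintf(
      "terminal slope is non-negative or flat (lambda_z = %g); no elimination phase",
      lambda))
  ss_tot <- sum((log(y) - mean(log(y)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  list(lambda_z = lambda, t_half = log(2) / lambda, r_squared = r2,
       n_points = n_points)
}

#' Area under the concentration-time curve
#'
#' Linear trapezoid over the observed span; with `extrapolate = TRUE` the
#' exponential tail `C_last / lambda_z` is added, using
#' [terminal_halflife()] on the last `n_points` samples.
#'
#' @param series a [timeseries_table] with >= 2 points.
#' @param extrapolate add the terminal extrapolation to infinity?
#' @param n_points terminal window for `lambda_z`, default 3.
#' @return list with `auc_0_t` and (if extrapolated) `auc_0_inf` (both
#'   ng*min/mL) plus `lambda_z`.
#' @export
#' @examples
#' auc(timeseries_table(c(0, 60), c(0, 10)))$auc_0_t  # 300
auc <- function(series, extrapolate = FALSE, n_points = 3L) {
  stopifnot(inherits(series, "timeseries_table"))
  if (nrow(series) < 2L) validation_error("AUC needs >= 2 points")
  a0t <- trapz(series$time, series$value)
  out <- list(auc_0_t = a0t)
  if (extrapolate) {
    th <- terminal_halflife(series, n_points)  # estimation_error on failure
    out$auc_0_inf <- a0t + series$value[nrow(series)] / th$lambda_z
    out$lambda_z <- th$lambda_z
  }
  out
}

#' Full non-compartmental summary
#'
#' Cmax, Tmax, terminal half-life and AUCs for a corrected tissue or blood
#' concentration series.
#'
#' @param series a [timeseries_table].
#' @param n_terminal terminal window for the log-linear fit, default 3.
#' @param extrapolate include `auc_0_inf`, default TRUE.
#' @return One-row data.frame (`pk_summary`): `cmax` (ng/mL), `tmax` (min),
#'   `lambda_z` (1/min), `t_half` (min), `auc_0_t`, `auc_0_inf`
#'   (ng*min/mL), `n_terminal_points`.
#' @export
pk_summary <- function(series, n_terminal = 3L, extrapolate = TRUE) {
  ct <- cmax_tmax(series)
  th <- terminal_halflife(series, n_terminal)
  a <- auc(series, extrapolate = extrapolate, n_points = n_terminal)
  out <- data.frame(cmax = ct$cmax, tmax = ct$tmax, lambda_z = th$lambda_z,
                    t_half = th$t_half, auc_0_t = a$auc_0_t,
                    auc_0_inf = if (extrapolate) a$auc_0_inf else NA_real_,
                    n_terminal_points = th$n_points)
  class(out) <- c("pk_summary", "data.frame")
  out
}
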