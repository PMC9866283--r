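#' Franz-cell permeation record
#'
#' Receptor-compartment sampling series plus the cell geometry needed for
#' the replacement-volume correction. Defaults match a standard 5 mL cell
#' sampled 1 mL at a time through a 0.785 cm^2 diffusion window.
#'
#' @param times sample times in hours, strictly increasing.
#' @param concentrations receptor concentrations (ng/mL) at each sample.
#' @param Vn receptor (receiving tank) volume, mL; must exceed `Vi`.
#' @param Vi sample volume withdrawn (and replaced) at each time, mL, > 0.
#' @param A diffusion area, cm^2, > 0.
#' @param donor_load formulation mass loaded in the donor cell (g), metadata.
#' @return A `permeation_record` list.
#' @export
permeation_record <- function(times, concentrations, Vn = 5, Vi = 1,
                              A = 0.785, donor_load = NA_real_) {
  times <- as.numeric(times); concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations) || length(times) == 0L)
    validation_error("times and concentrations must be non-empty and matched")
  if (any(diff(times) <= 0))
    validation_error("sample times must be strictly increasing")
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    validation_error("receptor concentrations must be finite and >= 0")
  if (!is.finite(Vn) || !is.finite(Vi) || Vi <= 0 || Vn <= Vi)
    validation_error(sprintf("need Vn > Vi > 0 (got Vn = %g, Vi = %g)", Vn, Vi))
  if (!is.finite(A) || A <= 0)
    validation_error(sprintf("diffusion area A must be > 0 (got %g)", A))
  rec <- list(times = times, concentrations = concentrations, Vn = Vn,
              Vi = Vi, A = A, donor_load = donor_load)
  class(rec) <- "permeation_record"
  rec
}

#' Cumulative permeated amount per area
#'
#' `Qn = (Cn*Vn + sum_{i<n} Ci*Vi) / A`: the receptor concentration at each
#' sample scaled to the full receptor volume, plus the drug removed in all
#' strictly earlier samples, per diffusion area.
#'
#' @param rec a [permeation_record()].
#' @return data.frame with columns `time` (h) and `Qn` (ng/cm^2).
#' @export
#' @examples
#' rec <- permeation_record(c(1, 2), c(10, 20))
#' cumulative_amount(rec)$Qn  # 63.69, 140.13
cumulative_amount <- function(rec) {
  stopifnot(inherits(rec, "permeation_record"))
  Cn <- rec$concentrations
  removed <- c(0, cumsum(Cn * rec$Vi)[-length(Cn)])
  data.frame(time = rec$times, Qn = (Cn * rec$Vn + removed) / rec$A)
}

#' Steady-state flux by linear regression
#'
#' Ordinary least squares of cumulative amount on time over a window. The
#' slope is the steady-state flux Js (ng cm^-2 h^-1); the time-axis
#' intercept gives the lag time. `window = "auto"` picks, among trailing
#' windows of at least `min_points` samples, the one maximising r^2 (ties
#' broken towards the longest window) - a standard way to exclude the
#' lag-phase curvature from the fit.
#'
#' @param qn data.frame with columns `time` and `Qn` (from
#'   [cumulative_amount()]), or a [permeation_record()].
#' @param window `"auto"`, or an integer vector of row indices to fit.
#' @param min_points minimum window size, default 4 (and never below 3).
#' @return A `flux_fit` list: `Js`, `intercept`, `lag_time` (h; NA when
#'   `Js <= 0`), `r_squared`, `window` (indices used), `n`.
#' @export
steady_state_flux <- function(qn, window = "auto", min_points = 4L) {
  if (inherits(qn, "permeation_record")) qn <- cumulative_amount(qn)
  stopifnot(is.data.frame(qn), all(c("time", "Qn") %in% names(qn)))
  n <- nrow(qn)
  min_points <- max(3L, as.integer(min_points))
  fit_window <- function(idx) {
    t <- qn$time[idx]; y <- qn$Qn[idx]
    fit <- stats::lm.fit(cbind(1, t), y)
    res <- fit$residuals
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot == 0) { if (sum(res^2) < 1e-20) 1 else 0 }
          else 1 - sum(res^2) / ss_tot
    list(intercept = fit$coefficients[1], slope = fit$coefficients[2], r2 = r2)
  }
  if (identical(window, "auto")) {
    if (n < min_points)
      validation_error(sprintf("need >= %d points for the auto window (have %d)",
                               min_points, n))
    starts <- seq_len(n - min_points + 1L)
    fits <- lapply(starts, function(s) fit_window(s:n))
    r2s <- vapply(fits, `[[`, numeric(1), "r2")
    best <- which(r2s >= max(r2s) - 1e-12)[1]  # earliest start = longest window
    idx <- starts[best]:n
    f <- fits[[best]]
  } else {
    idx <- as.integer(window)
    if (length(idx) < 3L || any(idx < 1L) || any(idx > n))
      validation_error("explicit window must give >= 3 valid row indices")
    f <- fit_window(idx)
  }
  Js <- unname(f$slope); b <- unname(f$intercept)
  out <- list(Js = Js, intercept = b,
              lag_time = if (is.finite(Js) && Js > 0) -b / Js else NA_real_,
              r_squared = f$r2, window = range(idx), n = length(idx))
  class(out) <- "flux_fit"
  out
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("<flux_fit> Js = %.6g ng cm^-2 h^-1, lag = %s h, r^2 = %.4f (rows %d..%d)\n",
              x$Js, format(x$lag_time, digits = 4), x$r_squared,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Apparent diffusivity from steady-state flux
#'
#' Fick's first law, `D = -Js / (dC/dx)`. Unless an explicit concentration
#' gradient is supplied, the steady-state linear profile across the barrier
#' is assumed, `dC/dx = -c0 / L`, giving `D = Js * L / c0` - the standard
#' Franz-cell treatment under sink conditions.
#'
#' @param Js steady-state flux (ng cm^-2 h^-1).
#' @param c0 donor-side drug concentration (ng/cm^3), > 0.
#' @param L barrier thickness (cm), > 0.
#' @param gradient optional explicit dC/dx (ng/cm^4, negative for transport
#'   in +x); overrides the linear-profile approximation.
#' @return Apparent diffusivity D (cm^2/h).
#' @export
#' @examples
#' diffusivity_from_flux(1, 1000, 0.04)  # 4e-5
diffusivity_from_flux <- function(Js, c0, L, gradient = NULL) {
  if (!is.null(gradient)) {
    if (!is.finite(gradient) || gradient == 0)
      domain_error("explicit gradient must be finite and non-zero")
    return(-Js / gradient)
  }
  if (!is.finite(c0) || c0 <= 0) domain_error("c0 must be > 0")
  if (!is.finite(L) || L <= 0) domain_error("L must be > 0")
  Js * L / c0
}
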