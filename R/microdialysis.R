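#' Probe recovery, gain method
#'
#' Recovery (%) of a microdialysis probe sampled from a spiked medium:
#' `100 * c_out / c_in`, where `c_in` is the drug level of the medium the
#' probe window is immersed in and `c_out` the dialysate concentration.
#'
#' @param c_in nominal medium concentration (ng/mL), > 0. Vectorised.
#' @param c_out dialysate concentration (ng/mL), >= 0.
#' @return Recovery in percent.
#' @export
#' @examples
#' gain_recovery(100, 61.4)  # 61.4
gain_recovery <- function(c_in, c_out) {
  if (any(!is.finite(c_in)) || any(c_in <= 0))
    domain_error("gain_recovery: c_in must be > 0")
  if (any(!is.finite(c_out)) || any(c_out < 0))
    domain_error("gain_recovery: c_out must be >= 0")
  100 * c_out / c_in
}

#' Probe recovery, loss (retrodialysis) method
#'
#' Recovery (%) from the loss of drug out of a spiked perfusate:
#' `100 * (c_in - c_out) / c_in`. Measurement noise can push `c_out` above
#' `c_in`; such values are clipped to 0% recovery with a warning rather
#' than rejected.
#'
#' @param c_in perfusate concentration (ng/mL), > 0. Vectorised.
#' @param c_out dialysate concentration (ng/mL), >= 0.
#' @return Recovery in percent.
#' @export
#' @examples
#' loss_recovery(100, 40)  # 60
loss_recovery <- function(c_in, c_out) {
  if (any(!is.finite(c_in)) || any(c_in <= 0))
    domain_error("loss_recovery: c_in must be > 0")
  if (any(!is.finite(c_out)) || any(c_out < 0))
    domain_error("loss_recovery: c_out must be >= 0")
  r <- 100 * (c_in - c_out) / c_in
  if (any(r < 0)) {
    warning("loss_recovery: c_out exceeds c_in for ",
            sum(r < 0), " measurement(s); recovery clipped to 0%",
            call. = FALSE)
    r <- pmax(r, 0)
  }
  r
}

#' Relative recovery across a concentration gradient
#'
#' `(c_d - c_p) / (c_m - c_p)`: the fraction of the tissue-perfusate
#' gradient that the probe captures. With drug-free perfusate (`c_p = 0`)
#' this reduces to the gain-method recovery; with drug-free tissue
#' (`c_m = 0`) it reduces to the loss-method recovery (the probe's
#' *delivery*, the quantity retrodialysis relies on being equal to the
#' recovery).
#'
#' @param c_d dialysate concentration (ng/mL).
#' @param c_p perfusate concentration (ng/mL).
#' @param c_m tissue (medium) concentration (ng/mL).
#' @return Recovery as a fraction.
#' @export
#' @examples
#' relative_recovery(50, 0, 100)  # 0.5
relative_recovery <- function(c_d, c_p, c_m) {
  if (any(!is.finite(c(c_d, c_p, c_m))))
    domain_error("relative_recovery: inputs must be finite")
  if (any(c_m == c_p))
    domain_error("relative_recovery: undefined when c_m = c_p (no gradient)")
  (c_d - c_p) / (c_m - c_p)
}

#' Probe calibration data set
#'
#' Replicated recovery measurements organised by probe kind, method and
#' nominal concentration level.
#'
#' @param measurements data.frame with columns `probe_kind`
#'   (`"linear"`/`"concentric"`), `method` (`"gain"`/`"loss"`), `c_in`
#'   (ng/mL, > 0), `c_out` (ng/mL, >= 0) and `replicate` (integer id).
#' @return A `probe_calibration` object (the validated data.frame with a
#'   computed `recovery` column in percent).
#' @export
probe_calibration <- function(measurements) {
  req <- c("probe_kind", "method", "c_in", "c_out", "replicate")
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    validation_error(paste("calibration is missing column(s):",
                           paste(miss, collapse = ", ")))
  if (nrow(measurements) == 0L)
    validation_error("calibration has no measurements")
  m <- measurements[req]
  bad <- setdiff(unique(m$method), c("gain", "loss"))
  if (length(bad))
    validation_error(paste("unknown method(s):", paste(bad, collapse = ", ")))
  if (any(!is.finite(m$c_in)) || any(m$c_in <= 0))
    validation_error("c_in must be > 0 for every measurement")
  if (any(!is.finite(m$c_out)) || any(m$c_out < 0))
    validation_error("c_out must be >= 0 for every measurement")
  m$recovery <- NA_real_
  g <- m$method == "gain"
  if (any(g)) m$recovery[g] <- gain_recovery(m$c_in[g], m$c_out[g])
  if (any(!g)) m$recovery[!g] <- loss_recovery(m$c_in[!g], m$c_out[!g])
  class(m) <- c("probe_calibration", "data.frame")
  m
}

#' Read a calibration CSV
#'
#' Columns: `probe_kind`, `method`, `c_in`, `c_out`, `replicate`.
#'
#' @param path file path.
#' @param delimiter field delimiter, default comma.
#' @return A [probe_calibration()].
#' @export
read_calibration <- function(path, delimiter = ",") {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  probe_calibration(utils::read.table(path, header = TRUE, sep = delimiter,
                                      stringsAsFactors = FALSE))
}

#' Summarise a probe calibration
#'
#' Mean and sample SD (n-1 denominator) of recovery per (probe kind,
#' method, concentration level), plus a pooled recovery per (probe kind,
#' method): the unweighted mean of the level means. The unweighted pooling
#' matches the arithmetic used when levels carry unequal replicate sets.
#'
#' @param cal a [probe_calibration()].
#' @return list with data.frames `levels` (`probe_kind`, `method`, `c_in`,
#'   `n`, `mean`, `sd`) and `pooled` (`probe_kind`, `method`, `n_levels`,
#'   `mean`, `sd_of_level_means`).
#' @export
summarize_calibration <- function(cal) {
  if (!inherits(cal, "probe_calibration")) cal <- probe_calibration(cal)
  key <- interaction(cal$probe_kind, cal$method, cal$c_in, drop = TRUE)
  sp <- split(cal, key)
  levels_df <- do.call(rbind, lapply(sp, function(d) data.frame(
    probe_kind = d$probe_kind[1], method = d$method[1], c_in = d$c_in[1],
    n = nrow(d), mean = mean(d$recovery),
    sd = if (nrow(d) >= 2L) stats::sd(d$recovery) else NA_real_)))
  levels_df <- levels_df[order(levels_df$probe_kind, levels_df$method,
                               levels_df$c_in), ]
  rownames(levels_df) <- NULL
  key2 <- interaction(levels_df$probe_kind, levels_df$method, drop = TRUE)
  sp2 <- split(levels_df, key2)
  pooled <- do.call(rbind, lapply(sp2, function(d) data.frame(
    probe_kind = d$probe_kind[1], method = d$method[1],
    n_levels = nrow(d), mean = mean(d$mean),
    sd_of_level_means = if (nrow(d) >= 2L) stats::sd(d$mean) else NA_real_)))
  rownames(pooled) <- NULL
  list(levels = levels_df, pooled = pooled)
}

#' Gain/loss method equivalence test
#'
#' Retrodialysis correction is only valid if the probe's recovery (gain
#' method) equals its delivery (loss method). For each concentration level
#' with both methods present, a two-sided Welch two-sample t-test compares
#' the replicate recoveries; the probe passes overall iff every level
#' passes at `alpha`.
#'
#' @param cal a [probe_calibration()]; each matched level needs >= 2
#'   replicates per method.
#' @param alpha significance level, default 0.05.
#' @return list with `table` (per-level statistic, df, p-value, pass) and
#'   `overall_pass`.
#' @export
gain_loss_equivalence <- function(cal, alpha = 0.05) {
  if (!inherits(cal, "probe_calibration")) cal <- probe_calibration(cal)
  rows <- list()
  for (pk in unique(cal$probe_kind)) {
    sub <- cal[cal$probe_kind == pk, ]
    lv_g <- unique(sub$c_in[sub$method == "gain"])
    lv_l <- unique(sub$c_in[sub$method == "loss"])
    missing_pairs <- c(setdiff(lv_g, lv_l), setdiff(lv_l, lv_g))
    if (length(missing_pairs))
      validation_error(sprintf(
        "probe '%s': concentration level(s) %s present for one method only",
        pk, paste(sort(missing_pairs), collapse = ", ")))
    for (lv in sort(intersect(lv_g, lv_l))) {
      g <- sub$recovery[sub$method == "gain" & sub$c_in == lv]
      l <- sub$recovery[sub$method == "loss" & sub$c_in == lv]
      if (length(g) < 2L || length(l) < 2L)
        validation_error(sprintf(
          "probe '%s', level %g: need >= 2 replicates per method", pk, lv))
      if (stats::sd(g) == 0 && stats::sd(l) == 0) {
        # degenerate replicate sets: decided by exact mean comparison
        eq <- isTRUE(all.equal(mean(g), mean(l)))
        stat <- if (eq) 0 else Inf
        p <- if (eq) 1 else 0
        df <- NA_real_
      } else {
        tt <- stats::t.test(g, l, var.equal = FALSE)
        stat <- unname(tt$statistic); df <- unname(tt$parameter)
        p <- tt$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        probe_kind = pk, c_in = lv, n_gain = length(g), n_loss = length(l),
        mean_gain = mean(g), mean_loss = mean(l), statistic = stat,
        df = df, p_value = p, pass = p > alpha)
    }
  }
  if (!length(rows))
    validation_error("no concentration level has both gain and loss data")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, alpha = alpha, overall_pass = all(tab$pass))
}

#' Correct a dialysate series to tissue concentrations
#'
#' Divides every dialysate concentration by the in vivo probe recovery
#' (`C_tissue = C_dialysate / R`), the standard microdialysis correction.
#'
#' @param dialysate a [timeseries_table] of dialysate concentrations.
#' @param recovery in vivo recovery as a fraction in (0, 1].
#' @return A [timeseries_table] of tissue concentrations; the recovery used
#'   is recorded in the metadata.
#' @export
#' @examples
#' ts <- timeseries_table(30, 103.2)
#' correct_series(ts, 0.516)$value  # 200
correct_series <- function(dialysate, recovery) {
  stopifnot(inherits(dialysate, "timeseries_table"))
  if (!is.numeric(recovery) || length(recovery) != 1L || !is.finite(recovery) ||
      recovery <= 0 || recovery > 1)
    domain_error(sprintf("recovery must be a fraction in (0, 1] (got %g)",
                         recovery))
  meta <- attr(dialysate, "meta") %||% list()
  meta$recovery_used <- recovery
  timeseries_table(dialysate$time, dialysate$value / recovery,
                   site = attr(dialysate, "site") %||% "", meta = meta)
}
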