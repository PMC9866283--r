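#' Sampled concentration time series
#'
#' The common container for dialysate, tissue and receptor concentration
#' series: sample times in minutes (strictly increasing) paired with
#' non-negative concentrations. The concentration unit (default ng/mL) is
#' carried as metadata and never converted silently.
#'
#' @param time numeric vector of sample times in minutes, strictly
#'   increasing, non-negative.
#' @param value numeric vector of concentrations (same length), finite and
#'   non-negative.
#' @param site free-text site label (e.g. `"skin"`, `"blood"`).
#' @param meta named list of annotations (units, probe recovery used, seed).
#'
#' @return A `timeseries_table`, a `data.frame` with columns `time` and
#'   `value` plus `site` and `meta` attributes.
#' @export
#' @examples
#' ts <- timeseries_table(c(30, 60), c(10, 20), site = "skin")
timeseries_table <- function(time, value, site = "", meta = list()) {
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value))
    validation_error("time and value must have the same length")
  if (length(time) == 0L)
    validation_error("a time series needs at least one row")
  out <- data.frame(time = time, value = value)
  attr(out, "site") <- as.character(site)
  attr(out, "meta") <- meta
  class(out) <- c("timeseries_table", "data.frame")
  validate_timeseries(out)
}

validate_timeseries <- function(ts) {
  time <- ts$time
  value <- ts$value
  if (any(!is.finite(time)) || any(time < 0))
    validation_error("times must be finite and non-negative")
  bad <- which(diff(time) <= 0)
  if (length(bad))
    validation_error(sprintf(
      "times must be strictly increasing; violated at row %d (t = %g after t = %g)",
      bad[1] + 1L, time[bad[1] + 1L], time[bad[1]]))
  if (any(!is.finite(value)))
    validation_error("concentrations must all be finite")
  if (any(value < 0))
    validation_error(sprintf("concentrations must be non-negative; row %d is %g",
                             which(value < 0)[1], value[value < 0][1]))
  ts
}

#' @export
print.timeseries_table <- function(x, ...) {
  site <- attr(x, "site")
  cat(sprintf("<timeseries_table> %d samples%s, t = %g..%g min\n",
              nrow(x), if (nzchar(site)) paste0(" at '", site, "'") else "",
              min(x$time), max(x$time)))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

.time_col_candidates <- c("time", "t", "time_min", "t_min", "minutes")
.value_col_candidates <- c("concentration", "conc", "value", "c", "c_out")

#' Read a concentration time series from delimited text
#'
#' Expects a header row naming a time column (minutes) and a concentration
#' column; recognised names are `time`/`t`/`time_min`/`t_min`/`minutes` and
#' `concentration`/`conc`/`value`/`c`, case-insensitively, unless overridden.
#'
#' @param path file path.
#' @param delimiter field delimiter, default comma.
#' @param time_col,value_col explicit column names (override auto-detection).
#' @param site site label stored on the result (default: value of a `site`
#'   column if present, else "").
#' @return A [timeseries_table].
#' @export
read_timeseries <- function(path, delimiter = ",", time_col = NULL,
                            value_col = NULL, site = NULL) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delimiter,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) format_error(sprintf("cannot parse '%s': %s",
                                             path, conditionMessage(e))))
  if (nrow(df) == 0L || ncol(df) == 0L)
    format_error(sprintf("'%s' contains no data rows", path))
  nm <- tolower(names(df))
  pick <- function(given, candidates, what) {
    if (!is.null(given)) {
      i <- match(tolower(given), nm)
      if (is.na(i)) format_error(sprintf("column '%s' not found in %s", given, path))
      return(i)
    }
    i <- which(nm %in% candidates)
    if (!length(i)) format_error(sprintf(
      "no %s column in '%s' (looked for: %s)", what, path,
      paste(candidates, collapse = ", ")))
    i[1]
  }
  it <- pick(time_col, .time_col_candidates, "time")
  iv <- pick(value_col, .value_col_candidates, "concentration")
  if (is.null(site))
    site <- if ("site" %in% nm) as.character(df[[which(nm == "site")[1]]][1]) else ""
  timeseries_table(df[[it]], df[[iv]], site = site,
                   meta = list(source = path, unit = "ng/mL"))
}

#' Write a time series as delimited text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces them exactly.
#'
#' @param ts a [timeseries_table].
#' @param path output file path.
#' @param delimiter field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, delimiter = ",") {
  stopifnot(inherits(ts, "timeseries_table"))
  out <- data.frame(time = sprintf("%.17g", ts$time),
                    concentration = sprintf("%.17g", ts$value),
                    site = rep(attr(ts, "site") %||% "", nrow(ts)))
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
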