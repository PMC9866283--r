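#' Two-layer diffusion model specification
#'
#' All parameters of the matrix-skin diffusion model. The delivery matrix
#' occupies \eqn{-L_m \le x \le 0}, the skin \eqn{0 \le x \le L_s}. Drug
#' diffuses in each layer with constant diffusivity (`Dm`, `Ds`); the donor
#' surface at \eqn{x=-L_m} is zero-flux; the matrix-skin interface carries a
#' partition (isolation) jump \eqn{C_s(0,t) = k_m C_m(0,t)} together with
#' flux continuity; the skin base at \eqn{x=L_s} loses drug to the capillary
#' bed through a Robin condition \eqn{-D_s \partial C_s/\partial x = k_{cl}
#' C_s}. Initial concentrations are uniform per layer.
#'
#' Lengths are cm, times hours, diffusivities cm^2/h, `kcl` cm/h.
#' Concentrations are unit-agnostic (the equations are linear); the default
#' `Cm0 = 0.2` is in g/cm^3.
#'
#' @param Lm,Ls layer thicknesses (cm); default 0.04 each.
#' @param Dm,Ds diffusivities (cm^2/h); defaults are the nanoemulsion-based
#'   gel values 7.42e-6 and 10.60e-6.
#' @param km dimensionless interface partition coefficient (> 0), default 0.5.
#' @param kcl capillary clearance coefficient (cm/h, >= 0), default 25.
#' @param Cm0,Cs0 uniform initial concentrations in matrix and skin;
#'   defaults 0.2 and 0.
#' @param nx_m,nx_s grid intervals per layer, default 200 each.
#' @param dt time step (h), default 0.001.
#' @param t_end simulated horizon (h), default 10.
#' @param out_every output cadence (h) for the stored field, default 0.05.
#' @param width transverse width of the patch (cm), metadata only (the model
#'   is one-dimensional in x), default 0.04.
#'
#' @return A `diffusion_spec` list.
#' @seealso [simulate_diffusion()], [read_model_config()]
#' @export
diffusion_spec <- function(Lm = 0.04, Ls = 0.04, Dm = 7.42e-6, Ds = 10.60e-6,
                           km = 0.5, kcl = 25, Cm0 = 0.2, Cs0 = 0,
                           nx_m = 200L, nx_s = 200L, dt = 0.001, t_end = 10,
                           out_every = 0.05, width = 0.04) {
  spec <- list(Lm = Lm, Ls = Ls, Dm = Dm, Ds = Ds, km = km, kcl = kcl,
               Cm0 = Cm0, Cs0 = Cs0, nx_m = as.integer(nx_m),
               nx_s = as.integer(nx_s), dt = dt, t_end = t_end,
               out_every = out_every, width = width)
  class(spec) <- "diffusion_spec"
  validate_diffusion_spec(spec)
}

validate_diffusion_spec <- function(spec) {
  num1 <- function(name) {
    v <- spec[[name]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      validation_error(sprintf("'%s' must be a single finite number", name))
    v
  }
  for (f in c("Lm", "Ls", "Dm", "Ds", "dt", "t_end", "out_every"))
    if (num1(f) <= 0) validation_error(sprintf("'%s' must be > 0 (got %g)", f, spec[[f]]))
  if (num1("km") <= 0) validation_error(sprintf("'km' must be > 0 (got %g)", spec$km))
  if (num1("kcl") < 0) validation_error(sprintf("'kcl' must be >= 0 (got %g)", spec$kcl))
  for (f in c("Cm0", "Cs0"))
    if (num1(f) < 0) validation_error(sprintf("'%s' must be >= 0 (got %g)", f, spec[[f]]))
  for (f in c("nx_m", "nx_s"))
    if (!is.finite(spec[[f]]) || spec[[f]] < 2L)
      validation_error(sprintf("'%s' must be an integer >= 2", f))
  spec
}

#' @export
print.diffusion_spec <- function(x, ...) {
  cat("<diffusion_spec> two-layer matrix/skin diffusion model\n")
  cat(sprintf("  matrix: Lm = %g cm, Dm = %g cm^2/h, Cm0 = %g\n", x$Lm, x$Dm, x$Cm0))
  cat(sprintf("  skin:   Ls = %g cm, Ds = %g cm^2/h, Cs0 = %g\n", x$Ls, x$Ds, x$Cs0))
  cat(sprintf("  interface km = %g, clearance kcl = %g cm/h\n", x$km, x$kcl))
  cat(sprintf("  grid %d + %d nodes, dt = %g h, t_end = %g h (output every %g h)\n",
              x$nx_m + 1L, x$nx_s + 1L, x$dt, x$t_end, x$out_every))
  invisible(x)
}

# --- configuration file ------------------------------------------------------

# Flat TOML-style `key = value` lines; '#' comments; quoted or bare scalars.
parse_flat_config <- function(path) {
  if (!file.exists(path)) format_error(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      format_error(sprintf("config line is not 'key = value': '%s'", ln))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (grepl('^".*"$', val) || grepl("^'.*'$", val)) {
      val <- substr(val, 2L, nchar(val) - 1L)
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
    }
    out[[key]] <- val
  }
  out
}

#' Read a diffusion model specification from a config file
#'
#' The file is flat TOML-style `key = value` text (`#` comments allowed);
#' recognised keys are the arguments of [diffusion_spec()]. Unset keys take
#' the documented defaults; unknown keys raise a format error so typos never
#' pass silently. Lengths are cm, times hours.
#'
#' @param path config file path.
#' @return A validated [diffusion_spec()].
#' @export
#' @examples
#' cfg <- tempfile(fileext = ".toml")
#' writeLines(c("Lm = 0.04", "km = 0.5", "kcl = 25", "Cm0 = 0.2"), cfg)
#' read_model_config(cfg)
read_model_config <- function(path) {
  kv <- parse_flat_config(path)
  known <- names(formals(diffusion_spec))
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    format_error(sprintf("unknown config key(s): %s (known: %s)",
                         paste(unknown, collapse = ", "),
                         paste(known, collapse = ", ")))
  do.call(diffusion_spec, kv)
}

#' Write a diffusion model specification as a config file
#'
#' @param spec a [diffusion_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(spec, path) {
  stopifnot(inherits(spec, "diffusion_spec"))
  writeLines(sprintf("%s = %.17g", names(unclass(spec)),
                     as.numeric(unlist(spec))), path)
  invisible(path)
}
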