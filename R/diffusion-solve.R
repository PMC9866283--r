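# Two-layer Fickian diffusion solver.
#
# Unknown vector w stacks the matrix nodes u_0..u_{nm} (u_{nm} is the
# matrix-side interface value) and the skin interior nodes v_1..v_{ns}; the
# skin-side interface value is km * u_{nm} (partition condition imposed
# exactly). Space is discretised in flux (finite-volume) form on uniform
# per-layer grids, so row sums of the operator vanish except for the Robin
# clearance term and discrete mass is conserved exactly. Time stepping is
# Crank-Nicolson with two backward-Euler startup steps to damp the
# discontinuous initial profile; the first step's right-hand side uses the
# exact piecewise initial cell masses so no mass is created by projecting
# the initial discontinuity onto the dual-valued interface node.

build_diffusion_operator <- function(spec) {
  nm <- spec$nx_m; ns <- spec$nx_s
  dxm <- spec$Lm / nm; dxs <- spec$Ls / ns
  N <- nm + 1L + ns
  am <- spec$Dm / dxm; as_ <- spec$Ds / dxs
  A <- matrix(0, N, N)
  # donor surface, zero flux
  A[1, 1] <- -am; A[1, 2] <- am
  # matrix interior
  for (i in seq_len(nm - 1L) + 1L) {
    A[i, i - 1L] <- am; A[i, i] <- -2 * am; A[i, i + 1L] <- am
  }
  # interface control volume (spans dxm/2 of matrix and dxs/2 of skin)
  I <- nm + 1L
  A[I, I - 1L] <- am
  A[I, I] <- -am - spec$km * as_
  A[I, I + 1L] <- as_
  # skin interior; v_0 = km * u_I enters the first row
  if (ns >= 2L) {
    A[I + 1L, I] <- spec$km * as_
    A[I + 1L, I + 1L] <- -2 * as_
    if (ns > 2L) {
      A[I + 1L, I + 2L] <- as_
      for (j in seq_len(ns - 2L) + 1L) {
        r <- I + j
        A[r, r - 1L] <- as_; A[r, r] <- -2 * as_; A[r, r + 1L] <- as_
      }
    } else {
      A[I + 1L, I + 2L] <- as_
    }
  }
  # skin base, Robin clearance
  L <- N
  A[L, L - 1L] <- if (ns == 1L) spec$km * as_ else as_
  A[L, L] <- -as_ - spec$kcl
  # cell widths (mass matrix diagonal)
  mvec <- c(dxm / 2, rep(dxm, nm - 1L), (dxm + spec$km * dxs) / 2,
            rep(dxs, ns - 1L), dxs / 2)
  list(A = A, mvec = mvec, N = N, I = I, dxm = dxm, dxs = dxs)
}

#' Solve the two-layer matrix-skin diffusion model
#'
#' Crank-Nicolson solution of the coupled diffusion equations
#' \eqn{\partial C_m/\partial t = D_m \partial^2 C_m/\partial x^2} on
#' \eqn{[-L_m, 0]} and \eqn{\partial C_s/\partial t = D_s \partial^2
#' C_s/\partial x^2} on \eqn{[0, L_s]}, with zero flux at the donor
#' surface, flux continuity plus the partition jump \eqn{C_s = k_m C_m} at
#' the interface, and the capillary Robin sink \eqn{-D_s \partial
#' C_s/\partial x = k_{cl} C_s} at the skin base.
#'
#' @param spec a [diffusion_spec()].
#' @return A `concentration_field`: list with `x` (cm; the interface x = 0
#'   appears twice, once per layer side), `t` (hours, including 0), matrix
#'   `C` of concentrations (space x time), `layer` labels
#'   ("matrix"/"skin") and the `spec` used.
#' @export
#' @examples
#' f <- simulate_diffusion(diffusion_spec(nx_m = 40, nx_s = 40, dt = 0.01,
#'                                        t_end = 1))
simulate_diffusion <- function(spec) {
  spec <- validate_diffusion_spec(spec)
  op <- build_diffusion_operator(spec)
  nm <- spec$nx_m; ns <- spec$nx_s; I <- op$I; N <- op$N
  nsteps <- max(1L, as.integer(round(spec$t_end / spec$dt)))
  dt <- spec$t_end / nsteps
  M <- diag(op$mvec, N, N)
  P_be_inv <- solve(M - dt * op$A)              # backward Euler: w' = P (rhs)
  P_cn <- P_be_inv_half <- NULL
  if (nsteps > 2L) {
    Mminus <- M - (dt / 2) * op$A
    P_cn <- solve(Mminus, M + (dt / 2) * op$A)  # CN propagator
  }
  # initial data (piecewise): matrix-side interface value Cm0
  w <- c(rep(spec$Cm0, nm + 1L), rep(spec$Cs0, ns))
  # exact initial cell masses; interface cell straddles the discontinuity
  m0 <- op$mvec * w
  m0[I] <- op$dxm / 2 * spec$Cm0 + op$dxs / 2 * spec$Cs0
  out_stride <- max(1L, as.integer(round(spec$out_every / dt)))
  keep <- unique(c(0L, seq(out_stride, nsteps, by = out_stride), nsteps))
  t_out <- keep * dt
  C <- matrix(NA_real_, nm + 1L + ns + 1L, length(keep))
  full_col <- function(w) c(w[seq_len(nm + 1L)], spec$km * w[I],
                            w[seq(I + 1L, length.out = ns)])
  C[, 1] <- c(rep(spec$Cm0, nm + 1L), rep(spec$Cs0, ns + 1L))  # t = 0 slice
  col <- 2L
  for (n in seq_len(nsteps)) {
    if (n == 1L) {
      w <- as.vector(P_be_inv %*% m0)
    } else if (n == 2L) {
      w <- as.vector(P_be_inv %*% (op$mvec * w))
    } else {
      w <- as.vector(P_cn %*% w)
    }
    if (col <= length(keep) && n == keep[col]) {
      C[, col] <- full_col(w)
      col <- col + 1L
    }
  }
  scale0 <- max(spec$Cm0, spec$Cs0, .Machine$double.eps)
  if (any(!is.finite(C)))
    numeric_error(sprintf(
      "solver produced non-finite values; refine dt (= %g h) or nx_m/nx_s (%d/%d)",
      dt, nm, ns))
  if (min(C) < -1e-6 * scale0)
    numeric_error(sprintf(
      "solver instability: concentration %g < 0; refine dt (= %g h) or nx_m/nx_s (%d/%d)",
      min(C), dt, nm, ns))
  x <- c(seq(-spec$Lm, 0, length.out = nm + 1L),
         seq(0, spec$Ls, length.out = ns + 1L))
  field <- list(x = x, t = t_out, C = C,
                layer = c(rep("matrix", nm + 1L), rep("skin", ns + 1L)),
                spec = spec)
  class(field) <- "concentration_field"
  field
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("<concentration_field> %d nodes x %d times, t = 0..%g h\n",
              nrow(x$C), ncol(x$C), max(x$t)))
  cat(sprintf("  layers: %d matrix + %d skin nodes; C range [%.4g, %.4g]\n",
              sum(x$layer == "matrix"), sum(x$layer == "skin"),
              min(x$C), max(x$C)))
  invisible(x)
}

#' Extract the concentration time course at a probe depth
#'
#' Linear interpolation of the skin-layer field at `depth` cm below the
#' skin surface, for every stored output time. Depth 0 returns the
#' skin-side interface series (km times the matrix-side series). The
#' default depth, 0.0336 cm, is the subcutaneous probe position of the
#' study design this package emulates.
#'
#' @param field a `concentration_field` from [simulate_diffusion()].
#' @param depth probe depth in cm, in `[0, Ls]`.
#' @return A [timeseries_table] (time in minutes).
#' @export
probe_series <- function(field, depth = 0.0336) {
  stopifnot(inherits(field, "concentration_field"))
  spec <- field$spec
  if (!is.numeric(depth) || length(depth) != 1L || !is.finite(depth) ||
      depth < 0 || depth > spec$Ls)
    domain_error(sprintf("depth must lie in the skin layer [0, %g] cm (got %g)",
                         spec$Ls, depth))
  skin <- field$layer == "skin"
  xs <- field$x[skin]
  Cs <- field$C[skin, , drop = FALSE]
  dxs <- spec$Ls / spec$nx_s
  j <- min(max(floor(depth / dxs) + 1L, 1L), length(xs) - 1L)
  wgt <- (depth - xs[j]) / dxs
  vals <- (1 - wgt) * Cs[j, ] + wgt * Cs[j + 1L, ]
  ts <- data.frame(time = hours_to_minutes(field$t), value = pmax(vals, 0))
  attr(ts, "site") <- "skin"
  attr(ts, "meta") <- list(depth_cm = depth, unit = "model")
  class(ts) <- c("timeseries_table", "data.frame")
  ts
}

#' Mass accounting for a simulated field
#'
#' Resident drug mass per unit area (trapezoidal integral of C over both
#' layers), cleared mass (time integral of the capillary uptake flux
#' `kcl * Cs(Ls, t)`), and the relative conservation error against the
#' initial loading `Lm*Cm0 + Ls*Cs0`.
#'
#' @param field a `concentration_field`.
#' @return data.frame with columns `t` (h), `resident`, `cleared`,
#'   `relative_error`.
#' @export
mass_balance <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  spec <- field$spec
  mat <- field$layer == "matrix"; skin <- field$layer == "skin"
  xm <- field$x[mat]; xs <- field$x[skin]
  resident <- vapply(seq_along(field$t), function(k)
    trapz(xm, field$C[mat, k]) + trapz(xs, field$C[skin, k]), numeric(1))
  flux <- spec$kcl * field$C[nrow(field$C), ]
  cleared <- cumtrapz(field$t, flux)
  m_init <- spec$Lm * spec$Cm0 + spec$Ls * spec$Cs0
  rel <- if (m_init > 0) abs(resident + cleared - m_init) / m_init
         else abs(resident + cleared)
  data.frame(t = field$t, resident = resident, cleared = cleared,
             relative_error = rel)
}

#' Reference explicit-Euler solver (validation oracle)
#'
#' An independently coded solution of the same two-layer model: explicit
#' forward-Euler time stepping on per-layer arrays with ghost-node boundary
#' conditions and a zero-capacity interface node obtained each step from
#' flux continuity plus the partition jump. Deliberately uses a different
#' interface treatment and time integrator than [simulate_diffusion()], so
#' agreement between the two is a meaningful cross-check. Subject to the
#' usual explicit stability limit `dt <= dx^2/(2 D)` (checked).
#'
#' @param spec a [diffusion_spec()]; `dt` must satisfy the explicit
#'   stability limit for both layers.
#' @return A `concentration_field`, same layout as [simulate_diffusion()].
#' @export
simulate_diffusion_reference <- function(spec) {
  spec <- validate_diffusion_spec(spec)
  nm <- spec$nx_m; ns <- spec$nx_s
  dxm <- spec$Lm / nm; dxs <- spec$Ls / ns
  rm_ <- spec$Dm * spec$dt / dxm^2
  rs_ <- spec$Ds * spec$dt / dxs^2
  # the Robin row adds a clearance term to the skin-base stability limit
  r_bnd <- 2 * rs_ + 2 * spec$dt * spec$kcl / dxs
  if (rm_ > 0.5 || rs_ > 0.5 || r_bnd > 1)
    numeric_error(sprintf(
      "explicit scheme unstable: D*dt/dx^2 = %.3g (matrix), %.3g (skin), boundary factor %.3g; need <= 0.5 / <= 1",
      rm_, rs_, r_bnd))
  nsteps <- max(1L, as.integer(round(spec$t_end / spec$dt)))
  dt <- spec$t_end / nsteps
  u <- rep(spec$Cm0, nm + 1L)   # matrix nodes incl. interface
  v <- rep(spec$Cs0, ns + 1L)   # skin nodes incl. interface
  # zero-capacity interface value from flux continuity + partition
  iface <- function(u, v) (spec$Dm / dxm * u[nm] + spec$Ds / dxs * v[2]) /
    (spec$Dm / dxm + spec$km * spec$Ds / dxs)
  ui <- iface(u, v); u[nm + 1L] <- ui; v[1] <- spec$km * ui
  out_stride <- max(1L, as.integer(round(spec$out_every / dt)))
  keep <- unique(c(0L, seq(out_stride, nsteps, by = out_stride), nsteps))
  C <- matrix(NA_real_, nm + 1L + ns + 1L, length(keep))
  C[, 1] <- c(rep(spec$Cm0, nm + 1L), rep(spec$Cs0, ns + 1L))
  col <- 2L
  for (n in seq_len(nsteps)) {
    un <- u; vn <- v
    # matrix: ghost node beyond x=-Lm mirrors (zero flux)
    u[1] <- un[1] + 2 * rm_ * (un[2] - un[1])
    i <- 2:nm
    u[i] <- un[i] + rm_ * (un[i + 1L] - 2 * un[i] + un[i - 1L])
    # skin interior
    j <- 2:ns
    v[j] <- vn[j] + rs_ * (vn[j + 1L] - 2 * vn[j] + vn[j - 1L])
    # skin base: Robin via ghost node v[ns+2] = v[ns] - 2*dxs*kcl/Ds*v[ns+1]
    v[ns + 1L] <- vn[ns + 1L] + rs_ *
      (vn[ns] - 2 * vn[ns + 1L] + vn[ns] - 2 * dxs * spec$kcl / spec$Ds * vn[ns + 1L])
    ui <- iface(u, v); u[nm + 1L] <- ui; v[1] <- spec$km * ui
    if (col <= length(keep) && n == keep[col]) {
      C[, col] <- c(u, v)
      col <- col + 1L
    }
  }
  x <- c(seq(-spec$Lm, 0, length.out = nm + 1L),
         seq(0, spec$Ls, length.out = ns + 1L))
  field <- list(x = x, t = keep * dt, C = C,
                layer = c(rep("matrix", nm + 1L), rep("skin", ns + 1L)),
                spec = spec)
  class(field) <- "concentration_field"
  field
}

#' Export a concentration field as long-format CSV
#'
#' @param field a `concentration_field`.
#' @param path output path; columns `x`, `t`, `C`, `layer`.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "concentration_field"))
  long <- data.frame(x = rep(field$x, times = length(field$t)),
                     t = rep(field$t, each = length(field$x)),
                     C = as.vector(field$C),
                     layer = rep(field$layer, times = length(field$t)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
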