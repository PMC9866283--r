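# Solver checks use moderate diffusivities (1e-3 cm^2/h scale) where the
# dynamics play out within a short horizon; the default transdermal values
# (1e-5 scale) are exercised in the acceptance suite.

test_that("initial slice is the exact piecewise profile", {
  sp <- diffusion_spec(nx_m = 20, nx_s = 20, dt = 0.01, t_end = 0.1)
  f <- simulate_diffusion(sp)
  expect_identical(f$C[f$layer == "matrix", 1], rep(0.2, 21))
  expect_identical(f$C[f$layer == "skin", 1], rep(0, 21))
  expect_equal(f$t[1], 0)
  # duplicated interface coordinate, one per layer side
  expect_equal(sum(f$x == 0), 2)
})

test_that("closed symmetric system relaxes to the mean concentration", {
  sp <- diffusion_spec(Dm = 1e-3, Ds = 1e-3, km = 1, kcl = 0,
                       Cm0 = 0.2, Cs0 = 0, t_end = 10,
                       nx_m = 100, nx_s = 100, dt = 0.002)
  f <- simulate_diffusion(sp)
  expect_equal(f$C[, ncol(f$C)], rep(0.1, nrow(f$C)), tolerance = 1e-4)
})

test_that("partitioned closed system reaches the analytic equilibrium", {
  sp <- diffusion_spec(Dm = 1e-3, Ds = 1e-3, km = 0.5, kcl = 0,
                       t_end = 10, nx_m = 100, nx_s = 100, dt = 0.002)
  f <- simulate_diffusion(sp)
  cm_inf <- 0.2 * sp$Lm / (sp$Lm + sp$km * sp$Ls)
  expect_equal(f$C[1, ncol(f$C)], cm_inf, tolerance = 1e-3)
  expect_equal(f$C[1, ncol(f$C)], 0.13333, tolerance = 1e-3)
  skin_end <- f$C[f$layer == "skin", ncol(f$C)]
  expect_equal(skin_end, rep(sp$km * cm_inf, length(skin_end)),
               tolerance = 1e-3)
})

test_that("field stays non-negative and matrix surface decays monotonically", {
  for (kcl in c(0, 5, 25)) {
    sp <- diffusion_spec(Dm = 5e-4, Ds = 8e-4, kcl = kcl, t_end = 4,
                         nx_m = 80, nx_s = 80, dt = 0.002)
    f <- simulate_diffusion(sp)
    expect_gte(min(f$C), -1e-12)
    expect_true(all(diff(f$C[1, ]) <= 1e-12))
  }
})

test_that("probe series interpolates the skin field correctly", {
  sp <- diffusion_spec(Dm = 1e-3, Ds = 1e-3, km = 0.5, kcl = 2,
                       t_end = 2, nx_m = 50, nx_s = 50, dt = 0.002)
  f <- simulate_diffusion(sp)
  # on-node depth: exact node values
  dxs <- sp$Ls / sp$nx_s
  node <- 10
  ps <- probe_series(f, depth = node * dxs)
  expect_equal(ps$value, pmax(f$C[which(f$layer == "skin")[node + 1], ], 0),
               tolerance = 1e-14)
  # depth 0 is the skin-side interface = km * matrix-side series (t > 0)
  ps0 <- probe_series(f, depth = 0)
  iface_matrix <- f$C[sum(f$layer == "matrix"), ]
  expect_equal(ps0$value[-1], (sp$km * iface_matrix)[-1], tolerance = 1e-12)
  # times reported in minutes
  expect_equal(ps$time, f$t * 60)
  expect_error(probe_series(f, depth = 0.05), class = "dermakin_domain_error")
})

test_that("probe series of a uniform field is constant at any depth", {
  sp <- diffusion_spec(Dm = 1e-3, Ds = 1e-3, km = 1, kcl = 0,
                       Cm0 = 0.07, Cs0 = 0.07, t_end = 1,
                       nx_m = 40, nx_s = 40, dt = 0.005)
  f <- simulate_diffusion(sp)
  for (depth in c(0, 0.013, 0.04))
    expect_equal(probe_series(f, depth)$value, rep(0.07, length(f$t)),
                 tolerance = 1e-10)
})

test_that("mass is conserved: closed system and clearance bookkeeping", {
  # kcl = 0: resident mass constant
  sp <- diffusion_spec(Dm = 1e-3, Ds = 1e-3, km = 0.5, kcl = 0, t_end = 5,
                       nx_m = 100, nx_s = 100, dt = 0.002)
  mb <- mass_balance(simulate_diffusion(sp))
  expect_equal(mb$cleared, rep(0, length(mb$cleared)))
  expect_lt(max(mb$relative_error), 1e-3)
  expect_equal(mb$relative_error[1], 0)

  # with clearance: resident + cleared accounts for the initial load
  sp2 <- diffusion_spec(Dm = 1e-3, Ds = 1e-3, kcl = 5, t_end = 5,
                        nx_m = 100, nx_s = 100, dt = 0.002)
  mb2 <- mass_balance(simulate_diffusion(sp2))
  expect_gt(mb2$cleared[length(mb2$cleared)], 0)
  expect_lt(max(mb2$relative_error), 1e-3)
})

test_that("halving dx and dt changes the probe series by < 0.5% sup-norm", {
  base <- diffusion_spec(Dm = 1e-3, Ds = 1e-3, km = 0.5, kcl = 5, t_end = 2,
                         nx_m = 60, nx_s = 60, dt = 0.005)
  fine <- diffusion_spec(Dm = 1e-3, Ds = 1e-3, km = 0.5, kcl = 5, t_end = 2,
                         nx_m = 120, nx_s = 120, dt = 0.0025)
  p1 <- probe_series(simulate_diffusion(base))
  p2 <- probe_series(simulate_diffusion(fine))
  expect_lt(max(abs(p1$value - p2$value)) / max(p2$value), 0.005)
})

test_that("early-time interface solution matches the erfc closed form", {
  D <- 1e-3
  sp <- diffusion_spec(Dm = D, Ds = D, km = 1, kcl = 0, t_end = 0.1,
                       dt = 1e-4, nx_m = 200, nx_s = 200, out_every = 0.02)
  f <- simulate_diffusion(sp)
  erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
  for (k in 2:length(f$t)) {
    t <- f$t[k]
    sig <- sqrt(D * t)          # sqrt(D t) < Lm/4 throughout this horizon
    sel <- abs(f$x) <= 2 * sig
    exact <- (sp$Cm0 / 2) * erfc(f$x[sel] / (2 * sig))
    expect_lt(max(abs(f$C[sel, k] - exact)) / max(exact), 0.02)
  }
})

test_that("Crank-Nicolson solution matches the independent explicit solver", {
  sp <- diffusion_spec(Dm = 8e-4, Ds = 1e-3, km = 0.8, kcl = 0.5,
                       t_end = 0.5, dt = 2e-4, nx_m = 40, nx_s = 40,
                       out_every = 0.05)
  fe <- simulate_diffusion_reference(sp)
  fc <- simulate_diffusion(sp)
  expect_equal(fe$t, fc$t)
  expect_lt(max(abs(fe$C - fc$C)) / max(fc$C), 0.01)

  # the reference solver refuses unstable settings
  expect_error(
    simulate_diffusion_reference(diffusion_spec(Dm = 1e-2, Ds = 1e-2,
                                                t_end = 1, dt = 0.01,
                                                nx_m = 40, nx_s = 40)),
    class = "dermakin_numeric_error")
})

test_that("spec validation rejects unphysical parameters", {
  expect_error(diffusion_spec(Dm = -1), class = "dermakin_validation_error")
  expect_error(diffusion_spec(km = 0), class = "dermakin_validation_error")
  expect_error(diffusion_spec(kcl = -2), class = "dermakin_validation_error")
  expect_error(diffusion_spec(Cm0 = -0.1), class = "dermakin_validation_error")
  expect_error(diffusion_spec(dt = 0), class = "dermakin_validation_error")
})
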