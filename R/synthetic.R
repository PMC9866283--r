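# Seeded synthetic-data generators. Every generator is a pure function of
# (parameters, seed): the global RNG state is saved and restored around the
# draw. Noise is multiplicative lognormal for concentrations (keeps
# positivity, unit mean) and additive normal for recovery percentages.

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Synthetic study scenario
#'
#' Bundles the forward diffusion model with the sampling design and probe
#' recoveries of a skin-blood microdialysis experiment: 30-minute dialysate
#' sampling over 12 h, a skin probe at 0.0336 cm depth corrected by the
#' linear-probe recovery, and a blood-site series at the capillary boundary
#' corrected by the concentric-probe recovery.
#'
#' @param model a [diffusion_spec()]; default is the standard spec with the
#'   horizon extended to 12 h to cover the sampling window.
#' @param probe_depth skin probe depth (cm), default 0.0336.
#' @param recovery_skin linear (skin) probe in vivo recovery fraction,
#'   default 0.697.
#' @param recovery_blood concentric (blood) probe in vivo recovery
#'   fraction, default 0.516.
#' @param sampling_interval minutes between dialysate collections, default 30.
#' @param duration experiment length in minutes, default 720 (12 h).
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise, default 0.05.
#' @param seed RNG seed recorded in all outputs, default 1.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(model = diffusion_spec(t_end = 12),
                               probe_depth = 0.0336, recovery_skin = 0.697,
                               recovery_blood = 0.516,
                               sampling_interval = 30, duration = 720,
                               noise_cv = 0.05, seed = 1L) {
  stopifnot(inherits(model, "diffusion_spec"))
  for (r in c(recovery_skin, recovery_blood))
    if (!is.finite(r) || r <= 0 || r > 1)
      validation_error("recoveries must be fractions in (0, 1]")
  if (!is.finite(noise_cv) || noise_cv < 0)
    validation_error("noise_cv must be >= 0")
  if (sampling_interval <= 0 || duration < sampling_interval)
    validation_error("need duration >= sampling_interval > 0")
  if (minutes_to_hours(duration) > model$t_end)
    validation_error(sprintf(
      "sampling window (%g h) exceeds the model horizon t_end = %g h",
      minutes_to_hours(duration), model$t_end))
  out <- list(model = model, probe_depth = probe_depth,
              recovery_skin = recovery_skin, recovery_blood = recovery_blood,
              sampling_interval = sampling_interval, duration = duration,
              noise_cv = noise_cv, seed = as.integer(seed))
  class(out) <- "synthetic_scenario"
  out
}

#' Generate a dialysate sampling data set with known truth
#'
#' Runs the forward diffusion model, samples the true concentration at the
#' probe site on the dialysate collection grid, and attenuates it by the
#' probe recovery plus multiplicative lognormal noise. Both the true tissue
#' series and the observed dialysate series are returned, so recovery
#' correction and diffusivity fitting can be validated against ground
#' truth.
#'
#' @param scn a [synthetic_scenario()].
#' @param site `"skin"` (probe at `probe_depth`, attenuated by
#'   `recovery_skin`) or `"blood"` (capillary-boundary concentration,
#'   attenuated by `recovery_blood`).
#' @param field optional precomputed `concentration_field` for `scn$model`
#'   (lets callers reuse one simulation across noise replicates).
#' @return list with `true` and `observed` [timeseries_table]s; metadata
#'   records the recovery, noise level and seed.
#' @export
make_dialysate_dataset <- function(scn, site = c("skin", "blood"),
                                   field = NULL) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  site <- match.arg(site)
  if (is.null(field)) field <- simulate_diffusion(scn$model)
  t_min <- seq(scn$sampling_interval, scn$duration,
               by = scn$sampling_interval)
  if (site == "skin") {
    ps <- probe_series(field, scn$probe_depth)
    recovery <- scn$recovery_skin
  } else {
    skin_rows <- which(field$layer == "skin")
    ps <- data.frame(time = hours_to_minutes(field$t),
                     value = field$C[skin_rows[length(skin_rows)], ])
    recovery <- scn$recovery_blood
  }
  truth <- stats::approx(ps$time, ps$value, xout = t_min, rule = 2)$y
  meta <- list(site = site, recovery = recovery, noise_cv = scn$noise_cv,
               seed = scn$seed, depth_cm = scn$probe_depth)
  true_ts <- timeseries_table(t_min, truth, site = site, meta = meta)
  noise <- with_seed(scn$seed, lognormal_noise(length(truth), scn$noise_cv))
  obs_ts <- timeseries_table(t_min, truth * recovery * noise, site = site,
                             meta = meta)
  list(true = true_ts, observed = obs_ts)
}

#' Generate a Franz-cell permeation data set from the membrane closed form
#'
#' The cumulative amount through a homogeneous membrane with constant
#' donor concentration `c0` and a perfect sink is
#' \deqn{Q(t) = \frac{D c_0}{L}\Big(t - \frac{L^2}{6D}\Big)
#'   - \frac{2 c_0 L}{\pi^2} \sum_{n \ge 1} \frac{(-1)^n}{n^2}
#'     e^{-D n^2 \pi^2 t / L^2},}
#' whose large-time slope is the steady-state flux `D*c0/L` and whose
#' time-axis intercept is the lag time `L^2/(6D)`. The series is truncated
#' at relative 1e-8. Q is converted to receptor concentrations by inverting
#' the replacement-volume bookkeeping of [cumulative_amount()], then
#' multiplied by lognormal noise.
#'
#' @param D membrane diffusivity (cm^2/h).
#' @param c0 donor concentration (ng/cm^3).
#' @param L membrane thickness (cm).
#' @param times sampling times in hours, default `1:12` (hourly over 12 h).
#' @param Vn,Vi,A cell geometry as in [permeation_record()].
#' @param noise_cv multiplicative noise CV on concentrations, default 0.05.
#' @param seed RNG seed, default 1.
#' @return list with `record` (a noisy [permeation_record()]), `Q_true`
#'   (noiseless cumulative amounts) and the closed-form `flux` and
#'   `lag_time`.
#' @export
make_permeation_dataset <- function(D, c0, L, times = 1:12, Vn = 5, Vi = 1,
                                    A = 0.785, noise_cv = 0.05, seed = 1L) {
  stopifnot(D > 0, c0 > 0, L > 0, all(times > 0))
  Q_true <- vapply(times, function(t) membrane_Q(t, D, c0, L), numeric(1))
  # invert Qn = (Cn*Vn + sum_{i<n} Ci*Vi)/A for the concentrations
  Cn <- numeric(length(times))
  removed <- 0
  for (n in seq_along(times)) {
    Cn[n] <- (A * Q_true[n] - removed) / Vn
    removed <- removed + Cn[n] * Vi
  }
  noise <- with_seed(seed, lognormal_noise(length(Cn), noise_cv))
  rec <- permeation_record(times, Cn * noise, Vn = Vn, Vi = Vi, A = A)
  list(record = rec, Q_true = data.frame(time = times, Qn = Q_true),
       flux = D * c0 / L, lag_time = L^2 / (6 * D), seed = as.integer(seed))
}

# Closed-form cumulative amount through a homogeneous membrane (sink
# receptor, constant donor), series truncated at relative 1e-8.
membrane_Q <- function(t, D, c0, L, rel_tol = 1e-8) {
  base <- D * c0 / L * (t - L^2 / (6 * D))
  s <- 0
  scale <- max(abs(base), c0 * L / 6)
  for (n in 1:10000) {
    term <- (-1)^n / n^2 * exp(-D * n^2 * pi^2 * t / L^2)
    s <- s + term
    if (abs(term) < rel_tol * scale * pi^2 / (2 * L * c0 + 1e-300) ||
        abs(term) < 1e-16) break
  }
  base - 2 * c0 * L / pi^2 * s
}

#' Generate a probe calibration data set with known recovery
#'
#' Gain and loss replicates at the standard three concentration levels
#' (52.5, 210, 1050 ng/mL by default), with additive normal noise on the
#' recovery percentage. `loss_offset` shifts the loss-method true recovery
#' to create method disagreement for power checks.
#'
#' @param true_R true recovery as a fraction in (0, 1].
#' @param n replicates per (method, level), >= 2, default 5.
#' @param noise_sd SD of the additive noise in percentage points; a single
#'   value or a named vector `c(gain = ..., loss = ...)`. Default 2.5.
#' @param seed RNG seed, default 1.
#' @param levels nominal concentrations (ng/mL), default
#'   `c(52.5, 210, 1050)`.
#' @param probe_kind `"linear"` or `"concentric"`, default `"linear"`.
#' @param loss_offset percentage points added to the loss-method true
#'   recovery, default 0.
#' @return A [probe_calibration()].
#' @export
make_calibration_dataset <- function(true_R, n = 5L, noise_sd = 2.5,
                                     seed = 1L, levels = c(52.5, 210, 1050),
                                     probe_kind = "linear",
                                     loss_offset = 0) {
  stopifnot(true_R > 0, true_R <= 1, n >= 2L)
  sd_gain <- if (!is.null(names(noise_sd))) noise_sd[["gain"]] else noise_sd[1]
  sd_loss <- if (!is.null(names(noise_sd))) noise_sd[["loss"]] else noise_sd[1]
  rows <- with_seed(seed, {
    out <- list()
    for (lv in levels) {
      r_gain <- 100 * true_R + stats::rnorm(n, 0, sd_gain)
      r_loss <- 100 * true_R + loss_offset + stats::rnorm(n, 0, sd_loss)
      r_gain <- pmax(r_gain, 0)
      r_loss <- pmin(pmax(r_loss, 0), 100)
      out[[length(out) + 1L]] <- data.frame(
        probe_kind = probe_kind, method = "gain", c_in = lv,
        c_out = lv * r_gain / 100, replicate = seq_len(n))
      out[[length(out) + 1L]] <- data.frame(
        probe_kind = probe_kind, method = "loss", c_in = lv,
        c_out = lv * (1 - r_loss / 100), replicate = seq_len(n))
    }
    out
  })
  probe_calibration(do.call(rbind, rows))
}

#' Generate a toy bilayer trajectory
#'
#' Phosphate atoms are laid out on two square lattices at z = +/-
#' thickness/2 and jittered independently per frame with isotropic Gaussian
#' noise; optional water representative atoms fill a slab above the upper
#' leaflet and an optional ligand blob sits above the water.
#'
#' @param n_lipids_per_leaflet phosphates per leaflet, default 100.
#' @param thickness headgroup plane separation (Angstrom), default 50.
#' @param n_frames number of frames, default 50.
#' @param jitter_sd per-axis Gaussian jitter SD (Angstrom), default 1.
#' @param seed RNG seed, default 1.
#' @param n_waters water representative atoms above the upper leaflet,
#'   default 0.
#' @param with_ligand add a small rigid ligand blob above the water slab?
#'   Default FALSE.
#' @return A [trajectory()] with tags `"P"`, `"W"` and `"LIG"`.
#' @export
make_trajectory <- function(n_lipids_per_leaflet = 100L, thickness = 50,
                            n_frames = 50L, jitter_sd = 1, seed = 1L,
                            n_waters = 0L, with_ligand = FALSE) {
  stopifnot(n_lipids_per_leaflet >= 1L, thickness > 0, n_frames >= 1L,
            jitter_sd >= 0)
  side <- ceiling(sqrt(n_lipids_per_leaflet))
  spacing <- 8  # Angstrom, roughly one lipid headgroup per 64 A^2
  g <- expand.grid(x = seq_len(side), y = seq_len(side))[
    seq_len(n_lipids_per_leaflet), ]
  base_xy <- as.matrix(g) * spacing
  p_up <- cbind(base_xy, thickness / 2)
  p_lo <- cbind(base_xy, -thickness / 2)
  base <- rbind(p_up, p_lo)
  tags <- rep("P", nrow(base))
  with_seed(seed, {
    if (n_waters > 0L) {
      span <- side * spacing
      w <- cbind(stats::runif(n_waters, 0, span),
                 stats::runif(n_waters, 0, span),
                 stats::runif(n_waters, thickness / 2 + 2, thickness / 2 + 15))
      base <- rbind(base, w)
      tags <- c(tags, rep("W", n_waters))
    }
    if (with_ligand) {
      centre <- c(side * spacing / 2, side * spacing / 2, thickness / 2 + 18)
      lig <- sweep(matrix(stats::rnorm(15, 0, 1.5), ncol = 3), 2, centre, `+`)
      base <- rbind(base, lig)
      tags <- c(tags, rep("LIG", nrow(lig)))
    }
    frames <- lapply(seq_len(n_frames), function(k)
      base + matrix(stats::rnorm(length(base), 0, jitter_sd), ncol = 3))
    trajectory(frames, data.frame(id = seq_along(tags), tag = tags),
               times = seq_len(n_frames))
  })
}
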