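test_that("gain and loss recovery formulas and their edge cases", {
  expect_equal(gain_recovery(100, 61.4), 61.4)
  expect_equal(gain_recovery(52.5, 52.5), 100)
  expect_equal(gain_recovery(52.5, 0), 0)
  expect_error(gain_recovery(0, 10), class = "dermakin_domain_error")

  expect_equal(loss_recovery(100, 40), 60)
  expect_equal(loss_recovery(210, 210), 0)
  expect_equal(loss_recovery(210, 0), 100)
  expect_error(loss_recovery(-5, 1), class = "dermakin_domain_error")
  expect_warning(r <- loss_recovery(100, 110), "clipped")
  expect_equal(r, 0)
})

test_that("relative recovery reduces to the gain and loss formulas", {
  expect_equal(relative_recovery(50, 0, 100), 0.5)
  expect_equal(relative_recovery(60, 100, 0), 0.4)
  expect_error(relative_recovery(100, 100, 100), class = "dermakin_domain_error")

  # algebraic identities on random inputs
  set.seed(21)
  for (i in 1:25) {
    c_in <- runif(1, 10, 1000)
    c_out <- runif(1, 0, c_in)
    expect_equal(relative_recovery(c_out, 0, c_in),
                 gain_recovery(c_in, c_out) / 100)
    expect_equal(relative_recovery(c_out, c_in, 0),
                 loss_recovery(c_in, c_out) / 100)
  }
})

make_cal <- function(recoveries, method = "loss", probe = "concentric",
                     levels = seq_along(recoveries)) {
  # build measurements whose computed recovery equals `recoveries` exactly
  df <- do.call(rbind, Map(function(r, lv) {
    c_in <- 100
    c_out <- if (method == "gain") c_in * r / 100 else c_in * (1 - r / 100)
    data.frame(probe_kind = probe, method = method, c_in = lv * 1000 + c_in,
               c_out = (lv * 1000 + c_in) *
                 (if (method == "gain") r / 100 else 1 - r / 100),
               replicate = 1L)
  }, recoveries, levels))
  df
}

test_that("calibration summary: level means, n-1 SDs and unweighted pooling", {
  # single level, two replicates
  df <- data.frame(probe_kind = "linear", method = "gain",
                   c_in = c(100, 100, 100, 100),
                   c_out = c(60, 60, 50, 70), replicate = 1:4)
  df$c_in[3:4] <- 200; df$c_out[3:4] <- c(100, 140)  # level 2: {50, 70}%
  s <- summarize_calibration(probe_calibration(df))
  lev1 <- s$levels[s$levels$c_in == 100, ]
  expect_equal(lev1$mean, 60); expect_equal(lev1$sd, 0)
  lev2 <- s$levels[s$levels$c_in == 200, ]
  expect_equal(lev2$mean, 60)
  expect_equal(lev2$sd, sqrt(sum((c(50, 70) - 60)^2) / 1))  # 14.1421...
  expect_equal(lev2$sd, 14.1421356, tolerance = 1e-7)

  # pooled concentric in vivo recovery: unweighted mean over levels
  cal <- probe_calibration(make_cal(c(46.4, 54.1, 54.4)))
  p <- summarize_calibration(cal)$pooled
  expect_equal(p$mean, mean(c(46.4, 54.1, 54.4)))
  expect_equal(round(p$mean, 1), 51.6)

  expect_error(summarize_calibration(df[0, ]),
               class = "dermakin_validation_error")
})

test_that("pooled mean is invariant to measurement order", {
  cal <- make_calibration_dataset(0.62, n = 4, noise_sd = 3, seed = 8)
  df <- as.data.frame(cal)[c("probe_kind", "method", "c_in", "c_out", "replicate")]
  s1 <- summarize_calibration(probe_calibration(df))
  s2 <- summarize_calibration(probe_calibration(df[rev(seq_len(nrow(df))), ]))
  expect_equal(s1$pooled, s2$pooled)
  expect_equal(s1$levels, s2$levels)
})

test_that("gain/loss equivalence test decides the trivial cases correctly", {
  # identical replicate sets -> p = 1, pass
  df <- rbind(
    data.frame(probe_kind = "linear", method = "gain", c_in = 100,
               c_out = c(60, 60, 60), replicate = 1:3),
    data.frame(probe_kind = "linear", method = "loss", c_in = 100,
               c_out = c(40, 40, 40), replicate = 1:3))
  eq <- gain_loss_equivalence(probe_calibration(df))
  expect_equal(eq$table$p_value, 1)
  expect_true(eq$overall_pass)

  # disjoint constant values -> fail
  df$c_out[df$method == "loss"] <- 10   # loss recovery 90%
  eq2 <- gain_loss_equivalence(probe_calibration(df))
  expect_equal(eq2$table$p_value, 0)
  expect_false(eq2$overall_pass)

  # unmatched levels -> validation error naming the level
  df3 <- df
  df3$c_in[df3$method == "loss"] <- 210
  err <- expect_error(gain_loss_equivalence(probe_calibration(df3)),
                      class = "dermakin_validation_error")
  expect_match(conditionMessage(err), "210|100")
})

test_that("equivalence passes for near-equal methods at the observed rate", {
  # gain ~ N(61.4, 2.4), loss ~ N(59.2, 3.1), n = 5: the exact Welch power
  # arithmetic for this configuration gives a pass (non-rejection) rate of
  # ~0.82; assert a band computed from a 4000-rep simulation (0.8178 +/- 0.006)
  passes <- vapply(1:200, function(k) {
    cal <- withr::with_seed(k, {
      g <- rnorm(5, 61.4, 2.4)
      l <- rnorm(5, 59.2, 3.1)
      rbind(
        data.frame(probe_kind = "linear", method = "gain", c_in = 100,
                   c_out = g, replicate = 1:5),
        data.frame(probe_kind = "linear", method = "loss", c_in = 100,
                   c_out = 100 - l, replicate = 1:5))
    })
    gain_loss_equivalence(probe_calibration(cal))$overall_pass
  }, logical(1))
  expect_gte(mean(passes), 0.78)
})

test_that("correct_series divides by recovery and inverts exactly", {
  ts <- timeseries_table(30, 100)
  expect_equal(correct_series(ts, 0.5)$value, 200)
  expect_equal(correct_series(ts, 1)$value, 100)
  expect_equal(correct_series(timeseries_table(30, 103.2), 0.516)$value, 200)
  expect_error(correct_series(ts, 0), class = "dermakin_domain_error")
  expect_error(correct_series(ts, 1.2), class = "dermakin_domain_error")

  # round trip inverts to machine precision
  set.seed(3)
  ts2 <- timeseries_table(cumsum(runif(10, 1, 30)), rexp(10, 1e-2))
  r <- 0.697
  expect_equal(correct_series(ts2, r)$value * r, ts2$value,
               tolerance = 1e-15)
  expect_identical(attr(correct_series(ts2, r), "meta")$recovery_used, r)
})
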