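test_that("BCECF ratio-to-pH conversion is the exact inverse of the forward map", {
  cal <- calibration_line(0.8, -3.5, 6.4, 7.8)
  ph_in <- seq(6.5, 7.7, by = 0.1)
  out <- bcecf_to_ph(predict_ratio(cal, ph_in), cal)
  expect_equal(out$pH, ph_in, tolerance = 1e-9)
  expect_false(any(out$extrapolated))
  # constant ratio maps to constant pH; out-of-range flagged, kept
  cst <- bcecf_to_ph(rep(2.1, 5), cal)
  expect_equal(length(unique(cst$pH)), 1)
  lo <- bcecf_to_ph(predict_ratio(cal, 6.0), cal)
  expect_true(lo$extrapolated)
  expect_equal(nrow(lo), 1)
})

test_that("alkalinization rates come from least squares over the fit window", {
  t <- seq(0, 30, by = 0.5)
  flat <- alkalinization_rate(t, rep(7, length(t)))
  expect_equal(flat$rate_pH_per_s, 0, tolerance = 1e-12)
  lin <- alkalinization_rate(t, 7 + 0.01 * t)
  expect_equal(lin$rate_pH_per_s, 0.01, tolerance = 1e-9)
  expect_error(alkalinization_rate(t[1:5], rep(7, 5)), ">= 10")
  # noisy series: recovered slope within 2 reported SEs of truth
  set.seed(3)
  noisy <- 7 + 0.01 * t + rnorm(length(t), sd = 0.005)
  fit <- alkalinization_rate(t, noisy)
  expect_lt(abs(fit$rate_pH_per_s - 0.01), 2 * fit$se + 1e-4)
})

test_that("rate normalization maps the reference to one and is idempotent", {
  rates <- data.frame(voltage_mV = c(60, 100, 140), rate = c(0.2, 0.6, 1.2))
  nr <- normalize_rates(rates)
  expect_equal(nr$rate_norm[3], 1.0)
  again <- normalize_rates(data.frame(voltage_mV = nr$voltage_mV,
                                      rate = nr$rate_norm))
  expect_equal(again$rate_norm, nr$rate_norm, tolerance = 1e-12)
  allsame <- normalize_rates(data.frame(voltage_mV = c(60, 140),
                                        rate = c(0.3, 0.3)))
  expect_true(all(allsame$rate_norm == 1))
  expect_error(normalize_rates(rates, ref_mV = 80), "not present")
})

test_that("normalized alkalinization rates overlay the normalized I-V", {
  # rates generated proportional to the activation-scaled current of a
  # strongly right-shifted transporter, then recovered through the ratio
  # pipeline and re-normalized at +140 mV
  pre <- clc5_preset("G212A")
  iv_fun <- function(v) {
    p <- 1 / (1 + exp(-(v - pre$transport$V05_mV) / thermal_mV() *
                        pre$transport$z_delta))
    pre$transport$Gmax_nS * p * v
  }
  volts <- seq(20, 140, by = 20)
  iv_norm <- iv_fun(volts) / iv_fun(140)
  cal <- calibration_line(0.8, -3.5, 6.4, 7.8)
  tc <- simulate_bcecf_timecourse(volts, function(v) 0.012 * iv_fun(v) /
                                    iv_fun(140),
                                  calibration = cal, noise_sd = 0.005,
                                  seed = 11)
  rates <- vapply(tc, function(d) {
    ph <- bcecf_to_ph(d$ratio, cal)
    alkalinization_rate(d$time_s, ph$pH)$rate_pH_per_s
  }, 1)
  nr <- normalize_rates(data.frame(voltage_mV = volts, rate = rates))
  expect_lt(max(abs(nr$rate_norm - iv_norm)), 0.05)
})

test_that("surface-expression ratios normalize to WT and flag reduced mutants", {
  set.seed(5)
  rec <- data.frame(
    construct = rep(c("WT", "E267A"), each = 6),
    luminescence = c(rnorm(6, 1000, 40), rnorm(6, 500, 40)),
    fluorescence = rep(1000, 12))
  res <- relative_surface_expression(rec)
  expect_equal(res$summary$mean[res$summary$construct == "WT"], 1.0,
               tolerance = 1e-12)
  expect_equal(res$summary$mean[res$summary$construct == "E267A"], 0.5,
               tolerance = 0.1)
  expect_true(res$tests$significant[res$tests$construct == "E267A"])
  # exactly half luminescence at equal fluorescence gives exactly 0.5
  rec2 <- data.frame(construct = c("WT", "mut"),
                     luminescence = c(800, 400), fluorescence = c(900, 900))
  res2 <- relative_surface_expression(rec2)
  expect_equal(res2$records$ratio_norm, c(1, 0.5), tolerance = 1e-12)
  rec_bad <- within(rec, fluorescence[1] <- 0)
  expect_error(relative_surface_expression(rec_bad), "non-positive")
})

test_that("the t-test matches the closed-form statistic on hand-computable input", {
  res <- compare_vesicular_ph(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res$tests$t, 0)
  expect_equal(res$tests$p, 1)
  # pooled-variance flag: equal-n equal-variance case matches Welch
  res_p <- compare_vesicular_ph(list(a = c(1, 2, 3), b = c(2, 3, 4)),
                                var_equal = TRUE)
  s2 <- 1  # pooled variance of {1,2,3} and {2,3,4}
  t_manual <- (2 - 3) / sqrt(s2 * (1 / 3 + 1 / 3))
  expect_equal(res_p$tests$t, t_manual, tolerance = 1e-12)
})
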