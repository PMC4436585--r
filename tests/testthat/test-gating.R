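test_that("P/4 subtraction nulls a purely linear cell to machine precision", {
  proto <- short_step_protocol(165, 165, 20)
  cell <- cell_params(Cm_pF = 12, Rs_MOhm = 4, Rm_MOhm = 800)
  g0 <- gating_params(Qmax_pC = 0); t0 <- transport_params(Gmax_nS = 0)
  fam <- simulate_trace_family(proto, cell, g0, t0, noise_sd_pA = 0)
  for (pol in c("inverted", "same")) {
    leak <- simulate_p4_leak_family(proto, 165, cell, g0, t0, polarity = pol)
    corr <- p4_leak_subtract(fam$sweeps[, 1], leak$sweeps,
                             n = leak$meta$scale, baseline_idx = 500:1000)
    expect_lt(max(abs(corr)), 1e-6)
  }
  # n = 2 sub-pulses null a linear cell just as well
  leak2 <- simulate_p4_leak_family(proto, 165, cell, g0, t0, n = 2,
                                   polarity = "same")
  corr2 <- p4_leak_subtract(fam$sweeps[, 1], leak2$sweeps,
                            n = leak2$meta$scale, baseline_idx = 500:1000)
  expect_lt(max(abs(corr2)), 1e-6)
})

test_that("P/4 subtraction retains the gating current", {
  pre <- clc5_preset("WT")
  proto <- short_step_protocol(165, 165, 20)
  fam <- simulate_p4_corrected_family(proto, pre$cell, pre$gating,
                                      pre$transport, noise_sd_pA = 0,
                                      filter = FALSE)
  fam0 <- simulate_trace_family(proto, pre$cell, pre$gating, pre$transport,
                                noise_sd_pA = 0, filter = FALSE)
  ig <- fam0$truth$Ig[, 1]; it <- fam0$truth$It[, 1]
  # during the tail (transport off) the corrected sweep is the gating
  # current plus the small constant transport offset at the tail voltage
  tail_idx <- which(fam$time_ms >= 60 & fam$time_ms < 80)
  resid <- fam$sweeps[tail_idx, 1] - (ig[tail_idx] + it[tail_idx])
  # residue limited to the sub-percent charge the leak pulses themselves move
  expect_lt(max(abs(resid - mean(resid))), 0.005 * max(abs(ig)))
})

test_that("p4_leak_subtract validates its inputs", {
  expect_error(p4_leak_subtract(1:10, matrix(0, 5, 4), baseline_idx = 1:2),
               "mismatched time bases")
  expect_error(p4_leak_subtract(1:10, matrix(0, 10, 4)), "baseline_idx")
})

test_that("off-charge integration matches hand arithmetic and a trapezoid oracle", {
  tm <- seq(0, 10, by = 0.01)
  sweep <- ifelse(tm >= 2 & tm < 4, 100, 0)
  q <- integrate_off_charge(sweep, tm, c(2, 4), c(8, 10))
  expect_equal(q, 0.2, tolerance = 1e-9)        # 100 pA * 2 ms = 0.2 pC
  expect_equal(integrate_off_charge(rep(0, length(tm)), tm, c(2, 4), c(8, 10)),
               0)
  expect_error(integrate_off_charge(sweep, tm, c(2, 2.03), c(8, 10)),
               "shorter than 5 samples")
  # Riemann sum vs trapezoid on a band-limited transient at 100 kHz
  tm2 <- seq(0, 20, by = 0.01)
  sw <- bessel4_lowpass(c(rep(0, 200), 500 * exp(-tm2 / 0.5)), 3, 100)
  tm2 <- seq(0, 22, by = 0.01)[seq_along(sw)]
  q_r <- integrate_off_charge(sw, tm2, c(0, 17), c(17, 20))
  q_t <- trapz_charge_pC(sw, tm2, c(0, 17),
                         baseline = mean(sw[tm2 >= 17 & tm2 < 20]))
  expect_equal(q_r, q_t, tolerance = 1e-3)
})

test_that("per-level off-charges track the generator's Boltzmann charge", {
  pre <- clc5_preset("WT")
  proto <- short_step_protocol(-115, 175, 20)
  fam <- simulate_p4_corrected_family(proto, pre$cell, pre$gating,
                                      pre$transport, noise_sd_pA = 0)
  q <- family_off_charges(fam)
  dq <- boltzmann_q(proto$levels_mV, 1, 132, 1) - boltzmann_q(-60, 1, 132, 1)
  big <- dq > 0.1    # levels carrying appreciable charge
  expect_true(all(abs(q$Q_off_pC[big] - dq[big]) / dq[big] < 0.02))
  expect_true(all(abs(q$Q_off_pC[!big] - pmax(dq[!big], 0)) < 0.01))
  # monotone non-decreasing in V up to sub-fC numerical residue
  expect_true(all(diff(q$Q_off_pC) > -2e-3))
})

test_that("steady-state current uses the window mean, not the endpoint", {
  tm <- seq(0, 10, by = 0.1)
  expect_equal(steady_state_current(rep(500, length(tm)), tm, c(8, 10)), 500)
  sag <- 1000 - 10 * tm
  expect_equal(steady_state_current(sag, tm, c(8, 10)),
               mean(sag[tm >= 8 & tm < 10]))
})

test_that("averaged I-V curves report per-voltage mean and SEM across cells", {
  pre <- clc5_preset("WT")
  proto <- short_step_protocol(-15, 165, 60)
  fam <- simulate_trace_family(proto, pre$cell, pre$gating, pre$transport,
                               noise_sd_pA = 0, filter = FALSE)
  iv1 <- build_iv(list(fam))
  expect_true(all(iv1$I_sem == 0))
  iv2 <- build_iv(list(fam, fam))
  expect_equal(iv2$I_mean, iv1$I_mean)
  expect_true(all(iv2$I_sem == 0))
  # cohort of noisy cells stays within 2 SEM-equivalents of the generator
  fams <- lapply(1:6, function(s)
    simulate_trace_family(proto, pre$cell, pre$gating, pre$transport,
                          noise_sd_pA = 5, seed = s))
  iv <- build_iv(fams)
  popen <- 1 / (1 + exp(-(proto$levels_mV - 132) / thermal_mV()))
  i_true <- 20 * popen * proto$levels_mV + proto$levels_mV  # transport + leak
  expect_true(all(abs(iv$I_mean - i_true) <= pmax(2 * iv$I_sem, 1)))
})

test_that("Q/I ratio arithmetic and division guard behave", {
  pre <- clc5_preset("WT")
  proto <- short_step_protocol(105, 165, 20)
  fam <- simulate_p4_corrected_family(proto, pre$cell, pre$gating,
                                      pre$transport, noise_sd_pA = 0)
  qi <- qi_ratio(fam, at_mV = 165)
  expect_equal(qi$ratio_ms, 1000 * qi$Q_off_pC / qi$I_ss_pA)
  expect_error(qi_ratio(fam, at_mV = 42), "not present")
  fam_no_t <- simulate_p4_corrected_family(proto, pre$cell, pre$gating,
                                           transport_params(Gmax_nS = 0),
                                           noise_sd_pA = 0)
  expect_error(qi_ratio(fam_no_t, at_mV = 165), "zero")
})

test_that("Boltzmann charge fits recover generator parameters on a grid", {
  V <- seq(-110, 350, length.out = 13)
  for (v05 in c(100, 150, 200, 250)) {
    for (z in c(0.5, 1, 2)) {
      q <- boltzmann_q(V, 1.5, v05, z)
      fit <- fit_boltzmann_q(V, q)
      expect_lt(abs(fit$Qmax_pC - 1.5) / 1.5, 0.005)
      expect_lt(abs(fit$V05_mV - v05) / v05, 0.005)
      expect_lt(abs(fit$z_delta - z) / z, 0.005)
    }
  }
})

test_that("the midpoint of a fitted Boltzmann carries half the charge", {
  V <- seq(-110, 350, by = 40)
  q <- boltzmann_q(V, 2, 132, 1)
  fit <- fit_boltzmann_q(V, q)
  q_mid <- boltzmann_q(fit$V05_mV, fit$Qmax_pC, fit$V05_mV, fit$z_delta)
  expect_equal(q_mid, fit$Qmax_pC / 2, tolerance = 1e-9)
})

test_that("saturation flag marks charge-voltage data without a plateau", {
  V <- seq(-110, 150, by = 20)       # truncated well below V05 = 240
  q <- boltzmann_q(V, 1, 240, 1)
  fit <- tryCatch(fit_boltzmann_q(V, q), error = function(e) NULL)
  if (!is.null(fit)) expect_true(fit$saturation_flag)
  expect_error(fit_boltzmann_q(V[1:3], q[1:3]), ">= 5")
})

test_that("series-resistance QC applies the 5-mV voltage-error criterion", {
  sweeps <- cbind(rep(2000, 10), rep(1000, 10))  # 2 nA and 1 nA
  pass <- qc_series_resistance(sweeps, Rs_uncomp_MOhm = 3)
  expect_identical(as.logical(pass), c(FALSE, TRUE))   # 6 mV vs 3 mV
  expect_equal(attr(pass, "max_error_mV"), c(6, 3))
  expect_true(all(qc_series_resistance(sweeps, Rs_uncomp_MOhm = 0)))
})
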