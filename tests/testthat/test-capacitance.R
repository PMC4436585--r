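# independent forward oracle: admittance of the three-element circuit,
# written out from first principles (series Gs into parallel Gm, Cm)
oracle_Y <- function(Gs, Gm, Cm_pF, f_Hz) {
  w <- 2 * pi * f_Hz / 1000
  zm <- 1 / complex(real = Gm, imaginary = w * Cm_pF)   # membrane impedance
  1 / (1 / Gs + zm)
}

test_that("lock-in admittance estimation matches ideal one-element circuits", {
  # access resistance into a near-short membrane: a pure 100 MOhm resistor
  cell_r <- cell_params(Cm_pF = 1e-6, Rs_MOhm = 100, Rm_MOhm = 1e-4)
  rec <- simulate_sine_dc_recording(c(-50, 50), cell_r,
                                    gating_params(Qmax_pC = 0),
                                    noise_sd_pA = 0)
  yp <- estimate_admittance(rec$sweeps[[2]])
  expect_equal(yp$Y_real_nS, 10, tolerance = 1e-4)
  expect_equal(abs(yp$Y_imag_nS), 0, tolerance = 1e-3)
  # a synthetic pure capacitor: I = C dV/dt
  tm <- seq(0, 80 - 0.01, by = 0.01)
  A <- 10; w <- 2 * pi * 0.4
  i_cap <- 1e-2 * A * w * cos(w * tm) * 1000      # 10 pF in nS*mV units
  sweep <- list(V_dc_mV = 0, current_pA = c(rep(0, 100), i_cap), n_hold = 100)
  yc <- estimate_admittance(sweep, holding_mV = -60)
  expect_equal(yc$Y_real_nS, 0, tolerance = 1e-9)
  expect_equal(yc$Y_imag_nS, 2 * pi * 400 * 1e-11 * 1e9, tolerance = 1e-6)
})

test_that("noiseless sine-plus-DC sweeps reproduce the closed-form admittance", {
  cell <- cell_params(Cm_pF = 10, Rs_MOhm = 10, Rm_MOhm = 2000)
  rec <- simulate_sine_dc_recording(c(-50, 0, 50), cell,
                                    gating_params(Qmax_pC = 0),
                                    noise_sd_pA = 0)
  Y_true <- oracle_Y(100, 0.5, 10, 400)
  for (sw in rec$sweeps) {
    yp <- estimate_admittance(sw)
    expect_equal(yp$Y_real_nS, Re(Y_true), tolerance = 1e-6)
    expect_equal(yp$Y_imag_nS, Im(Y_true), tolerance = 1e-6)
  }
})

test_that("three-element inversion reproduces the worked admittance example", {
  # A = 1.2, B = 1.6, Gdc = 10/11 at omega = 1 correspond to
  # Gs = 10, Gm = 1, omega*Cm = 2 (verified by forward substitution)
  sol <- solve_three_element(list(Y_real_nS = 1.2, Y_imag_nS = 1.6,
                                  G_dc_nS = 10 / 11), omega = 1)
  expect_equal(sol$Gs_nS, 10, tolerance = 1e-12)
  expect_equal(sol$Gm_nS, 1, tolerance = 1e-12)
  expect_equal(sol$Cm_pF, 2, tolerance = 1e-12)
  Y_back <- oracle_Y(10, 1, 2, 1000 / (2 * pi))
  expect_equal(Re(Y_back), 1.2, tolerance = 1e-12)
  expect_equal(Im(Y_back), 1.6, tolerance = 1e-12)
})

test_that("forward-then-inverse circuit round trip is exact on a parameter grid", {
  f <- 400; w <- 2 * pi * f / 1000
  for (Gs in c(50, 100, 200, 400)) {
    for (Gm in c(0.2, 0.5, 1, 2)) {
      for (Cm in c(5, 10, 20, 40)) {
        Y <- oracle_Y(Gs, Gm, Cm, f)
        sol <- solve_three_element(list(Y_real_nS = Re(Y), Y_imag_nS = Im(Y),
                                        G_dc_nS = Gs * Gm / (Gs + Gm)), w)
        expect_equal(sol$Cm_pF, Cm, tolerance = 1e-9)
        expect_equal(sol$Gm_nS, Gm, tolerance = 1e-9)
        expect_equal(sol$Gs_nS, Gs, tolerance = 1e-9)
      }
    }
  }
})

test_that("degenerate admittance points are rejected as unphysical", {
  expect_error(solve_three_element(list(Y_real_nS = 1, Y_imag_nS = 0,
                                        G_dc_nS = 1), 1),
               "unphysical")
  expect_error(solve_three_element(list(Y_real_nS = 0.5, Y_imag_nS = 1,
                                        G_dc_nS = 1), 1),
               "unphysical")
})

test_that("non-linear capacitance isolates the Boltzmann-derivative bell", {
  pre <- clc5_preset("WT")
  # flat Cm(V) when no mobile charge
  rec0 <- simulate_sine_dc_recording(seq(-105, 195, 20), pre$cell,
                                     gating_params(Qmax_pC = 0),
                                     noise_sd_pA = 0)
  dc0 <- nonlinear_capacitance(capacitance_sweep(rec0))
  expect_lt(max(abs(dc0$dC_pF)), 1e-6)
  # with mobile charge: peak at V05 with amplitude beta*Qmax/4
  vgrid <- seq(-105, 245, 10)
  rec <- simulate_sine_dc_recording(vgrid, pre$cell, pre$gating,
                                    cap_V05_mV = 128, noise_sd_pA = 0)
  dc <- nonlinear_capacitance(capacitance_sweep(rec))
  v_peak <- dc$V_dc_mV[which.max(dc$dC_pF)]
  expect_lt(abs(v_peak - 128), 10 + 1e-9)        # within grid resolution
  beta <- 1 / thermal_mV()
  peak_expected <- 1000 * beta * 1 / 4           # pF, Qmax = 1 pC
  expect_equal(max(dc$dC_pF), peak_expected, tolerance = 0.01)
  expect_error(nonlinear_capacitance(
    capacitance_sweep(rec)[sort(vgrid) > -70, ]), ">= 3")
})

test_that("derivative-of-Boltzmann fits recover parameters and refuse rising flanks", {
  V <- seq(-105, 245, 10)
  y <- dboltzmann_c(V, 0.5, 128, 1)
  fit <- fit_dboltzmann_c(V, y)
  expect_false(fit$no_peak_in_range)
  expect_lt(abs(fit$Qmax_pC - 0.5) / 0.5, 0.001)
  expect_lt(abs(fit$V05_mV - 128) / 128, 0.001)
  expect_lt(abs(fit$z_delta - 1), 0.001)
  # truncated 40 mV below the generator V05: monotone rise, fit refused
  V2 <- seq(-105, 200, 10)
  y2 <- dboltzmann_c(V2, 0.5, 240, 1)
  fit2 <- fit_dboltzmann_c(V2, y2)
  expect_true(fit2$no_peak_in_range)
  # doubling z halves the bell width and doubles the fitted valence
  y3 <- dboltzmann_c(V, 0.5, 128, 2)
  fit3 <- fit_dboltzmann_c(V, y3)
  expect_equal(fit3$z_delta, 2, tolerance = 1e-3)
  hw <- function(yy) diff(range(V[yy > max(yy) / 2]))
  expect_lt(hw(y3), 0.6 * hw(y))
})

test_that("the integrated capacitance bell recovers the total gating charge", {
  # normalization of the Boltzmann derivative: integral over V equals Qmax
  beta <- 1 / thermal_mV()
  V <- seq(128 - 8 / beta, 128 + 8 / beta, length.out = 2000)
  y <- dboltzmann_c(V, 1.5, 128, 1) / 1000       # pC/mV
  q_int <- sum(y) * (V[2] - V[1])
  expect_gt(q_int, 0.99 * 1.5)
  expect_lt(q_int, 1.5 + 1e-6)
})

test_that("the end-to-end lock-in pipeline recovers generator gating parameters", {
  vgrid <- seq(-105, 245, 10)
  for (preset in list(c(128, 1), c(153, 1))) {
    g <- gating_params(Qmax_pC = 1, V05_mV = preset[1], z_delta = preset[2])
    rec <- simulate_sine_dc_recording(vgrid, cell_params(), g,
                                      noise_sd_pA = 0)
    dc <- nonlinear_capacitance(capacitance_sweep(rec))
    fit <- fit_dboltzmann_c(dc$V_dc_mV, dc$dC_pF)
    expect_lt(abs(fit$V05_mV - preset[1]) / preset[1], 0.001)
    expect_lt(abs(fit$Qmax_pC - 1), 0.001)
    expect_lt(abs(fit$z_delta - preset[2]), 0.001)
  }
})

test_that("shifting the generator V05 shifts the fitted V05 one to one", {
  vgrid <- seq(-105, 295, 10)
  fits <- sapply(c(120, 145), function(v05) {
    rec <- simulate_sine_dc_recording(vgrid, cell_params(),
                                      gating_params(Qmax_pC = 1,
                                                    V05_mV = v05),
                                      noise_sd_pA = 0)
    dc <- nonlinear_capacitance(capacitance_sweep(rec))
    fit_dboltzmann_c(dc$V_dc_mV, dc$dC_pF)$V05_mV
  })
  expect_equal(fits[2] - fits[1], 25, tolerance = 1)
})
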