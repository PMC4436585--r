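#' Lock-in admittance estimation from a sine-plus-DC sweep
#'
#' Projects the current of one DC level onto the in-phase and quadrature
#' components of the sine stimulus to obtain the complex admittance at the
#' stimulus frequency, and forms the DC conductance from the cycle-averaged
#' current relative to the holding segment. The first `settle_cycles` sine
#' cycles after the DC jump are discarded as settling.
#'
#' @param sweep one element of a `sine_dc_recording` (list with `time_ms`,
#'   `current_pA`, `command_mV`, `V_dc_mV`, `n_hold`).
#' @param sine_Hz,sine_amp_mV stimulus frequency (Hz) and amplitude (mV).
#' @param sampling_kHz sampling rate, kHz.
#' @param holding_mV holding potential of the pre-segment, mV.
#' @param settle_cycles cycles discarded before averaging (default 2).
#' @return object of class `admittance_point`: list with `V_dc_mV`,
#'   `Y_real_nS`, `Y_imag_nS`, `G_dc_nS`, `n_cycles` averaged.
#' @export
estimate_admittance <- function(sweep, sine_Hz = 400, sine_amp_mV = 10,
                                sampling_kHz = 100, holding_mV = -60,
                                settle_cycles = 2) {
  spc <- sampling_kHz * 1000 / sine_Hz
  if (abs(spc - round(spc)) > 1e-9)
    stop("sine period is not an integer number of samples")
  spc <- round(spc)
  n_hold <- sweep$n_hold
  i_sine <- sweep$current_pA[-seq_len(n_hold)]
  n_cyc_total <- length(i_sine) %/% spc
  if (n_cyc_total * spc != length(i_sine))
    stop("sweep does not contain an integer number of sine cycles")
  if (n_cyc_total - settle_cycles < 1)
    stop("no cycles left after discarding settling prefix")
  keep <- (settle_cycles * spc + 1):(n_cyc_total * spc)
  ii <- i_sine[keep]
  t_rel <- (keep - 1) / sampling_kHz
  omega <- 2 * pi * sine_Hz / 1000
  s <- sin(omega * t_rel); cph <- cos(omega * t_rel)
  n <- length(ii)
  Is <- 2 * sum(ii * s) / n       # in-phase current amplitude, pA
  Ic <- 2 * sum(ii * cph) / n     # quadrature current amplitude, pA
  i_dc <- mean(ii)
  i_hold <- mean(sweep$current_pA[seq_len(n_hold)])
  if (abs(sweep$V_dc_mV - holding_mV) < 1)
    stop("DC level coincides with the holding potential; G_dc undefined")
  g_dc <- (i_dc - i_hold) / (sweep$V_dc_mV - holding_mV)
  structure(list(V_dc_mV = sweep$V_dc_mV,
                 Y_real_nS = Is / sine_amp_mV,
                 Y_imag_nS = Ic / sine_amp_mV,
                 G_dc_nS = g_dc,
                 n_cycles = n_cyc_total - settle_cycles),
            class = "admittance_point")
}

#' Solve the three-element circuit from one admittance point
#'
#' Closed-form inversion of Y(omega) = Gs (Gm + j omega Cm)/(Gs + Gm +
#' j omega Cm) given additionally the DC conductance Gdc = Gs Gm/(Gs + Gm):
#' with A = Re(Y), B = Im(Y),
#' Gs = Gdc + ((A - Gdc)^2 + B^2)/(A - Gdc),
#' Cm = Gs^2 B / (omega ((Gs - A)^2 + B^2)),
#' Gm = Gdc Gs / (Gs - Gdc).
#'
#' @param Y an `admittance_point` (or list with `Y_real_nS`, `Y_imag_nS`,
#'   `G_dc_nS`).
#' @param omega angular frequency in rad/ms (2*pi*f_Hz/1000); with nS and pF
#'   these units are self-consistent.
#' @return list with `Cm_pF`, `Gm_nS`, `Gs_nS`.
#' @export
solve_three_element <- function(Y, omega) {
  A <- Y$Y_real_nS; B <- Y$Y_imag_nS; gdc <- Y$G_dc_nS
  if (!is.finite(A) || !is.finite(B) || !is.finite(gdc))
    stop("unphysical admittance: non-finite input")
  if (A <= gdc || B <= 0)
    stop("unphysical admittance: require Re(Y) > G_dc and Im(Y) > 0")
  Gs <- gdc + ((A - gdc)^2 + B^2) / (A - gdc)
  Cm <- Gs^2 * B / (omega * ((Gs - A)^2 + B^2))
  Gm <- gdc * Gs / (Gs - gdc)
  list(Cm_pF = Cm, Gm_nS = Gm, Gs_nS = Gs)
}

#' Run the lock-in analysis over all DC levels of a recording
#'
#' @param rec a `sine_dc_recording`.
#' @param settle_cycles cycles discarded as settling.
#' @return object of class `capacitance_sweep`: data.frame with columns
#'   `V_dc_mV`, `Cm_pF`, `Gm_nS`, `Gs_nS`, `G_dc_nS`; rows ordered by
#'   voltage. A warning attribute flags levels where Gs <= Gm.
#' @export
capacitance_sweep <- function(rec, settle_cycles = 2) {
  stopifnot(inherits(rec, "sine_dc_recording"))
  omega <- 2 * pi * rec$sine_Hz / 1000
  rows <- lapply(rec$sweeps, function(sw) {
    yp <- estimate_admittance(sw, sine_Hz = rec$sine_Hz,
                              sine_amp_mV = rec$sine_amp_mV,
                              sampling_kHz = rec$sampling_kHz,
                              holding_mV = rec$holding_mV,
                              settle_cycles = settle_cycles)
    sol <- solve_three_element(yp, omega)
    data.frame(V_dc_mV = sw$V_dc_mV, Cm_pF = sol$Cm_pF, Gm_nS = sol$Gm_nS,
               Gs_nS = sol$Gs_nS, G_dc_nS = yp$G_dc_nS)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$V_dc_mV), , drop = FALSE]
  if (any(out$Gs_nS <= out$Gm_nS))
    warning("access conductance does not dominate (Gs <= Gm) at some levels")
  class(out) <- c("capacitance_sweep", "data.frame")
  out
}

#' Non-linear capacitance by baseline removal
#'
#' Subtracts the linear membrane capacitance, estimated as the mean Cm over
#' a hyperpolarized baseline region where mobile gating charge is immobile,
#' leaving the voltage-dependent excess (bell-shaped for a two-state
#' voltage sensor).
#'
#' @param sweep a [capacitance_sweep()] (data.frame with `V_dc_mV`, `Cm_pF`).
#' @param baseline_max_mV upper edge of the baseline region (default -60 mV).
#' @return data.frame with `V_dc_mV` and `dC_pF`.
#' @export
nonlinear_capacitance <- function(sweep, baseline_max_mV = -60) {
  base <- sweep$V_dc_mV <= baseline_max_mV
  if (sum(base) < 3)
    stop("need >= 3 DC levels in the hyperpolarized baseline region")
  data.frame(V_dc_mV = sweep$V_dc_mV,
             dC_pF = sweep$Cm_pF - mean(sweep$Cm_pF[base]))
}

#' Fit the derivative-of-Boltzmann model to non-linear capacitance
#'
#' Least-squares fit of C(V) = beta Qmax exp(-beta (V - V05)) /
#' (1 + exp(-beta (V - V05)))^2 (+ optional constant offset), with
#' beta = z_delta e0/(kB T). When the capacitance maximum lies at the edge
#' of the sampled voltage range the bell peak is not contained in the data;
#' the fit is then refused and the `no_peak_in_range` flag returned, the
#' appropriate outcome for strongly right-shifted voltage sensors.
#'
#' @param V_mV DC voltages, mV.
#' @param dC_pF non-linear capacitance, pF.
#' @param offset fit a free additive offset (default TRUE; absorbs the
#'   residual Boltzmann tail left by finite-voltage baseline subtraction).
#' @param const a [phys_constants()].
#' @param edge_frac the peak is accepted only if the bell has decayed below
#'   `edge_frac` of its maximum at the depolarized end (default 0.97).
#' @return object of class `boltzmann_fit`: list with `Qmax_pC`, `V05_mV`,
#'   `z_delta`, standard errors, `residual_norm`, `no_peak_in_range` flag
#'   and the fitted values; when the flag is TRUE parameters are NA.
#' @export
fit_dboltzmann_c <- function(V_mV, dC_pF, offset = TRUE,
                             const = phys_constants(), edge_frac = 0.97) {
  stopifnot(length(V_mV) == length(dC_pF))
  if (length(V_mV) < 6) stop("need >= 6 points")
  ord <- order(V_mV); V <- V_mV[ord]; y <- dC_pF[ord]
  imax <- which.max(y)
  if (imax == 1L || imax == length(y) || y[length(y)] > edge_frac * y[imax]) {
    return(structure(list(Qmax_pC = NA_real_, V05_mV = NA_real_,
                          z_delta = NA_real_, se = c(Qmax_pC = NA, V05_mV = NA,
                                                     z_delta = NA),
                          residual_norm = NA_real_, no_peak_in_range = TRUE),
                     class = "boltzmann_fit"))
  }
  kT <- thermal_mV(const)
  v05_0 <- V[imax]
  z0 <- 1
  qmax_0 <- 4 * max(y) * kT / z0 / 1000            # invert peak = beta*Qmax/4
  df <- data.frame(V = V, y = y)
  form <- if (offset)
    y ~ 1000 * (z / kT) * Qmax * exp(-(z / kT) * (V - V05)) /
      (1 + exp(-(z / kT) * (V - V05)))^2 + c0
  else
    y ~ 1000 * (z / kT) * Qmax * exp(-(z / kT) * (V - V05)) /
      (1 + exp(-(z / kT) * (V - V05)))^2
  start <- list(Qmax = qmax_0, V05 = v05_0, z = z0)
  if (offset) start$c0 <- 0
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("derivative-of-Boltzmann fit failed: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  structure(list(Qmax_pC = unname(cf["Qmax"]), V05_mV = unname(cf["V05"]),
                 z_delta = unname(cf["z"]),
                 se = c(Qmax_pC = unname(se["Qmax"]),
                        V05_mV = unname(se["V05"]),
                        z_delta = unname(se["z"])),
                 offset_pF = if (offset) unname(cf["c0"]) else 0,
                 residual_norm = sqrt(sum(residuals(fit)^2)),
                 fitted = fitted(fit), no_peak_in_range = FALSE),
            class = "boltzmann_fit")
}
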