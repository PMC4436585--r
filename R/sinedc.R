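#' Closed-form admittance of the three-element cell circuit
#'
#' Y(omega) = Gs (Gm + j omega Cm) / (Gs + Gm + j omega Cm): access
#' conductance Gs in series with the parallel combination of membrane
#' conductance Gm and membrane capacitance Cm.
#'
#' @param Gs_nS,Gm_nS conductances, nS.
#' @param Cm_pF membrane capacitance, pF.
#' @param f_Hz stimulus frequency, Hz.
#' @return complex admittance in nS.
#' @export
three_element_admittance <- function(Gs_nS, Gm_nS, Cm_pF, f_Hz) {
  omega <- 2 * pi * f_Hz / 1000                     # rad/ms; pF*rad/ms = nS
  jwc <- complex(imaginary = omega * Cm_pF)
  Gs_nS * (Gm_nS + jwc) / (Gs_nS + Gm_nS + jwc)
}

#' Simulate sine-plus-DC lock-in capacitance sweeps
#'
#' For each DC level a command of V(t) = Vdc + A sin(2 pi f t) is applied
#' after a short holding segment, and the current response of the
#' three-element circuit (Gs in series with Gm parallel Cm(V)) is computed
#' from the exact linear solution, including the exponential settling
#' transient after the DC jump. The membrane capacitance is voltage
#' dependent, Cm(V) = Cm + Cnl(V), with the non-linear part given by the
#' derivative-of-Boltzmann relation of the mobile gating charge
#' ([dboltzmann_c()]), evaluated quasi-statically at the DC potential.
#'
#' @param vdc_levels_mV DC step voltages, mV.
#' @param cell a [cell_params()]; Gs = 1000/Rs_MOhm nS, Gm = 1000/Rm_MOhm nS.
#' @param gating a [gating_params()]; the non-linear capacitance source.
#'   Use `Qmax_pC = 0` for a purely passive cell.
#' @param cap_V05_mV half-activation voltage of the capacitance bell; default
#'   the gating `V05_mV` (capacitance and charge fits may differ, so it is
#'   exposed separately).
#' @param sine_amp_mV,sine_Hz sine amplitude (mV) and frequency (Hz).
#' @param n_cycles integer number of sine cycles per DC level (>= 8).
#' @param holding_mV holding potential preceding each DC step, mV.
#' @param holding_ms duration of the holding segment, ms.
#' @param sampling_kHz sampling rate; the sine period must be an integer
#'   number of samples, else an error is raised.
#' @param noise_sd_pA additive Gaussian current noise, pA.
#' @param seed RNG seed; required when `noise_sd_pA > 0`.
#' @return object of class `sine_dc_recording`: list of per-level sweeps
#'   (`time_ms`, `command_mV`, `current_pA`), plus stimulus metadata and a
#'   `truth` sidecar with the generator's Gs, Gm, Cm(V) per level.
#' @export
simulate_sine_dc_recording <- function(vdc_levels_mV, cell, gating,
                                       cap_V05_mV = gating$V05_mV,
                                       sine_amp_mV = 10, sine_Hz = 400,
                                       n_cycles = 32, holding_mV = -60,
                                       holding_ms = 5, sampling_kHz = 100,
                                       noise_sd_pA = 0, seed = NULL) {
  stopifnot(inherits(cell, "cell_params"), inherits(gating, "gating_params"))
  if (n_cycles < 8 || n_cycles != round(n_cycles))
    stop("n_cycles must be an integer >= 8")
  samples_per_cycle <- sampling_kHz * 1000 / sine_Hz
  if (abs(samples_per_cycle - round(samples_per_cycle)) > 1e-9)
    stop("sine period is not an integer number of samples")
  if (samples_per_cycle < 20) stop("need >= 20 samples per sine cycle")
  if (noise_sd_pA > 0 && is.null(seed))
    stop("seed required when noise_sd_pA > 0")
  if (!is.null(seed)) set.seed(seed)

  spc <- round(samples_per_cycle)
  dt <- 1 / sampling_kHz
  n_hold <- round(holding_ms * sampling_kHz)
  n_sine <- spc * n_cycles
  Gs <- 1000 / cell$Rs_MOhm
  Gm <- 1000 / cell$Rm_MOhm
  omega <- 2 * pi * sine_Hz / 1000                  # rad/ms
  gdc_circ <- Gs * Gm / (Gs + Gm)

  cm_of_v <- function(v)
    cell$Cm_pF + dboltzmann_c(v, gating$Qmax_pC, cap_V05_mV, gating$z_delta)

  sweeps <- vector("list", length(vdc_levels_mV))
  truth_cm <- numeric(length(vdc_levels_mV))
  for (k in seq_along(vdc_levels_mV)) {
    vdc <- vdc_levels_mV[k]
    cm <- cm_of_v(vdc)
    truth_cm[k] <- cm
    tau <- cm / (Gs + Gm)                           # pF/nS = ms
    t_sine <- (seq_len(n_sine) - 1) * dt
    vcmd_sine <- vdc + sine_amp_mV * sin(omega * t_sine)

    # exact linear response: membrane-voltage phasor for the sine drive,
    # steady DC part, and the settling exponential from the DC jump
    H <- Gs / complex(real = Gs + Gm, imaginary = omega * cm)  # Vm/Vc
    vm_dc_ss <- vdc * Gs / (Gs + Gm)
    vm_hold <- holding_mV * Gs / (Gs + Gm)
    # initial condition: Vm continuous at the DC jump (sine starts at phase 0,
    # whose steady-state membrane contribution at t = 0 is A*Im(H))
    K <- vm_hold - vm_dc_ss - sine_amp_mV * Im(H)
    vm <- vm_dc_ss +
      sine_amp_mV * (Re(H) * sin(omega * t_sine) +
                       Im(H) * cos(omega * t_sine)) +
      K * exp(-t_sine / tau)
    i_sine <- Gs * (vcmd_sine - vm) * 1  # nS*mV = pA
    i_hold <- rep(gdc_circ * holding_mV, n_hold)
    cur <- c(i_hold, i_sine)
    if (noise_sd_pA > 0) cur <- cur + rnorm(length(cur), sd = noise_sd_pA)
    tm <- (seq_along(cur) - 1) * dt
    sweeps[[k]] <- list(V_dc_mV = vdc, time_ms = tm,
                        command_mV = c(rep(holding_mV, n_hold), vcmd_sine),
                        current_pA = cur, n_hold = n_hold)
  }
  structure(list(sweeps = sweeps, vdc_levels_mV = vdc_levels_mV,
                 sine_amp_mV = sine_amp_mV, sine_Hz = sine_Hz,
                 n_cycles = n_cycles, sampling_kHz = sampling_kHz,
                 holding_mV = holding_mV,
                 truth = list(Gs_nS = Gs, Gm_nS = Gm, Cm_pF = truth_cm,
                              gating = gating, cap_V05_mV = cap_V05_mV)),
            class = "sine_dc_recording")
}
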