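#' Voltage-step protocol
#'
#' Describes a whole-cell voltage-clamp step protocol: a holding segment,
#' a pre-step epoch, one step epoch per listed level, and a tail epoch at a
#' fixed tail voltage. Sampling must satisfy Nyquist with respect to the
#' acquisition filter corner.
#'
#' @param holding_mV holding potential, mV.
#' @param levels_mV strictly increasing step voltages, mV.
#' @param pre_ms,step_ms,tail_ms epoch durations, ms (all > 0).
#' @param tail_mV tail (repolarization) voltage, mV.
#' @param sampling_kHz sampling rate, kHz.
#' @param filter_kHz low-pass corner frequency, kHz.
#' @return object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(holding_mV, levels_mV, pre_ms, step_ms, tail_ms,
                             tail_mV = holding_mV, sampling_kHz = 100,
                             filter_kHz = 3) {
  if (!all(is.finite(c(holding_mV, levels_mV, pre_ms, step_ms, tail_ms,
                       tail_mV, sampling_kHz, filter_kHz))))
    stop("invalid protocol: non-finite field")
  if (pre_ms <= 0 || step_ms <= 0 || tail_ms <= 0)
    stop("invalid protocol: all durations must be positive")
  if (sampling_kHz <= 0 || filter_kHz <= 0)
    stop("invalid protocol: rates must be positive")
  if (sampling_kHz <= 2 * filter_kHz)
    stop("invalid protocol: sampling_kHz must exceed 2*filter_kHz")
  if (length(levels_mV) > 1 && any(diff(levels_mV) <= 0))
    stop("invalid protocol: levels must be strictly increasing")
  structure(list(holding_mV = holding_mV, levels_mV = levels_mV,
                 pre_ms = pre_ms, step_ms = step_ms, tail_ms = tail_ms,
                 tail_mV = tail_mV, sampling_kHz = sampling_kHz,
                 filter_kHz = filter_kHz),
            class = "voltage_protocol")
}

#' Build an arithmetic voltage-step protocol
#'
#' Levels form an arithmetic sequence from `v_start_mV` to `v_end_mV`
#' inclusive. `dv_mV` is the nominal increment: the number of steps is
#' `round((v_end - v_start)/dv)` and the actual increment is adjusted so
#' both endpoints are always included, as step generators in acquisition
#' software do.
#'
#' @param holding_mV holding potential, mV.
#' @param v_start_mV,v_end_mV first and last step voltage, mV.
#' @param dv_mV voltage increment, mV (> 0).
#' @param pre_ms,step_ms,tail_ms epoch durations, ms.
#' @param sampling_kHz sampling rate, kHz.
#' @param tail_mV tail voltage (default: holding).
#' @param filter_kHz filter corner, kHz.
#' @return a [voltage_protocol()].
#' @examples
#' p <- make_step_protocol(-60, -115, 175, 20, 20, 100, 50, 100)
#' length(p$levels_mV)  # 15
#' @export
make_step_protocol <- function(holding_mV, v_start_mV, v_end_mV, dv_mV,
                               pre_ms, step_ms, tail_ms, sampling_kHz = 100,
                               tail_mV = holding_mV, filter_kHz = 3) {
  if (dv_mV <= 0) stop("invalid protocol: dv_mV must be positive")
  if (v_end_mV < v_start_mV) stop("invalid protocol: v_end < v_start")
  n_steps <- max(1, round((v_end_mV - v_start_mV) / dv_mV))
  levels <- if (v_end_mV == v_start_mV) v_start_mV
            else seq(v_start_mV, v_end_mV, length.out = n_steps + 1)
  voltage_protocol(holding_mV, levels, pre_ms, step_ms, tail_ms,
                   tail_mV = tail_mV, sampling_kHz = sampling_kHz,
                   filter_kHz = filter_kHz)
}

#' Sample-exact command waveform of one protocol level
#'
#' @param protocol a [voltage_protocol()].
#' @param level_mV one of the protocol's step voltages.
#' @return data.frame with `time_ms` and `command_mV`; the first sample is
#'   at t = 0 at the start of the pre epoch.
#' @export
protocol_waveform <- function(protocol, level_mV) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  if (!any(abs(protocol$levels_mV - level_mV) < 1e-9))
    stop("level not in protocol")
  dt <- 1 / protocol$sampling_kHz
  n_pre  <- round(protocol$pre_ms  * protocol$sampling_kHz)
  n_step <- round(protocol$step_ms * protocol$sampling_kHz)
  n_tail <- round(protocol$tail_ms * protocol$sampling_kHz)
  v <- c(rep(protocol$holding_mV, n_pre), rep(level_mV, n_step),
         rep(protocol$tail_mV, n_tail))
  data.frame(time_ms = (seq_along(v) - 1) * dt, command_mV = v)
}

#' Passive cell parameters
#'
#' @param Cm_pF linear membrane capacitance, pF.
#' @param Rs_MOhm series (access) resistance, MOhm.
#' @param Rm_MOhm membrane resistance, MOhm.
#' @param Rs_comp_frac fraction of Rs electronically compensated, in [0, 1).
#' @return object of class `cell_params`.
#' @export
cell_params <- function(Cm_pF = 10, Rs_MOhm = 3, Rm_MOhm = 1000,
                        Rs_comp_frac = 0) {
  stopifnot(Cm_pF > 0, Rs_MOhm > 0, Rm_MOhm > 0,
            Rs_comp_frac >= 0, Rs_comp_frac < 1)
  structure(list(Cm_pF = Cm_pF, Rs_MOhm = Rs_MOhm, Rm_MOhm = Rm_MOhm,
                 Rs_comp_frac = Rs_comp_frac), class = "cell_params")
}

#' Phenomenological gating-charge parameters
#'
#' Two-state Boltzmann description of intramembrane charge movement:
#' steady-state charge Qss(V) = Qmax/(1 + exp(-beta (V - V05))) relaxing
#' first-order with time constant `tau0_ms`.
#'
#' @param Qmax_pC saturating mobile charge, pC (>= 0).
#' @param V05_mV half-activation voltage, mV.
#' @param z_delta effective valence (> 0).
#' @param tau0_ms relaxation time constant, ms (> 0).
#' @return object of class `gating_params`.
#' @export
gating_params <- function(Qmax_pC = 1, V05_mV = 132, z_delta = 1,
                          tau0_ms = 0.5) {
  stopifnot(Qmax_pC >= 0, z_delta > 0, tau0_ms > 0)
  structure(list(Qmax_pC = Qmax_pC, V05_mV = V05_mV, z_delta = z_delta,
                 tau0_ms = tau0_ms), class = "gating_params")
}

#' Phenomenological transport-current parameters
#'
#' Steady-state transport current It(V) = Gmax * Popen(V) * (V - Erev) with
#' Popen a Boltzmann sharing the activation voltage dependence of the gating
#' charge; strongly depolarized V05 yields the outwardly rectifying currents
#' characteristic of plasma-membrane CLC exchangers.
#'
#' @param Gmax_nS limiting chord conductance, nS (>= 0).
#' @param V05_mV,z_delta Boltzmann activation of the open probability.
#' @param Erev_mV reversal voltage, mV.
#' @return object of class `transport_params`.
#' @export
transport_params <- function(Gmax_nS = 20, V05_mV = 132, z_delta = 1,
                             Erev_mV = 0) {
  stopifnot(Gmax_nS >= 0, z_delta > 0)
  structure(list(Gmax_nS = Gmax_nS, V05_mV = V05_mV, z_delta = z_delta,
                 Erev_mV = Erev_mV), class = "transport_params")
}

#' Canonical generator presets for WT and Dent's-disease mutant ClC-5
#'
#' Phenomenological parameter sets emulating WT ClC-5 and the mutants G212A
#' and E267A. Half-activation voltages follow the published fits
#' (capacitance: 128 mV WT, 153 mV E267A; gating charge: 132 mV WT,
#' 240 mV G212A); effective valences and absolute Qmax/Gmax scales are
#' package presets chosen to reproduce the qualitative phenotypes: G212A
#' strongly right-shifted activation, E267A roughly tenfold-reduced
#' transport current at +165 mV with enlarged gating charge, hence
#' Q/I ordering E267A > WT > G212A.
#'
#' @param construct one of "WT", "G212A", "E267A".
#' @return list with elements `gating` ([gating_params()]), `transport`
#'   ([transport_params()]), `cap_V05_mV` (half-activation used for the
#'   non-linear-capacitance forward model) and `cell` ([cell_params()]).
#' @export
clc5_preset <- function(construct = c("WT", "G212A", "E267A")) {
  construct <- match.arg(construct)
  p <- switch(construct,
    WT    = list(Qmax = 1.0, V05_q = 132, V05_c = 128, z = 1.0,  Gmax = 20),
    G212A = list(Qmax = 0.6, V05_q = 240, V05_c = 240, z = 0.7,  Gmax = 15),
    E267A = list(Qmax = 2.0, V05_q = 153, V05_c = 153, z = 1.0,  Gmax = 2.5))
  list(construct = construct,
       gating = gating_params(Qmax_pC = p$Qmax, V05_mV = p$V05_q,
                              z_delta = p$z, tau0_ms = 0.5),
       transport = transport_params(Gmax_nS = p$Gmax, V05_mV = p$V05_q,
                                    z_delta = p$z, Erev_mV = 0),
       cap_V05_mV = p$V05_c,
       cell = cell_params())
}
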