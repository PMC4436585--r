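#' Four-pole Bessel-type low-pass filter
#'
#' Digital IIR approximation of the 4th-order analog Bessel low-pass used by
#' patch-clamp amplifiers, designed by bilinear transform (with frequency
#' prewarping) of the standard -3 dB-normalized analog poles. DC gain is
#' exactly 1, so time integrals of long transients are preserved.
#'
#' @param x numeric signal.
#' @param corner_kHz -3 dB corner frequency, kHz.
#' @param sampling_kHz sampling rate, kHz.
#' @return filtered signal, same length as `x`.
#' @export
bessel4_lowpass <- function(x, corner_kHz, sampling_kHz) {
  stopifnot(corner_kHz > 0, sampling_kHz > 2 * corner_kHz)
  # normalized (-3 dB at 1 rad/s) analog Bessel poles, order 4
  p0 <- c(complex(real = -0.6572111716718827, imaginary =  0.8301614350048733),
          complex(real = -0.6572111716718827, imaginary = -0.8301614350048733),
          complex(real = -0.9047587967882449, imaginary =  0.2709187330038746),
          complex(real = -0.9047587967882449, imaginary = -0.2709187330038746))
  Ts <- 1 / sampling_kHz
  wc <- 2 / Ts * tan(pi * corner_kHz * Ts)     # prewarped corner, rad/ms
  p <- p0 * wc
  zp <- (1 + p * Ts / 2) / (1 - p * Ts / 2)    # bilinear pole map
  a <- Re(poly_from_roots(zp))
  b <- c(1, 4, 6, 4, 1)                        # zeros at z = -1 (order 4)
  b <- b * sum(a) / sum(b)                     # unit DC gain
  # start from the steady state of the first sample so constant prefixes
  # pass unchanged (no warm-up transient at the start of a sweep)
  x0 <- x[1]
  as.numeric(signal::filter(signal::Arma(b = b, a = a), x - x0)) + x0
}

#' Group delay of the acquisition low-pass filter
#'
#' Area-equivalent delay of the filtered unit step (integral of 1 minus the
#' step response), in ms. Analysis windows that straddle a command edge are
#' shifted by this delay so that the filtered edge of any settled current
#' step integrates to zero excess.
#'
#' @param corner_kHz,sampling_kHz filter corner and sampling rate, kHz.
#' @return delay in ms.
#' @export
bessel4_group_delay <- function(corner_kHz, sampling_kHz) {
  n <- ceiling(5 * sampling_kHz / corner_kHz)
  st <- bessel4_lowpass(c(rep(0, 10), rep(1, n)), corner_kHz, sampling_kHz)
  sum(1 - st[-seq_len(10)]) / sampling_kHz
}

# monic polynomial coefficients from roots (descending powers)
poly_from_roots <- function(r) {
  coef <- 1
  for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
  coef
}

# time course of mobile gating charge (pC) along a command waveform:
# first-order relaxation of Q toward Qss(V) with time constant tau0
gating_charge_timecourse <- function(command_mV, dt_ms, gating, q0_pC,
                                     const = phys_constants()) {
  qss <- boltzmann_q(command_mV, gating$Qmax_pC, gating$V05_mV,
                     gating$z_delta, const)
  a <- exp(-dt_ms / gating$tau0_ms)
  n <- length(command_mV)
  q <- numeric(n)
  q_prev <- q0_pC
  for (i in seq_len(n)) {
    q_prev <- qss[i] + (q_prev - qss[i]) * a
    q[i] <- q_prev
  }
  q
}

#' Simulate a voltage-clamp trace family
#'
#' Forward model for whole-cell current families of a voltage-gated
#' transporter: each sweep is the sum of (i) the capacitive charging
#' transient of the passive cell (series resistance into the linear membrane
#' capacitance, compensation reducing the effective access resistance),
#' (ii) ohmic leak V/Rm, (iii) the gating current Ig = dQ/dt with the mobile
#' charge Q relaxing first-order toward the Boltzmann steady state, and
#' (iv) the steady-state transport current Gmax*Popen(V)*(V-Erev). The sum
#' is low-pass filtered at the protocol's corner frequency and Gaussian
#' current noise is added.
#'
#' @param protocol a [voltage_protocol()].
#' @param cell a [cell_params()].
#' @param gating a [gating_params()].
#' @param transport a [transport_params()].
#' @param noise_sd_pA standard deviation of additive current noise, pA.
#' @param seed integer RNG seed; required whenever `noise_sd_pA > 0`
#'   (reproducibility contract).
#' @param filter logical; apply the acquisition low-pass (default TRUE).
#' @return object of class `trace_family`: list with `protocol`, `time_ms`,
#'   `sweeps` (samples x levels matrix, pA), `meta`, and a `truth` sidecar
#'   holding the noiseless component decomposition per sweep
#'   (`Ig`, `It`, `Ileak`, `Icap` matrices) and the generator parameters.
#' @export
simulate_trace_family <- function(protocol, cell, gating, transport,
                                  noise_sd_pA = 5, seed = NULL,
                                  filter = TRUE) {
  stopifnot(inherits(protocol, "voltage_protocol"),
            inherits(cell, "cell_params"),
            inherits(gating, "gating_params"),
            inherits(transport, "transport_params"))
  if (noise_sd_pA > 0 && is.null(seed))
    stop("seed required when noise_sd_pA > 0")
  if (!is.null(seed)) set.seed(seed)

  dt <- 1 / protocol$sampling_kHz
  const <- phys_constants()
  rs_eff_MOhm <- cell$Rs_MOhm * (1 - cell$Rs_comp_frac)
  tau_cap <- cell$Cm_pF * rs_eff_MOhm * 1e-3      # pF * MOhm = us -> ms
  gleak_nS <- 1000 / cell$Rm_MOhm

  wf0 <- protocol_waveform(protocol, protocol$levels_mV[1])
  n <- nrow(wf0)
  nlev <- length(protocol$levels_mV)
  sweeps <- Ig <- It <- Ileak <- Icap <- matrix(0, n, nlev)
  q0 <- boltzmann_q(protocol$holding_mV, gating$Qmax_pC, gating$V05_mV,
                    gating$z_delta, const)

  for (k in seq_len(nlev)) {
    v <- protocol_waveform(protocol, protocol$levels_mV[k])$command_mV
    # capacitive transient: exponential relaxation at each command jump
    icap <- numeric(n)
    jumps <- which(diff(v) != 0)
    t_idx <- seq_len(n)
    for (j in jumps) {
      dv <- v[j + 1] - v[j]
      tt <- (t_idx - (j + 1)) * dt
      on <- t_idx > j
      icap[on] <- icap[on] +
        (dv / rs_eff_MOhm) * 1000 * exp(-tt[on] / tau_cap)  # mV/MOhm = nA -> pA
    }
    ileak <- v * gleak_nS
    q <- gating_charge_timecourse(v, dt, gating, q0, const)
    ig <- c(0, diff(q)) / dt * 1000               # pC/ms = nA -> pA
    popen <- 1 / (1 + exp(-boltzmann_beta(transport$z_delta, const) *
                            (v - transport$V05_mV)))
    it <- transport$Gmax_nS * popen * (v - transport$Erev_mV)
    total <- icap + ileak + ig + it
    if (filter) total <- bessel4_lowpass(total, protocol$filter_kHz,
                                         protocol$sampling_kHz)
    if (noise_sd_pA > 0) total <- total + rnorm(n, sd = noise_sd_pA)
    sweeps[, k] <- total
    Ig[, k] <- ig; It[, k] <- it; Ileak[, k] <- ileak; Icap[, k] <- icap
  }
  structure(list(protocol = protocol, time_ms = wf0$time_ms, sweeps = sweeps,
                 meta = list(cell = cell, noise_sd_pA = noise_sd_pA,
                             seed = seed, filtered = filter),
                 truth = list(gating = gating, transport = transport,
                              Ig = Ig, It = It, Ileak = Ileak, Icap = Icap)),
            class = "trace_family")
}

#' Simulate a trace family with on-line P/4 leak subtraction
#'
#' Simulates the main trace family plus, for every level, n quarter-
#' amplitude leak pulses from the leak holding potential, and applies
#' [p4_leak_subtract()] sweep by sweep. The returned sweeps are baseline-
#' referenced currents with linear leak and capacitive components removed,
#' as delivered by an amplifier's P/4 protocol; non-linear gating and
#' transport components survive.
#'
#' @inheritParams simulate_trace_family
#' @param n number of leak sub-pulses (default 4).
#' @param leak_holding_mV leak-pulse holding potential (default -60 mV).
#' @return a `trace_family` whose `sweeps` are leak-subtracted; `truth`
#'   carries the generator decomposition of the main family.
#' @export
simulate_p4_corrected_family <- function(protocol, cell, gating, transport,
                                         noise_sd_pA = 5, seed = NULL,
                                         n = 4, leak_holding_mV = -60,
                                         filter = TRUE) {
  fam <- simulate_trace_family(protocol, cell, gating, transport,
                               noise_sd_pA = noise_sd_pA, seed = seed,
                               filter = filter)
  n_pre <- round(protocol$pre_ms * protocol$sampling_kHz)
  baseline_idx <- seq(max(1, floor(n_pre / 2)), n_pre)
  for (k in seq_along(protocol$levels_mV)) {
    leak <- simulate_p4_leak_family(protocol, protocol$levels_mV[k], cell,
                                    gating, transport, n = n,
                                    leak_holding_mV = leak_holding_mV,
                                    noise_sd_pA = noise_sd_pA, filter = filter,
                                    seed = if (is.null(seed)) NULL
                                           else seed + 1000L * k)
    fam$sweeps[, k] <- p4_leak_subtract(fam$sweeps[, k], leak$sweeps,
                                        n = leak$meta$scale,
                                        baseline_idx = baseline_idx)
  }
  fam$meta$p4 <- list(n = n, leak_holding_mV = leak_holding_mV)
  fam
}

#' Simulate the P/4 leak-pulse family for a protocol level
#'
#' Generates `n` sub-pulses, each 1/n of the main step amplitude, delivered
#' from the leak holding potential with the same epoch timing as the main
#' protocol. Only the passive (linear) cell responds at these small
#' excursions in proportion to amplitude; gating and transport components
#' are simulated faithfully and are negligible when activation sits at
#' depolarized voltages.
#'
#' @param protocol main-protocol [voltage_protocol()].
#' @param level_mV main step voltage the leak pulses scale down.
#' @param cell,gating,transport generator parameter objects.
#' @param n number of sub-pulses (default 4).
#' @param leak_holding_mV holding potential for the leak protocol, mV.
#' @param polarity `"inverted"` (default) delivers the sub-pulses with
#'   opposite sign (hyperpolarizing for depolarizing main steps), keeping
#'   the voltage sensor immobile during the leak protocol; `"same"` uses
#'   1/n-amplitude replicas of the main step.
#' @param noise_sd_pA,seed as in [simulate_trace_family()].
#' @param filter apply the acquisition low-pass.
#' @return `trace_family` with `n` sweeps (one per sub-pulse); attribute
#'   `scale` is the signed factor (+n or -n) to use in
#'   [p4_leak_subtract()].
#' @export
simulate_p4_leak_family <- function(protocol, level_mV, cell, gating,
                                    transport, n = 4, leak_holding_mV = -60,
                                    polarity = c("inverted", "same"),
                                    noise_sd_pA = 0, seed = NULL,
                                    filter = TRUE) {
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "inverted") -1 else 1
  dv <- sgn * (level_mV - leak_holding_mV) / n
  leak_level <- leak_holding_mV + dv
  leak_proto <- voltage_protocol(leak_holding_mV, leak_level,
                                 protocol$pre_ms, protocol$step_ms,
                                 protocol$tail_ms,
                                 tail_mV = leak_holding_mV,
                                 sampling_kHz = protocol$sampling_kHz,
                                 filter_kHz = protocol$filter_kHz)
  fams <- lapply(seq_len(n), function(i)
    simulate_trace_family(leak_proto, cell, gating, transport,
                          noise_sd_pA = noise_sd_pA, filter = filter,
                          seed = if (is.null(seed)) NULL else seed + i))
  sweeps <- do.call(cbind, lapply(fams, function(f) f$sweeps[, 1]))
  structure(list(protocol = leak_proto, time_ms = fams[[1]]$time_ms,
                 sweeps = sweeps,
                 meta = list(cell = cell, n = n, scale = sgn * n,
                             leak_holding_mV = leak_holding_mV),
                 truth = fams[[1]]$truth),
            class = "trace_family")
}
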