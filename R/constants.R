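#' Physical constants for Boltzmann voltage-dependence analysis
#'
#' Bundle of the elementary charge, Boltzmann constant and absolute
#' temperature entering the steepness factor beta = z*delta*e0/(kB*T) of
#' two-state Boltzmann charge movement. The default temperature of 296 K
#' corresponds to room-temperature recordings (22-24 degrees C), at which
#' the thermal voltage kB*T/e0 is about 25.5 mV.
#'
#' @param T_K absolute temperature in kelvin.
#' @return a list with fields `e0` (C), `kB` (J/K) and `T` (K), of class
#'   `phys_constants`.
#' @export
phys_constants <- function(T_K = 296) {
  stopifnot(is.numeric(T_K), length(T_K) == 1L, T_K > 0)
  structure(list(e0 = 1.602176634e-19, kB = 1.380649e-23, T = T_K),
            class = "phys_constants")
}

#' Thermal voltage kB*T/e0 in millivolts
#'
#' @param const a [phys_constants()] object.
#' @return thermal voltage in mV (about 25.51 mV at 296 K).
#' @export
thermal_mV <- function(const = phys_constants()) {
  1000 * const$kB * const$T / const$e0
}

#' Boltzmann steepness beta (1/mV) for an effective valence
#'
#' beta = z*delta * e0 / (kB*T), expressed per millivolt so that products
#' beta * V with V in mV are dimensionless.
#'
#' @param z_delta effective valence (elementary charges times membrane-field
#'   fraction traversed).
#' @param const a [phys_constants()] object.
#' @return beta in 1/mV.
#' @export
boltzmann_beta <- function(z_delta, const = phys_constants()) {
  stopifnot(all(z_delta > 0))
  z_delta / thermal_mV(const)
}

#' Two-state Boltzmann charge-voltage relation
#'
#' Q(V) = Qmax / (1 + exp(-beta (V - V05))) with beta = z*e0/(kB*T).
#'
#' @param V_mV membrane potential(s), mV.
#' @param Qmax_pC saturating mobile charge, pC.
#' @param V05_mV half-activation voltage, mV.
#' @param z_delta effective valence.
#' @param const a [phys_constants()] object.
#' @return charge in pC, same length as `V_mV`.
#' @export
boltzmann_q <- function(V_mV, Qmax_pC, V05_mV, z_delta,
                        const = phys_constants()) {
  beta <- boltzmann_beta(z_delta, const)
  Qmax_pC / (1 + exp(-beta * (V_mV - V05_mV)))
}

#' Derivative-of-Boltzmann non-linear capacitance
#'
#' C(V) = beta * Qmax * u / (1 + u)^2 with u = exp(-beta (V - V05)):
#' the bell-shaped excess capacitance contributed by mobile gating charge,
#' peaking at V05 with amplitude beta*Qmax/4. With Qmax in pC and beta in
#' 1/mV the natural unit is pC/mV = nF; the return value is converted to pF.
#'
#' @inheritParams boltzmann_q
#' @return capacitance in pF, same length as `V_mV`.
#' @export
dboltzmann_c <- function(V_mV, Qmax_pC, V05_mV, z_delta,
                         const = phys_constants()) {
  beta <- boltzmann_beta(z_delta, const)
  u <- exp(-beta * (V_mV - V05_mV))
  1000 * beta * Qmax_pC * u / (1 + u)^2
}
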