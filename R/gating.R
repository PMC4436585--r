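#' P/4 leak subtraction
#'
#' Removes linear leak and capacitive components from a sweep using n
#' quarter-amplitude (1/n) leak pulses: each sweep is referenced to its own
#' pre-step baseline, the averaged leak response is scaled by n and
#' subtracted. For a purely passive (linear) cell the corrected sweep is
#' exactly zero (noiseless); non-linear components such as gating currents
#' survive the subtraction.
#'
#' @param main_sweep numeric current sweep, pA.
#' @param leak_sweeps matrix (samples x n) of leak-pulse responses, pA, on
#'   the same time base as `main_sweep`.
#' @param n signed sub-pulse scaling factor (default `ncol(leak_sweeps)`;
#'   negative for inverted-polarity leak pulses).
#' @param baseline_idx sample indices of the pre-step epoch used as baseline
#'   (default: the final half of the samples before the first command jump
#'   cannot be inferred from currents alone, so the caller passes it;
#'   required).
#' @return corrected sweep, pA (baseline-referenced).
#' @export
p4_leak_subtract <- function(main_sweep, leak_sweeps, n = ncol(leak_sweeps),
                             baseline_idx) {
  leak_sweeps <- as.matrix(leak_sweeps)
  if (nrow(leak_sweeps) != length(main_sweep))
    stop("mismatched time bases between main sweep and leak sweeps")
  if (missing(baseline_idx)) stop("baseline_idx is required")
  b_main <- mean(main_sweep[baseline_idx])
  leak_avg <- rowMeans(leak_sweeps)
  b_leak <- mean(leak_avg[baseline_idx])
  (main_sweep - b_main) - n * (leak_avg - b_leak)
}

#' Integrate off-gating charge in a tail window
#'
#' Q_off = |sum (I - baseline) * dt| over the off window, with the baseline
#' taken as the mean current in a later window after the transient has
#' decayed. The absolute value implements the convention that charge moved
#' back at repolarization is reported positive.
#'
#' @param sweep numeric current sweep, pA.
#' @param time_ms shared time base, ms.
#' @param off_window_ms length-2 vector, start/end of the integration
#'   window, ms.
#' @param baseline_window_ms length-2 vector, baseline window, ms (after
#'   transient decay).
#' @param pre_baseline_window_ms optional length-2 window in the settled
#'   late-step plateau. When given, a two-baseline integral is used: the
#'   integration runs from the start of this window across the
#'   repolarization edge (`edge_ms`) to the end of the off window, and the
#'   plateau mean is subtracted before the edge, the tail baseline after
#'   it. Because the acquisition low-pass preserves area, this cancels the
#'   filtered ionic-current step edge exactly instead of leaking part of
#'   it into the charge.
#' @param edge_ms repolarization time (required with
#'   `pre_baseline_window_ms`).
#' @return off-charge in pC (pA * ms = fC; converted).
#' @export
integrate_off_charge <- function(sweep, time_ms, off_window_ms,
                                 baseline_window_ms,
                                 pre_baseline_window_ms = NULL,
                                 edge_ms = NULL) {
  dt <- time_ms[2] - time_ms[1]
  idx_off <- which(time_ms >= off_window_ms[1] & time_ms < off_window_ms[2])
  idx_base <- which(time_ms >= baseline_window_ms[1] &
                      time_ms < baseline_window_ms[2])
  if (length(idx_off) < 5) stop("integration window shorter than 5 samples")
  if (length(idx_base) < 5) stop("baseline window shorter than 5 samples")
  baseline <- mean(sweep[idx_base])
  if (is.null(pre_baseline_window_ms)) {
    q_fC <- sum(sweep[idx_off] - baseline) * dt    # pA*ms = fC
    return(abs(q_fC) / 1000)                       # pC
  }
  if (is.null(edge_ms))
    stop("edge_ms required with pre_baseline_window_ms")
  idx_pre <- which(time_ms >= pre_baseline_window_ms[1] &
                     time_ms < pre_baseline_window_ms[2])
  if (length(idx_pre) < 5) stop("plateau window shorter than 5 samples")
  plateau <- mean(sweep[idx_pre])
  idx1 <- which(time_ms >= pre_baseline_window_ms[1] & time_ms < edge_ms)
  idx2 <- which(time_ms >= edge_ms & time_ms < off_window_ms[2])
  q_fC <- (sum(sweep[idx1] - plateau) + sum(sweep[idx2] - baseline)) * dt
  abs(q_fC) / 1000
}

#' Steady-state current in a late-step window
#'
#' Mean current over a window placed at the end of the step epoch.
#'
#' @param sweep numeric current sweep, pA.
#' @param time_ms time base, ms.
#' @param window_ms length-2 vector delimiting the window, ms.
#' @return mean current, pA.
#' @export
steady_state_current <- function(sweep, time_ms, window_ms) {
  idx <- which(time_ms >= window_ms[1] & time_ms < window_ms[2])
  if (length(idx) < 1) stop("empty steady-state window")
  mean(sweep[idx])
}

#' Average current-voltage relation across cells
#'
#' @param families list of `trace_family` objects sharing one protocol.
#' @param window_ms steady-state window, ms (default: final 20% of the step
#'   epoch).
#' @param per_pF normalize each cell's currents to its membrane capacitance
#'   (current density, pA/pF)? Default FALSE.
#' @return object of class `iv_curve`: data.frame with `V_mV`, `I_mean`,
#'   `I_sem`, `n`.
#' @export
build_iv <- function(families, window_ms = NULL, per_pF = FALSE) {
  stopifnot(length(families) >= 1)
  proto <- families[[1]]$protocol
  for (f in families)
    if (!isTRUE(all.equal(f$protocol$levels_mV, proto$levels_mV)))
      stop("families do not share a protocol")
  if (is.null(window_ms)) {
    step_end <- proto$pre_ms + proto$step_ms
    window_ms <- c(step_end - 0.2 * proto$step_ms, step_end)
  }
  imat <- sapply(families, function(f) {
    i <- apply(f$sweeps, 2, steady_state_current, time_ms = f$time_ms,
               window_ms = window_ms)
    if (per_pF) i / f$meta$cell$Cm_pF else i
  })
  imat <- matrix(imat, nrow = length(proto$levels_mV))
  n <- ncol(imat)
  sem <- if (n > 1) apply(imat, 1, stats::sd) / sqrt(n) else rep(0, nrow(imat))
  out <- data.frame(V_mV = proto$levels_mV, I_mean = rowMeans(imat),
                    I_sem = sem, n = n)
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' Per-level off-gating charge of a trace family
#'
#' Integrates the tail-epoch off-gating charge at every protocol level
#' using the two-baseline scheme of [integrate_off_charge()]: plateau
#' baseline over the final 10% of the step epoch, integration across the
#' repolarization edge over the first 20% of the tail (about ten
#' relaxation time constants at the default gating kinetics, so the
#' transient is captured without integrating tail-long noise), tail
#' baseline over the final 20% (gating relaxation complete there).
#'
#' @param family a `trace_family`.
#' @param off_window_ms,baseline_window_ms optional explicit windows, ms.
#' @return data.frame with `V_mV` and `Q_off_pC`.
#' @export
family_off_charges <- function(family, off_window_ms = NULL,
                               baseline_window_ms = NULL) {
  proto <- family$protocol
  tail_start <- proto$pre_ms + proto$step_ms
  tail_end <- tail_start + proto$tail_ms
  if (is.null(off_window_ms))
    off_window_ms <- c(tail_start, tail_start + 0.2 * proto$tail_ms)
  if (is.null(baseline_window_ms))
    baseline_window_ms <- c(tail_end - 0.2 * proto$tail_ms, tail_end)
  pre_window_ms <- c(tail_start - 0.1 * proto$step_ms, tail_start)
  gd <- if (isFALSE(family$meta$filtered)) 0
        else bessel4_group_delay(proto$filter_kHz, proto$sampling_kHz)
  q <- apply(family$sweeps, 2, integrate_off_charge, time_ms = family$time_ms,
             off_window_ms = off_window_ms,
             baseline_window_ms = baseline_window_ms,
             pre_baseline_window_ms = pre_window_ms,
             edge_ms = tail_start + gd)
  data.frame(V_mV = proto$levels_mV, Q_off_pC = q)
}

#' Ratio of off-gating charge to steady-state transport current
#'
#' Q_off/I at a single step voltage (units pC/pA = ms), inversely related to
#' the probability that a mobilized voltage sensor completes an electrogenic
#' transport cycle.
#'
#' @param family a `trace_family`.
#' @param at_mV step voltage at which to evaluate (default +165 mV).
#' @param ss_window_ms steady-state window (default final 20% of step).
#' @param ... windows forwarded to [family_off_charges()].
#' @return list with `Q_off_pC`, `I_ss_pA`, `ratio_ms`.
#' @export
qi_ratio <- function(family, at_mV = 165, ss_window_ms = NULL, ...) {
  proto <- family$protocol
  k <- which(abs(proto$levels_mV - at_mV) < 1e-9)
  if (length(k) != 1) stop("requested voltage not present in protocol")
  if (is.null(ss_window_ms)) {
    step_end <- proto$pre_ms + proto$step_ms
    ss_window_ms <- c(step_end - 0.2 * proto$step_ms, step_end)
  }
  i_ss <- steady_state_current(family$sweeps[, k], family$time_ms,
                               ss_window_ms)
  if (abs(i_ss) < .Machine$double.eps^0.5)
    stop("steady-state transport current is zero; Q/I undefined")
  q <- family_off_charges(family, ...)$Q_off_pC[k]
  list(Q_off_pC = q, I_ss_pA = i_ss, ratio_ms = 1000 * q / i_ss)
}

#' Fit a two-state Boltzmann to charge-voltage data
#'
#' Least-squares fit of Q(V) = Qmax/(1 + exp(-beta (V - V05))),
#' beta = z_delta e0/(kB T). Initialization: V05 from the half-maximum
#' crossing of the monotone-smoothed charges, Qmax from the maximum charge,
#' z_delta = 1. A saturation flag is set when the largest observed charge
#' lies more than 20% below the fitted plateau.
#'
#' @param levels_mV step voltages, mV (>= 5 points).
#' @param Q_pC off-gating charges, pC.
#' @param const a [phys_constants()].
#' @return object of class `boltzmann_fit`: `Qmax_pC`, `V05_mV`, `z_delta`,
#'   per-parameter standard errors, `residual_norm`, `saturation_flag`.
#' @export
fit_boltzmann_q <- function(levels_mV, Q_pC, const = phys_constants()) {
  stopifnot(length(levels_mV) == length(Q_pC))
  if (length(levels_mV) < 5) stop("need >= 5 voltage points")
  ord <- order(levels_mV); V <- levels_mV[ord]; q <- Q_pC[ord]
  kT <- thermal_mV(const)
  q_sm <- stats::isoreg(V, q)$yf                   # monotone smoothing
  qmax_0 <- max(q_sm)
  half_idx <- which(q_sm >= qmax_0 / 2)[1]
  v05_0 <- if (is.na(half_idx)) stats::median(V) else V[half_idx]
  fit <- tryCatch(
    minpack.lm::nlsLM(q ~ Qmax / (1 + exp(-(z / kT) * (V - V05))),
                      data = data.frame(V = V, q = q),
                      start = list(Qmax = qmax_0, V05 = v05_0, z = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Boltzmann fit failed: ", conditionMessage(e)))
  cf <- coef(fit)
  if (cf["z"] <= 0) stop("Boltzmann fit converged to non-positive valence")
  span <- range(V)
  if (cf["V05"] < span[1] - 500 || cf["V05"] > span[2] + 500)
    stop("fitted V05 implausibly far outside the data span")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(Qmax_pC = unname(cf["Qmax"]), V05_mV = unname(cf["V05"]),
                 z_delta = unname(cf["z"]),
                 se = c(Qmax_pC = unname(se["Qmax"]),
                        V05_mV = unname(se["V05"]),
                        z_delta = unname(se["z"])),
                 residual_norm = sqrt(sum(residuals(fit)^2)),
                 fitted = fitted(fit),
                 saturation_flag = max(q) < 0.8 * unname(cf["Qmax"])),
            class = "boltzmann_fit")
}

#' Series-resistance voltage-error quality control
#'
#' Flags sweeps whose maximal uncompensated series-resistance voltage error
#' |I| * Rs_uncomp exceeds the limit (default 5 mV); such recordings are
#' excluded from averaging.
#'
#' @param sweeps matrix (samples x sweeps) of currents, pA.
#' @param Rs_uncomp_MOhm uncompensated series resistance, MOhm.
#' @param limit_mV maximal tolerated voltage error, mV.
#' @return logical vector, TRUE = pass, with attribute `max_error_mV`.
#' @export
qc_series_resistance <- function(sweeps, Rs_uncomp_MOhm, limit_mV = 5) {
  sweeps <- as.matrix(sweeps)
  stopifnot(Rs_uncomp_MOhm >= 0)
  err <- apply(abs(sweeps), 2, max) * Rs_uncomp_MOhm * 1e-3  # pA*MOhm = uV
  pass <- err <= limit_mV
  attr(pass, "max_error_mV") <- err
  pass
}
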