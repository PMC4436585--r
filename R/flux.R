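#' Simulate BCECF cytosolic-pH timecourses under voltage steps
#'
#' Forward model for intracellular alkalinization by electrogenic proton
#' export: during each voltage step the cytosolic pH rises piecewise
#' linearly with slope rate_model(V)/buffer_capacity, and the observable is
#' the dual-excitation ratio F490/F440 through a linear ex-situ calibration
#' line, plus Gaussian ratio noise.
#'
#' @param voltage_steps_mV voltages, one timecourse each.
#' @param rate_model function V -> proton flux (pH-equivalents/s before
#'   division by buffer capacity).
#' @param buffer_capacity dimensionless cytosolic buffering (> 0); the
#'   realized slope is rate_model(V)/buffer_capacity.
#' @param calibration forward [calibration_line()] mapping pH to ratio.
#' @param duration_s,dt_s step duration and sampling interval, s.
#' @param pH0 initial cytosolic pH.
#' @param noise_sd SD of additive ratio noise.
#' @param seed RNG seed; required when `noise_sd > 0`.
#' @return list of data.frames (one per voltage) with `time_s`, `ratio`,
#'   `voltage_mV`; attribute `truth` holds the generator slopes (pH/s).
#' @export
simulate_bcecf_timecourse <- function(voltage_steps_mV, rate_model,
                                      buffer_capacity = 1,
                                      calibration =
                                        calibration_line(0.8, -3.5, 6.4, 7.8),
                                      duration_s = 30, dt_s = 0.5,
                                      pH0 = 7.0, noise_sd = 0.005,
                                      seed = NULL) {
  stopifnot(buffer_capacity > 0, is.function(rate_model))
  if (noise_sd > 0 && is.null(seed))
    stop("seed required when noise_sd > 0")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_s, by = dt_s)
  slopes <- vapply(voltage_steps_mV, rate_model, 1) / buffer_capacity
  out <- lapply(seq_along(voltage_steps_mV), function(k) {
    ph <- pH0 + slopes[k] * t
    ratio <- predict_ratio(calibration, ph)
    if (noise_sd > 0) ratio <- ratio + stats::rnorm(length(ratio), sd = noise_sd)
    data.frame(time_s = t, ratio = ratio,
               voltage_mV = voltage_steps_mV[k])
  })
  names(out) <- paste0("V", voltage_steps_mV)
  attr(out, "truth") <- data.frame(voltage_mV = voltage_steps_mV,
                                   slope_pH_per_s = slopes)
  out
}

#' Convert a BCECF ratio series to pH
#'
#' Elementwise linear inversion through the ex-situ calibration line;
#' out-of-range values are flagged as extrapolated, never dropped.
#'
#' @param ratio numeric F490/F440 series.
#' @param calibration a [calibration_line()].
#' @return data.frame with `ratio`, `pH`, `extrapolated`.
#' @export
bcecf_to_ph <- function(ratio, calibration) {
  out <- ratios_to_pH(ratio, calibration)
  names(out)[names(out) == "R"] <- "ratio"
  out
}

#' Rate of cytosolic alkalinization from a pH timecourse
#'
#' Ordinary least-squares slope of pH against time over a fit window
#' (default: the full epoch minus 10% at each edge).
#'
#' @param time_s,pH numeric vectors.
#' @param fit_window_s optional length-2 window, s.
#' @return list with `rate_pH_per_s`, `se`, `n`.
#' @export
alkalinization_rate <- function(time_s, pH, fit_window_s = NULL) {
  stopifnot(length(time_s) == length(pH))
  if (is.null(fit_window_s)) {
    span <- diff(range(time_s))
    fit_window_s <- c(min(time_s) + 0.1 * span, max(time_s) - 0.1 * span)
  }
  idx <- time_s >= fit_window_s[1] & time_s <= fit_window_s[2]
  if (sum(idx) < 10) stop("need >= 10 samples in the fit window")
  fit <- stats::lm(pH[idx] ~ time_s[idx])
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(rate_pH_per_s = unname(cf[2, 1]), se = unname(cf[2, 2]),
       n = sum(idx))
}

#' Normalize rate-voltage data to a reference voltage
#'
#' Divides every rate by the rate at the reference voltage, so the
#' reference maps to exactly 1. Idempotent.
#'
#' @param rates data.frame with `voltage_mV` and `rate` columns (or numeric
#'   vector with voltages in `names`).
#' @param ref_mV reference voltage (must be present; default +140).
#' @return data.frame `voltage_mV`, `rate_norm`.
#' @export
normalize_rates <- function(rates, ref_mV = 140) {
  if (!is.data.frame(rates))
    rates <- data.frame(voltage_mV = as.numeric(names(rates)),
                        rate = as.numeric(rates))
  k <- which(abs(rates$voltage_mV - ref_mV) < 1e-9)
  if (length(k) != 1) stop("reference voltage not present")
  data.frame(voltage_mV = rates$voltage_mV,
             rate_norm = rates$rate / rates$rate[k])
}

#' Relative surface expression from HRP luminescence / mCherry fluorescence
#'
#' Per-well surface/total expression ratio (extracellular-epitope HRP
#' chemiluminescence divided by total-expression mCherry fluorescence),
#' normalized so the WT group mean is 1, with Welch t-tests of each group
#' against WT.
#'
#' @param records data.frame with columns `construct`, `luminescence`,
#'   `fluorescence` (fluorescence must be positive).
#' @param wt_label label of the reference group (default "WT").
#' @param alpha significance level.
#' @return list with `records` (input plus `ratio`, `ratio_norm`),
#'   `summary` (per-group mean, sem, n of the normalized ratio) and
#'   `tests` (vs WT).
#' @export
relative_surface_expression <- function(records, wt_label = "WT",
                                        alpha = 0.05) {
  stopifnot(all(c("construct", "luminescence", "fluorescence") %in%
                  names(records)))
  if (any(records$fluorescence <= 0))
    stop("non-positive fluorescence: ratio undefined")
  if (!wt_label %in% records$construct) stop("WT group not present")
  records$ratio <- records$luminescence / records$fluorescence
  wt_mean <- mean(records$ratio[records$construct == wt_label])
  records$ratio_norm <- records$ratio / wt_mean
  grp <- split(records$ratio_norm, records$construct)
  summ <- data.frame(construct = names(grp),
                     n = vapply(grp, length, 1L),
                     mean = vapply(grp, mean, 1),
                     sem = vapply(grp, function(g)
                       if (length(g) > 1) stats::sd(g) / sqrt(length(g))
                       else 0, 1))
  rownames(summ) <- NULL
  others <- setdiff(names(grp), wt_label)
  tests <- if (length(others) > 0 &&
               length(grp[[wt_label]]) > 1) {
    do.call(rbind, lapply(others, function(g) {
      if (length(grp[[g]]) < 2)
        return(data.frame(construct = g, t = NA_real_, p = NA_real_,
                          significant = NA))
      tt <- stats::t.test(grp[[g]], grp[[wt_label]])
      data.frame(construct = g, t = unname(tt$statistic), p = tt$p.value,
                 significant = tt$p.value < alpha)
    }))
  } else NULL
  list(records = records, summary = summ, tests = tests)
}
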