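#!/usr/bin/env Rscript
# Stage 5: cytosolic alkalinization rates and relative surface expression.
#
# BCECF timecourses are generated with proton-flux rates proportional to
# the G212A-like normalized current-voltage relation; the recovered rates,
# re-normalized to +140 mV, should overlay that I-V. The surface-
# expression stage reproduces the HRP/mCherry normalization with an
# E267A-like group at half the WT surface abundance.

suppressMessages(library(clampsight))
dir.create("results", showWarnings = FALSE)
seed <- 20260930L

pre <- clc5_preset("G212A")
iv_fun <- function(v) {
  p <- 1 / (1 + exp(-(v - pre$transport$V05_mV) * pre$transport$z_delta /
                      thermal_mV()))
  pre$transport$Gmax_nS * p * v
}
volts <- seq(20, 140, by = 20)
cal <- calibration_line(0.8, -3.5, 6.4, 7.8)
tc <- simulate_bcecf_timecourse(volts,
                                function(v) 0.012 * iv_fun(v) / iv_fun(140),
                                calibration = cal, noise_sd = 0.005,
                                seed = seed)
rates <- t(vapply(tc, function(d) {
  f <- alkalinization_rate(d$time_s, bcecf_to_ph(d$ratio, cal)$pH)
  c(rate = f$rate_pH_per_s, se = f$se)
}, c(rate = 1, se = 1)))
nr <- normalize_rates(data.frame(voltage_mV = volts, rate = rates[, "rate"]))
tab <- data.frame(voltage_mV = volts, rate_pH_per_s = rates[, "rate"],
                  rate_se = rates[, "se"], rate_norm = nr$rate_norm,
                  iv_norm = iv_fun(volts) / iv_fun(140))
write_truth_sidecar(tab, "results/flux_rates.tsv")
cat("normalized alkalinization rates vs normalized I-V:\n")
print(tab, row.names = FALSE, digits = 3)
cat(sprintf("max |rate_norm - iv_norm| = %.3f\n",
            max(abs(tab$rate_norm - tab$iv_norm))))

## surface expression
set.seed(seed)
wells <- data.frame(
  construct = rep(c("WT", "G212A", "E267A"), each = 6),
  luminescence = c(rnorm(6, 1000, 60), rnorm(6, 950, 60), rnorm(6, 500, 40)),
  fluorescence = rnorm(18, 1000, 50))
surf <- relative_surface_expression(wells)
write_truth_sidecar(surf$summary, "results/surface_expression.tsv")
write_truth_sidecar(surf$tests, "results/surface_expression_tests.tsv")
cat("\nrelative surface expression (WT = 1):\n")
print(surf$summary, row.names = FALSE, digits = 3)
print(surf$tests, row.names = FALSE, digits = 3)
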