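#!/usr/bin/env Rscript
# Stage 1: generate the synthetic electrophysiology data set.
#
# For each construct (WT, G212A, E267A) this writes, under results/data/:
#   - a P/4-corrected voltage-clamp trace bundle (steps -115..+175 mV)
#     with its ground-truth charge table, and
#   - a sine-plus-DC lock-in recording summary (per-DC-level Cm truth).
# Everything is seeded; rerunning reproduces the files bit for bit.

suppressMessages(library(clampsight))
seed <- 20260930L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

proto <- make_step_protocol(-60, -115, 175, 20,
                            pre_ms = 10, step_ms = 50, tail_ms = 25,
                            sampling_kHz = 100)

for (con in c("WT", "G212A", "E267A")) {
  p <- clc5_preset(con)
  fam <- simulate_p4_corrected_family(proto, p$cell, p$gating, p$transport,
                                      noise_sd_pA = 5,
                                      seed = seed + match(con, c("WT",
                                                                 "G212A",
                                                                 "E267A")))
  write_trace_bundle(fam, file.path(out, paste0("traces_", con, ".tsv")),
                     extra = c(construct = con))
  truth <- data.frame(
    V_mV = proto$levels_mV,
    Qss_pC = boltzmann_q(proto$levels_mV, p$gating$Qmax_pC, p$gating$V05_mV,
                         p$gating$z_delta) -
      boltzmann_q(-60, p$gating$Qmax_pC, p$gating$V05_mV, p$gating$z_delta))
  write_truth_sidecar(truth, file.path(out, paste0("traces_", con,
                                                   ".truth.tsv")))
  cat(sprintf("%s: wrote %d sweeps (%d samples each)\n", con,
              ncol(fam$sweeps), nrow(fam$sweeps)))
}

# short 5-ms pulses up to +350 mV preserve the whole-cell configuration at
# extreme voltages and expose the full charge-voltage relation of the
# right-shifted mutant
proto_sp <- make_step_protocol(-60, -110, 350, 25, pre_ms = 5, step_ms = 5,
                               tail_ms = 10, sampling_kHz = 100)
for (con in c("WT", "G212A")) {
  p <- clc5_preset(con)
  fam <- simulate_p4_corrected_family(proto_sp, p$cell, p$gating,
                                      p$transport, noise_sd_pA = 5,
                                      seed = seed + 20 +
                                        match(con, c("WT", "G212A")))
  write_trace_bundle(fam, file.path(out, paste0("shortpulse_", con, ".tsv")),
                     extra = c(construct = con))
  cat(sprintf("%s: wrote short-pulse family (%d levels to +%g mV)\n", con,
              length(proto_sp$levels_mV), max(proto_sp$levels_mV)))
}

# lock-in recordings: the G212A scan stops at +195 mV (stable whole-cell
# range), leaving its capacitance rise without a peak in range
for (con in c("WT", "G212A", "E267A")) {
  p <- clc5_preset(con)
  vgrid <- if (con == "G212A") seq(-105, 195, 10) else seq(-105, 245, 10)
  rec <- simulate_sine_dc_recording(vgrid, p$cell, p$gating,
                                    cap_V05_mV = p$cap_V05_mV,
                                    noise_sd_pA = 5, seed = seed + 50 +
                                      match(con, c("WT", "G212A", "E267A")))
  cs <- capacitance_sweep(rec)
  cs$Cm_truth_pF <- rec$truth$Cm_pF[order(rec$vdc_levels_mV)]
  write_truth_sidecar(cs, file.path(out, paste0("lockin_", con, ".tsv")))
  cat(sprintf("%s: lock-in scan over %d DC levels\n", con, nrow(cs)))
}
cat("done; data under", out, "\n")
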