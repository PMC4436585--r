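# clampsight

Analysis chain for the biophysical characterization of voltage-dependent
CLC anion/proton exchangers (ClC-5 and its Dent's-disease mutants G212A
and E267A), built as an R package plus numbered analysis drivers. It is
aimed at electrophysiologists and cell biologists who quantify
voltage-sensor gating and organellar pH:

* **Gating analysis** — P/4 leak subtraction, off-gating-charge
  integration, current–voltage relations, Q/I ratios, and least-squares
  fits of the two-state Boltzmann charge–voltage relation
  Q(V) = Qmax / (1 + e^(−β(V−V0.5))), β = zδ·e0/(kB·T).
* **Lock-in capacitance** — sine-plus-DC admittance estimation, closed-
  form inversion of the three-element cell circuit (Gs, Gm, Cm), and
  fits of the non-linear capacitance with the Boltzmann derivative
  C(V) = βQmax·e^(−β(V−V0.5))/(1+e^(−β(V−V0.5)))², including the
  "no peak in range" refusal for strongly right-shifted sensors.
* **Imaging pH** — Crocker–Grier-style particle detection with sub-pixel
  centroids, per-vesicle F488/F405 ratios, straight-line pH calibration,
  colocalization, and group statistics (Welch t-tests).
* **Flux and expression** — BCECF F490/F440 alkalinization rates,
  normalization to +140 mV, and HRP/mCherry relative surface expression.
* **Synthetic generators** — seeded forward models for all of the above
  (voltage-clamp trace families at 100 kHz/3 kHz, sine-plus-DC sweeps,
  three-channel vesicle scenes, BCECF timecourses) with ground-truth
  sidecars, so every stage is validated by parameter recovery.

## Worked example

Simulate a WT-like lock-in scan and recover its gating parameters from
the non-linear capacitance:

```r
library(clampsight)
g   <- gating_params(Qmax_pC = 1, V05_mV = 128, z_delta = 1)
rec <- simulate_sine_dc_recording(seq(-105, 245, 10), cell_params(), g,
                                  noise_sd_pA = 5, seed = 1)
cs  <- capacitance_sweep(rec)              # per-level Cm, Gm, Gs
dc  <- nonlinear_capacitance(cs)           # baseline-subtracted bell
fit <- fit_dboltzmann_c(dc$V_dc_mV, dc$dC_pF)
print(c(fit$Qmax_pC, fit$V05_mV, fit$z_delta), digits = 7)
#> [1]   1.000052 128.011121   1.000042
```

The fitted maximum charge (pC), half-activation voltage (mV) and
effective valence land on the generator's truth to better than 0.01% at
5 pA current noise, because a 1-pC Boltzmann sensor contributes a ~10 pF
capacitance bell on the 10 pF cell — far above the lock-in noise floor.

The numbered drivers run the full study over synthetic data and write
tables under `results/`:

```sh
Rscript analysis/01_simulate_ephys.R     # trace bundles + lock-in scans
Rscript analysis/02_gating_analysis.R    # I-V, Q_off(V), Q/I, Boltzmann fits
Rscript analysis/03_capacitance.R        # Cnl(V) + derivative-of-Boltzmann fits
Rscript analysis/04_vesicular_ph.R       # calibration + cohort pH statistics
Rscript analysis/05_proton_flux.R        # BCECF rates + surface expression
```

Stage 2, for example, prints the short-pulse Boltzmann fits

```
 construct Qmax_pC V05_mV z_delta saturation_flag
        WT  0.9992  132.4  0.9961           FALSE
     G212A  0.5943  239.5  0.7067           FALSE
activation shift G212A - WT: 107 mV
```

— the ~100-mV right shift of the mutant's activation — and stage 3 fits
the capacitance bells of WT (V0.5 ≈ 128 mV) and E267A (≈ 153 mV) while
refusing the G212A curve, which only rises within the scanned range.

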