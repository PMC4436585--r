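---
title: "Voltage-sensor gating, lock-in capacitance and vesicular pH: the models behind clampsight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voltage-sensor gating, lock-in capacitance and vesicular pH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampsight)
```

clampsight reconstructs, as a tested pipeline over seeded synthetic data,
the quantitative analysis chain used to characterize voltage-dependent CLC
anion/proton exchangers such as ClC-5 and its Dent's-disease mutants:
whole-cell gating-current analysis, sine-plus-DC lock-in capacitance
measurement, and ratiometric fluorescence pH imaging. This vignette
explains the underlying models, the defaults and why they were chosen,
and what the synthetic generators do and do not emulate.

## Two-state Boltzmann charge movement

The central phenomenological object is a mobile gating charge obeying a
two-state Boltzmann distribution. The steady-state charge moved at
membrane potential $V$ is

$$Q(V) = \frac{Q_{max}}{1 + e^{-\beta (V - V_{0.5})}},
\qquad \beta = \frac{z\delta\, e_0}{k_B T},$$

with $Q_{max}$ the saturating charge, $V_{0.5}$ the half-activation
voltage and $z\delta$ the effective valence — the product of elementary
charges moved and the fraction of the membrane field they traverse, which
a Boltzmann fit cannot separate (`fit_boltzmann_q` therefore reports the
product). At the default temperature of 296 K (room-temperature
recordings, 22–24 °C) the thermal voltage $k_BT/e_0$ is 25.5 mV.

Mobile charge also contributes a voltage-dependent *non-linear
capacitance*, the derivative of $Q(V)$:

$$C_{nl}(V) = \beta Q_{max}
\frac{e^{-\beta (V - V_{0.5})}}{\left(1 + e^{-\beta (V - V_{0.5})}\right)^2},$$

a bell-shaped curve peaking at $V_{0.5}$ with amplitude
$\beta Q_{max}/4$ and total area $Q_{max}$. Both fits use
Levenberg–Marquardt least squares (`minpack.lm`), initialized from the
half-maximum crossing of the monotone-smoothed data (charge fits) or from
the position and height of the observed maximum (capacitance fits).

Two flags guard interpretation. The charge fit sets a *saturation flag*
when the largest observed charge is more than 20% below the fitted
plateau — extrapolated $Q_{max}$ and $V_{0.5}$ are then unreliable, which
is exactly the situation for a strongly right-shifted mutant probed only
up to +175 mV; the remedy, as in the experiments, is a short-pulse
protocol reaching +350 mV. The capacitance fit *refuses* data whose
maximum sits at the edge of the sampled voltage range ("no peak in
range"), since a monotone rising flank cannot constrain all three
parameters; this reproduces the deliberate refusal to fit the
G212A-like curve.

### Generator presets

The canonical presets (`clc5_preset`) encode the published fit values as
generator truth: half-activation 128 mV (WT) and 153 mV (E267A) for the
capacitance bell, 132 mV (WT) and 240 mV (G212A) for the gating charge.
Quantities the source experiments do not print are package choices, made
once: effective valences of 1.0 (WT, E267A) and 0.7 (G212A, a shallower
sensor); $Q_{max}$ of 1 / 0.6 / 2 pC for WT / G212A / E267A; limiting
transport conductances of 20 / 15 / 2.5 nS, scaled so that the E267A-like
cell passes roughly tenfold less current than WT at +165 mV while moving
twice the gating charge — the phenotype the Q/I ratio quantifies. The
E267A gating-charge midpoint reuses its capacitance value (153 mV), as no
charge-fit value is reported for it.

## The voltage-clamp forward model

`simulate_trace_family` composes each sweep additively from four
components evaluated on the sample-exact command waveform: (i) the
capacitive charging transient of the passive cell, an exponential of
amplitude $\Delta V / R_s^{eff}$ and time constant
$C_m R_s^{eff}$, with $R_s^{eff}$ the series resistance after
compensation; (ii) ohmic leak $V/R_m$; (iii) the gating current
$I_g = dQ/dt$, with $Q$ relaxing first-order toward $Q_{ss}(V)$ with a
voltage-independent time constant $\tau_0$; and (iv) a steady transport
current $G_{max} P_o(V) (V - E_{rev})$ whose open probability shares the
activation parameters of the gating charge. The sum is low-pass filtered
by a 4-pole Bessel-type IIR filter (3 kHz corner at 100 kHz sampling,
matching the acquisition settings) and Gaussian current noise (default
5 pA SD) is added. No transport-cycle kinetic scheme is modeled — states
and rates are not available — so the transport current is phenomenological
and strictly follows activation.

Choices worth stating explicitly:

* $\tau_0 = 0.5$ ms. Gating-current kinetics are unreported; this value
  makes off-transients decay well within every tail epoch while remaining
  slow enough to be band-limited at 3 kHz.
* The filter is designed from the standard normalized 4th-order Bessel
  analog poles by bilinear transform with prewarping, has exactly unit DC
  gain (so time integrals of settled transients are preserved), and is
  initialized at the steady state of the first sample so constant
  prefixes pass unchanged.
* The reversal potential defaults to 0 mV; the true exchanger reversal is
  not modeled.
* `make_step_protocol` treats the voltage increment as nominal and
  adjusts it so both endpoint voltages are always included, as step
  generators in acquisition software do.

## P/4 leak subtraction and charge integration

`p4_leak_subtract` removes linear leak and capacitance using $n$
sub-pulses of $1/n$ amplitude delivered from a −60 mV leak holding
potential: each sweep is referenced to its own pre-step baseline and the
averaged leak response, scaled by $n$, is subtracted. For a purely linear
cell this is exact to machine precision. By default the generator delivers
the sub-pulses with *inverted* polarity (hyperpolarizing for depolarizing
main steps): with activation far from the leak holding potential the
voltage sensor then stays immobile during the leak protocol, and the
correction leaves the gating current intact to within a few tenths of a
percent of the moved charge. Same-polarity sub-pulses are available and
differ only by that small residue.

Off-gating charge is the integral of the repolarization transient. Two
numerical details matter. First, the integration baseline is the mean
current over the final 20% of the tail, where gating relaxation is
complete. Second, the acquisition filter delays every current edge by its
group delay (≈0.17 ms at 3 kHz/100 kHz); an integration window that
starts exactly at the command edge would therefore swallow a slice of the
pre-edge transport plateau. `family_off_charges` uses a two-baseline
integral: it opens the window inside the settled late-step plateau,
subtracts the plateau mean before the delay-shifted edge and the tail
baseline after it. Because the filter's delay area equals its group delay
exactly, the filtered plateau edge then integrates to zero and the
recovered charge matches the generator's $\Delta Q_{ss}$ to a few tenths
of a percent at charge-carrying voltages. The integration extends over
the first fifth of the tail — about ten relaxation time constants at the
default kinetics — so the transient is captured in full without
accumulating integration noise over the rest of the tail, which matters
most for constructs whose accessible charge is small. Off-charge is
reported with charge moved back at repolarization positive (implemented
as the absolute value of the signed integral).

The Q/I ratio divides this charge by the steady-state current at the same
voltage (pC/pA, i.e. ms). Because open probability and charge share their
voltage dependence in the forward model, the ratio is voltage-independent
and equals $Q_{max}/(G_{max}(V-E_{rev}))$ — its ordering across constructs
(E267A > WT > G212A) is therefore a direct readout of charge moved per
transporting conductance, mirroring the interpretation of reduced
transport-cycle completion probability.

Recordings whose maximal uncompensated voltage error $|I| R_s$ exceeds
5 mV are excluded (`qc_series_resistance`), the criterion used during
acquisition.

## Sine-plus-DC lock-in capacitance

A 10-mV, 400-Hz sine is superimposed on DC steps. The measured complex
admittance at the stimulus frequency, together with the DC conductance
$G_{dc}$ from the cycle-averaged current (relative to a −60 mV holding
segment), determines the three-element cell circuit in closed form:

$$G_s = G_{dc} + \frac{(A - G_{dc})^2 + B^2}{A - G_{dc}}, \quad
C_m = \frac{G_s^2 B}{\omega\left((G_s - A)^2 + B^2\right)}, \quad
G_m = \frac{G_{dc} G_s}{G_s - G_{dc}},$$

with $A = \mathrm{Re}\,Y$, $B = \mathrm{Im}\,Y$. Inputs with
$A \le G_{dc}$ or $B \le 0$ are rejected as unphysical, and a DC level
within 1 mV of the holding potential is refused because $G_{dc}$ is a
difference quotient. The admittance estimator discards the first two sine
cycles after each DC jump (settling) and requires an integer cycle count.
The per-step dwell (cycle count) is unreported in the source; the default
of 32 cycles (80 ms at 400 Hz) is a realistic lock-in dwell chosen before
any recovery experiments. The generator evaluates $C_m(V)$ quasi-
statically at the DC potential and solves the linear circuit exactly
(including the settling exponential), so noiseless sweeps reproduce the
closed-form admittance to better than $10^{-6}$; the 3-kHz acquisition
filter is not applied on this path, whose 400-Hz stimulus lies far below
the corner.

The non-linear capacitance is $C_m(V)$ minus its mean over a
hyperpolarized baseline region (default $V \le -60$ mV), where the
Boltzmann bell's tail is below 0.3% of its peak. The derivative-of-
Boltzmann fit includes a free additive offset by default: baseline
subtraction at finite voltages leaves a small constant residue of that
tail, and the offset absorbs it exactly — without it, noiseless
$Q_{max}$ recovery is biased by about 0.3%. As printed, the model's
exponent is sometimes typeset with $V_0$ where the membrane potential is
meant; the implementation uses the DC step potential throughout.

## Fluorescence scenes and the imaging pipeline

`render_vesicle_scene` emulates single 2-D frames of endocytic vesicles
carrying a ratiometric pH-sensitive fluorophore excited at 405 and
488 nm, plus a pH-independent 561-nm channel from a red tag on the
transporter. Vesicles are sub-resolution points rendered as isotropic
Gaussian spots (default σ = 1.3 px); per-vesicle 405-amplitude varies
±30%, the 488 amplitude is the 405 amplitude times the forward
calibration line evaluated at the vesicle's luminal pH, so the
integrated-intensity ratio $F_{488}/F_{405}$ encodes pH exactly before
noise. Noise is Poisson shot noise on (signal + uniform background)
counts. Centers keep 3σ from borders and 4σ from each other; placement is
rejection-sampled with bounded retries. Channel brightnesses are
arbitrary units — relative fluorophore brightness is unreported.

Detection follows the classic colloidal-particle recipe: band-pass
(Gaussian blur minus boxcar mean, edge-renormalized so constants map to
zero), local maxima above a brightness percentile within a
$(2w+1)^2$ neighborhood, and iterated intensity-centroid refinement over
a disc of radius $w$ with brightness ($m_0$) and size ($R_g^2$) moments;
duplicates closer than $w$ merge keeping the brighter. The detector
parameters are unreported in the source ("house-written" software);
defaults are $w = 3$ px and the 90th percentile, plus an absolute
6-sigma noise floor estimated from the 84th percentile of the clipped
filtered image — the floor is what makes a background-only image return
an empty set rather than noise maxima. Detection runs in the 561 channel
when the transporter tag is present and falls back to the 405 channel for
mock cells, as in the experiments.

Ratios are measured as background-subtracted integrated intensities over
discs of radius 3 px, with the background taken as the median of an
annulus 1–3 px outside the disc (robust to neighbors); vesicles with a
non-positive denominator are excluded and logged. Calibration is an
ordinary least-squares line of mean ratio against nigericin-clamped pH,
valid over the span of calibration points; conversion inverts it and
flags (never drops) out-of-range values. Colocalization reports the
Pearson correlation over a mask plus a fixed-percentile overlap map (no
automatic threshold selection). Group comparison uses Welch's t-test by
default — the source states only "two-sample t-test", and unequal
variances are the safer default — with the pooled-variance variant behind
a flag.

The synthetic cohort mirrors the imaging experiment's sample sizes
(7 mock, 18 WT, 18 G212A, 9 E267A cells). Group mean luminal pH values
are generator presets — the experimental figure plots but never prints
them — set to 6.7 (mock), 6.3 (WT), 6.6 (G212A), 6.5 (E267A): a 0.4-pH
mock–WT gap with mutants in between. Cell-to-cell SD is 0.15 pH and
within-cell vesicle SD 0.2 pH, typical for endosomal populations.
Recovery is judged against the *realized* per-cell ground truth, so the
check isolates measurement error from sampling noise.

## BCECF flux and surface expression

Cytosolic alkalinization by electrogenic proton export is modeled as
piecewise-linear pH growth with slope `rate_model(V)/buffer_capacity`,
observed as an $F_{490}/F_{440}$ ratio through a linear ex-situ
calibration (the experimental calibration parameters are not printed;
synthetic analyses generate their own forward line over pH 6.4–7.8). The
analysis side fits an ordinary least-squares slope over the step epoch
minus 10% edges and normalizes rate–voltage relations to the rate at
+140 mV; normalization is idempotent and the congruence of normalized
rates with the normalized I–V is a generator-level identity that the
pipeline must recover through the ratio round trip. The reduced
intracellular buffering used experimentally (0.25 mM HEPES) enters only
through the generator's `buffer_capacity`; the analysis is agnostic to it.

Relative surface expression divides extracellular-epitope HRP
chemiluminescence by total-expression mCherry fluorescence per well,
normalizes group means to WT = 1, and Welch-tests each construct against
WT.

## Problem sizes, determinism, limitations

The bundled analyses and tests use 50-ms steps with 25-ms tails at
100 kHz (8,500 samples per sweep), 31–36 DC levels per lock-in scan,
128×128-px scenes with 50 vesicles for detector characterization and
96×96-px scenes with 25 vesicles per cohort cell — sizes at which every
stage's statistical behavior is already asymptotic while a full cohort
replicate takes about a second. All stochastic stages require an explicit
seed whenever noise is enabled and are bit-reproducible given one.

What passing these tests does *not* show: the generators contain no
vesicle motion or focus drift, no cell-to-cell optical background
structure, no transport-cycle kinetics (so transport tails and their
possible contamination of off-charge integration are absent by
construction, a question the windows expose as configuration), and no
absolute current-density scale — the original recordings are not
deposited, so published headline values serve as generator presets whose
*recovery* is what the pipeline demonstrates.
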