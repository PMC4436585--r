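Package: clampsight
Title: Voltage-Clamp Gating, Lock-In Capacitance and Vesicular pH Analysis
    for CLC Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for the biophysical characterization of
    voltage-dependent CLC anion/proton exchangers such as ClC-5:
    P/4 leak subtraction and off-gating-charge integration of whole-cell
    voltage-clamp trace families, Boltzmann fits of charge-voltage
    relations, sine-plus-DC lock-in estimation of membrane capacitance
    with derivative-of-Boltzmann fits of the non-linear capacitance,
    Crocker-Grier particle detection and ratiometric pHluorin2 vesicular
    pH measurement with linear calibration, BCECF cytosolic
    alkalinization rates, and surface-expression normalization.
    Includes seeded synthetic-data generators (voltage-clamp trace
    families, sine-plus-DC sweeps, multi-channel fluorescence scenes,
    BCECF timecourses) with ground-truth sidecars for parameter-recovery
    validation.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    signal,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
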