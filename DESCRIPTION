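Package: hfirebench
Title: Burst Waveform Synthesis and Tissue Impedance Analysis for
    High-Frequency Irreversible Electroporation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for parameterizing high-frequency irreversible
    electroporation (H-FIRE) burst waveforms and analyzing the voltage and
    current traces recorded during pulsed-field-ablation experiments.
    Implements burst synthesis from the standard pulse-width/interphase/
    interpulse notation with spectral characterization, a first-order
    low-pass filtering and per-pulse median pipeline that turns
    oscilloscope traces into per-burst quasistatic resistances, shape-factor
    conductivity inversion for parallel-plate and needle-pair electrode
    geometries, a seeded synthetic tissue and virtual-oscilloscope generator
    with field-dependent (electroporation) conductivity, voltage-ramp
    experiment orchestration with Welch and ANOVA/Tukey delay-invariance
    statistics, and an electrostatic forward model (analytic two-cylinder
    field map and a nonlinear finite-difference Laplace solver) linking
    conductivity to electric-field distributions and ablation areas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
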