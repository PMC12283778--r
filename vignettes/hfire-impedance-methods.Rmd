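---
title: "Burst waveforms, tissue impedance, and delay invariance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst waveforms, tissue impedance, and delay invariance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfirebench)
```

## The measurement problem

High-frequency irreversible electroporation (H-FIRE) ablates tissue with
bursts of short (0.5–10 µs) bipolar pulses: a positive pulse, an
interphase delay `d1`, a negative pulse, and an interpulse delay `d2`,
repeated for a number of cycles so that the total energized time of a
burst is comparable to one long monopolar IRE pulse (100 µs by
convention). A waveform is named `PW-d1-PW-d2` in microseconds, e.g.
`2-5-2-5`. Two questions drive the analyses this package implements:

1. **Does tissue impedance depend on the delays?** If conductivity,
   resistance, and current at a given pulse width and field are the same
   for `d1, d2` anywhere between 1 and 100 µs, then treatment planning
   can choose delays freely (e.g. to minimize nerve excitation) without
   re-characterizing the tissue.
2. **How does apparent conductivity depend on pulse width and field?**
   Short pulses end before cell membranes charge fully, so the membrane
   still shunts current and the *apparent* bulk conductivity is higher;
   above the electroporation threshold the permeabilized membranes raise
   conductivity to a plateau regardless of pulse width.

The package provides the full computational chain used to answer both on
the bench — burst synthesis, oscilloscope-trace processing, shape-factor
conductivity inversion, ramp orchestration, and the statistics — plus a
synthetic "virtual oscilloscope + tissue" generator so the chain is
testable end to end without instrument data.

## Waveform model

`build_burst()` synthesizes the ideal square burst: `cycles` repetitions
of `[+A, 0 (d1), -A, 0 (d2)]`, sampled at the protocol's sampling period
(default 2 ns, which puts at least 500 samples across the shortest 1 µs
pulse). Pulse boundaries are quantized to the sampling clock with
`round(t/dt)`, and positive and negative windows share one rounded
per-pulse sample count, so every synthesized burst is exactly charge
balanced — its samples sum to zero, and its DC spectral bin is exactly
zero.

The *characteristic frequency* of a waveform is defined as the
fundamental of one full cycle,

```
f_char = 1 / (2 PW + d1 + d2),
```

which gives ~45 kHz for `1-10-1-10` and ~71 kHz for `2-5-2-5` (and the
same values for their reciprocal waveforms `10-1-10-1` and `5-2-5-2`).
`power_spectrum()` computes the one-sided FFT magnitude spectrum; for
multi-cycle square bursts of the studied waveforms the dominant
nonzero-frequency peak coincides with `f_char` to within one frequency
bin, and the package uses that spectral peak as a *cross-check* of the
definition, not as the definition itself. Spectra can be normalized to
unit energy when only relative frequency content matters. Note the
peak-equals-fundamental property is not universal — a waveform with a
very asymmetric delay split (e.g. `d1 = 0`, `d2` large) pushes spectral
weight to higher harmonics — but it holds for the symmetric and
reciprocal waveforms studied here.

## Trace-processing pipeline

`burst_metrics()` implements the measurement chain for one recorded
burst:

1. **Filter.** Both channels pass a first-order digital low-pass with
   time constant `τ = PW/3` (`lowpass_first_order()`, backward-Euler
   `α = dt/(τ+dt)`; at 2 ns sampling this differs from the exact
   `1 − e^(−dt/τ)` by under 0.01%). The filter suppresses the capacitive
   charging spike at pulse onset that otherwise corrupts plateau readings
   on short (< 2 µs) pulses. Its step response reaches `1 − e^(−3)`
   (≈ 95.02%) of the plateau by pulse end; because voltage and current
   are filtered identically, this attenuation cancels exactly in the
   resistance ratio.
2. **Segment.** `segment_pulses()` cuts the trace into its `2·cycles`
   pulse windows from protocol timing (the recording is synchronized
   with the generator), not edge detection.
3. **Rectified maxima.** `pulse_magnitudes()` takes the maximum of the
   polarity-rectified filtered samples per window — on a bipolar
   waveform a plain maximum is only meaningful per polarity.
4. **Median and Ohm's law.** The per-burst voltage and current are the
   medians of the per-pulse maxima, and the quasistatic resistance is
   `R = V/I`. The median makes one corrupted pulse in a burst
   inconsequential.
5. **Level average.** `level_metrics()` / `process_ramp()` average the
   three bursts of each ramp level, keeping per-burst values for
   dispersion.

Two numerical consequences are worth knowing. The filter is initialized
at the first sample (`y[1] = x[1]`), so if a record begins exactly at a
pulse onset the first pulse's maximum is unattenuated; the per-burst
median is insensitive to that single value, and any real oscilloscope
record carries pre-trigger baseline anyway. And the filtered maximum of
a pulse depends slightly on the *preceding* gap length (the filter state
decays during delays), so per-pulse filtered currents are not exactly
delay-invariant even when the physics is — the V/I ratio is, which is
why resistance is the primary response in the delay statistics.

Traces round-trip through `write_trace()` / `read_trace()` as
comma-delimited text (`time_s,voltage_V,current_A`, full precision) with
a JSON metadata sidecar; `read_trace()` rejects non-uniform timestamps
(max 1% jitter of the median step) naming the first offending index, and
never pads or repairs truncated records.

## Geometry and conductivity inversion

Two electrode configurations are modelled (`geometry_spec`):

* **Parallel plates** holding a cylindrical sample (thickness `l`
  ≈ 6 mm, diameter 6 mm). The field is uniform, `E = V/l`, and
  conductivity follows from the prism shape factor:
  `σ = l / (A · R)` (`prism_conductivity()`). 100 V/cm across a 6 mm
  sample needs 60 V.
* **Needle pairs** (spacing `D` 1.0–1.5 cm, radius `a` 0.225–0.5 mm,
  exposure `L`). The infinite-medium two-cylinder shape factor is
  `S = πL / acosh(D/(2a))` with predicted `R = 1/(σS)`
  (`needle_pair_shape_factor()`).

`conductivity_curve()` inverts only plate measurements by default:
needle-pair resistance folds the non-uniform field and any
field-dependent conductivity into one number, so a single-shape-factor
inversion is physically ambiguous there. An explicit
`allow_needle = TRUE` override exists for exploratory use.

Voltage schedules are expressed as distance-normalized voltage (V/cm,
voltage over electrode gap). The shipped `ramp_levels()` schedules are
50–2000 V/cm for 1.0 cm needles, capped at 1500 V/cm for 1.5 cm needles
(generator current limit), 100–2000 V/cm for plates (generator voltage
floor), and 100–2500 V/cm for cardiac needles.

## The synthetic tissue model

`tissue_params()` defines a phenomenological apparent-conductivity
surface

```
σ(E, PW) = σ_bulk(PW) + (σ_max(PW) − σ_bulk(PW)) · s((E − E_th)/w)
```

with `s` a sigmoid rising from 0 to 1. The sigmoid is a compact-support
C² *smootherstep* on `(E − E_th)/w ∈ [−3, 3]` rather than a logistic:
this keeps `s(0) = 0.5` at the transition field while attaining the
floor and plateau *exactly* (at `E ≤ E_th − 3w` and `E ≥ E_th + 3w`), so
"bulk conductivity" and "electroporated plateau" are exact model
constants rather than asymptotes. With the potato preset
(`E_th = 500 V/cm`, `w = 150 V/cm`) the floor is reached at 50 V/cm and
the plateau at 950 V/cm.

The **potato preset** is calibrated to published summary measurements of
russet potato: `σ_bulk` = 0.13 S/m (1 µs) and 0.04 S/m (10 µs),
`σ_max` = 0.55 S/m (1 µs) and 0.67 S/m (10 µs). The transition center
(500 V/cm) is the midpoint of the 250–750 V/cm bracket within which the
bench measurements localize the onset of significant conductivity rise,
and the width (150 V/cm) spans that bracket. Intermediate pulse widths
interpolate linearly in `log10(PW)` — a monotone, scale-aware choice for
a quantity controlled by membrane charging. The **cardiac preset** is a
clearly-labelled synthetic placeholder (higher bulk conductivity, same
transition), useful only for qualitative exercises.

A **mechanistic mode** adds intra-pulse membrane charging:
`σ(t, E) = σ_ss(E) + (σ_hf − σ_ss(E)) e^(−t/τ_mem)` with
`τ_mem = 1 µs` (the middle of the 0.7–1.4 µs range reported for tuber
tissue), `σ_hf` the bulk value at the shortest tabulated pulse width and
`σ_ss` the apparent conductivity at the longest. It reproduces the
qualitative pulse-width dependence (short pulses read higher apparent
conductivity) but is not a fitted cell-scale model; the phenomenological
mode is the contract surface for all quantitative claims.

`simulate_trace()` assembles a virtual recording: ideal (optionally
rise-time-lagged) voltage, current `V/R` with `R = 1/(σS)` from the
geometry, an optional capacitive onset overshoot on the current channel
(default 10% decaying with τ = 0.2 µs, so the PW/3 filter's purpose is
actually exercised — it leaves a residual resistance bias under 1% at
1 µs and negligible beyond), and additive Gaussian noise at 1% of each
channel's plateau (oscilloscope noise is not published; 1% of full scale
is a realistic 8-bit-scope figure). Delays affect only waveform timing,
never the tissue state — **delay invariance is built into the
generator**, which is exactly what makes it a null model for the delay
statistics. A `delay_effect` knob can inject a d2-proportional
conductivity change to power-check those statistics.

`simulate_ramp()` delivers 3 bursts per level in ascending order with
**no memory across levels**, the behaviour verified on the bench by
comparing full-ramp to standalone deliveries. For plate samples it draws
one per-sample thickness per ramp (Normal(6, 0.2) mm truncated positive,
mirroring caliper variation), computes level voltages from the drawn
thickness, and records it so the inversion uses the measured value — as
the bench procedure does. A `ramp_memory_frac` knob injects a
resistance change after the first level for power checks. All
randomness flows from one integer seed; the RNG state is restored
afterwards.

## Experiment designs and statistics

`design_spec()` + `run_design()` orchestrate the waveform grid (e.g. 4
pulse widths × 3 symmetric delays = 12 waveforms, n = 8 replicates
each, one ramp per replicate) into a tidy one-row-per
(waveform, replicate, level) table; per-replicate seeds derive
deterministically from the base seed. Asymmetric `(d1, d2)` pairs are
supported for reciprocal-waveform comparisons.

The statistics mirror bench practice at α = 0.05: `welch_t_test()`
(unpaired, two-tailed, Welch–Satterthwaite df) for two-group
comparisons, and `oneway_anova_tukey()` (fixed-effects one-way ANOVA
with Tukey HSD adjusted pairwise p-values from the studentized-range
distribution) for multi-group ones. Both are thin wrappers over the
corresponding `stats` routines; the test suite cross-checks them against
hand-computed closed forms. `delay_invariance_report()` runs one ANOVA
across delay groups per (pulse width, level) cell and summarizes the
fraction of significant cells; no correction is applied across cells
beyond Tukey within each ANOVA, mirroring per-panel bench testing (a
documented caveat, not an oversight). `ramp_memory_test()` compares
full-ramp and standalone final-level resistances with Welch's t per
target level, processing only the final level of each ramp (earlier
levels influence nothing in a memoryless model but are still simulated
as delivered).

## Field and ablation forward model

`bipolar_field_map()` evaluates the exact two-cylinder potential (image
line charges at `±b`, `b = sqrt((D/2)² − a²)`) for a uniform medium on a
2D grid over the electrode midline cross-section; `E = |∇φ|` by central
differences. `ablation_area()` counts grid cells at or above a lethal
electric-field threshold (EFT), excluding electrode interiors — the
standard threshold model of IRE ablation. Per-pulse-width lethal EFTs
are literature-informed placeholders (lower thresholds for longer
pulses), so predicted areas increase with pulse width qualitatively.
Because neither the field map (for fixed σ and V) nor the σ model
depends on the delays, predicted ablation areas are delay-invariant *as
an identity* of the model — the package reproduces that structural
claim by construction, and documents it as such rather than as an
empirical finding.

`fd_laplace()` is the numerical oracle: it solves
`∇·(σ(E)∇φ) = 0` with Dirichlet electrodes and insulating outer
boundary on a uniform grid (5-point stencil, arithmetic-mean face
conductivities, sparse Cholesky solves), iterating σ(E) by Picard with
under-relaxation. Numerical choices:

* **Rasterization.** Electrode disks are dilated by half a cell so the
  staircase boundary straddles the true circle instead of inscribing
  it; this removes most of the systematic radius bias of a
  center-inclusion rule.
* **Current integration.** Electrode boundary flux uses trapezoid
  weights (half weight on domain-edge faces), which makes the uniform
  plate limit reproduce `R = l/(σA)` essentially exactly.
* **Relaxation.** The default under-relaxation is 0.5: with the preset
  sigmoid σ(E) a lighter damping (e.g. 0.7) can enter a limit cycle
  where the electroporated front oscillates between grid rings; 0.5
  converges in ~15–25 iterations for all shipped presets. Tolerance
  1e-6 (relative max-norm on φ), maximum 500 iterations,
  non-convergence is an error carrying the residual.
* **Grids.** The default is 50 µm spacing on a 4 × 4 cm domain. The
  test and acceptance suites run 100–200 µm grids, at which the
  needle-pair FD resistance agrees with the analytic shape factor to
  2–5% (the residual is dominated by domain truncation under the
  insulating boundary) and the plate limit to well under 1%.

## Problem sizes and what the tests show

The simulation studies in the test suite run at reduced problem sizes
chosen so the whole suite completes on a laptop: Monte-Carlo loops
(delay-invariance null/power, ramp-memory null) use 1 µs pulses at
20–40 ns sampling with 3–5 cycles per burst and 2–3 ramp levels, because
the pipeline statistics operate on per-burst medians whose distribution
is unchanged once a pulse spans ~50 samples. The conductivity-recovery
checks run at the full bench conditions: 2 ns sampling, 100 µs on-time
bursts, 9-level plate ramps, 3 bursts per level, n = 8 replicates, 1%
noise. Under those conditions the pipeline recovers the preset 1 µs
electroporated plateau (median over the two highest levels) and the
10 µs bulk conductivity (mean at 100 V/cm) within 5%, the
delay-invariance ANOVA is null-calibrated (significant-cell rate ≤ 0.10
at α = 0.05 over 100 seeded runs) yet detects an injected +10% d2
effect, and the ramp-memory Welch tests are non-significant in ≥ 90% of
null runs per target level.

What passing these tests does *not* show: the generator is a lumped,
homogeneous, memoryless model with Gaussian noise. Real tissue has
spatial heterogeneity, electrode–tissue contact impedance, temperature
drift, and possibly reversible-electroporation recovery dynamics between
bursts — none of which are modelled (deliberately: the delay-invariance
statistics need a clean null). Agreement of the pipeline with the
generator therefore validates the *computation*, not the biology.

## Known limitations

* The spectral "impedance distribution" of a waveform is represented by
  its normalized voltage magnitude spectrum; whether bench spectra are
  of voltage, current, or a transfer estimate is not determinable from
  published material, and only relative frequency content is compared.
* Needle-pair conductivity inversion is gated for the physical reasons
  above; the override is exploratory.
* The FD solver is 2D (per unit length, scaled by exposure); end
  effects of finite electrode exposure and insertion depth are not
  modelled.
* No thermal model: delays orders of magnitude shorter than thermal
  diffusion time scales cannot plausibly change temperature
  distributions, and nothing thermal is computed.
* The mechanistic conductivity mode is qualitative; mapping a 0.7–1.4 µs
  membrane time constant to per-pulse-width apparent conductivities
  exactly is not possible from apparent measurements alone.

## A worked example

```{r example, eval = FALSE}
library(hfirebench)

# a 12-waveform grid on the virtual potato, scaled down for speed
design <- design_spec(pulse_widths = c(1, 10), delays = c(1, 10, 100),
                      geometry = geometry_preset("potato_needle_1.0cm"),
                      levels = c(100, 1000, 2000), n_replicates = 8,
                      base_seed = 42, cycles = 5, sampling_period = 20)
tbl <- run_design(design, tissue_preset("potato"))
delay_invariance_report(tbl)

# conductivity vs field from plate ramps
p <- burst_protocol(10, 10, 10)
ramp <- simulate_ramp(p, geometry_preset("potato_plate"),
                      tissue_preset("potato"), levels = ramp_levels("plate"),
                      seed = 7)
conductivity_curve(process_ramp(ramp, p), attr(ramp, "geometry"))
```
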