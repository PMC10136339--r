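---
title: "Modelling the log-transformed EMG-force relation and its spatial dependence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the log-transformed EMG-force relation and its spatial dependence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`emgforce` simulates surface electromyography (EMG) and isometric force
from a motor neuron pool embedded in a volume conductor, and quantifies
their relation by the slope *b* of the log-log regression
`ln(RMS) = b ln(force) + ln(a)`. This vignette documents the model, the
parameters that matter, the design decisions taken where the problem was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The motor neuron pool

The pool (`pool_params()`, `build_pool()`) contains 150 motor units.
Recruitment thresholds (RTE), innervation numbers and peak twitch forces
are *deterministic exponential interpolations* across the unit index:

* `rte[i] = rte_max_fraction * 100 * exp(i * ln(R)/n) / R`, with a fixed
  100-fold threshold range ratio `R`. Most units therefore have low
  thresholds; the last unit is recruited at 40% of maximum excitation
  (the default, typical of small muscles where rate coding dominates) or
  80% (large limb muscles).
* innervation numbers run 22 to 2137 fibers; the pool totals just under
  70,000 fibers.
* peak twitch force `P` runs 1 to 100 au; contraction time is tied to it
  by `T = 90 ms * P^(-ln 3 / ln 100)`, so the 100-fold force range and the
  3-fold time range (90 down to 30 ms) hold simultaneously.

Interpolating deterministically rather than sampling the "exponential
distributions" makes the range endpoints exact and the pool reproducible;
randomness enters the simulation only through discharge timing and
geometry.

Rate coding is linear: a unit is silent below its RTE, fires at 8 Hz at
threshold, and its rate rises with excitation until its peak firing rate
(PFR) caps it. PFRs interpolate linearly between 25 and 35 Hz; under the
*onion-skin* organisation the earliest-recruited unit holds the highest
rate, under *reverse onion-skin* the latest. The excitation-to-rate gain
defaults to the value at which the **last-recruited unit reaches its PFR
exactly at 100% excitation** (0.45 Hz/% for the 40% recruitment range).
This convention makes "maximum excitation" mean full rate coding of the
whole pool and keeps the force-excitation curve strictly monotone. The
obvious alternative — scaling the gain so the *first* unit saturates at
100% — leaves high-threshold units firing barely above 8 Hz even at full
drive; rate coding then contributes almost nothing at high forces and the
log-log slope collapses well below 1 in every depth condition, which is
inconsistent with the near-linear EMG-force relation this model family is
known to produce under random placement. The gain is exposed in
`pool_params()` for users who want either behaviour.

Inter-spike intervals are Gaussian with mean `1/rate` and CV 0.2 (a
typical physiological value; not a sensitive choice here), *resampled*
until positive rather than clipped so the mean is preserved; each unit's
first discharge is placed uniformly within one mean interval so units
start out of phase.

## Force

Each discharge contributes a twitch — the critically damped impulse
response `g * P * (t/T) exp(1 - t/T)` — scaled by a fusion gain that
depends on the preceding inter-spike interval: with `u = T/ISI`, the gain
is 1 for `u <= 0.4` and `S(u)/S(0.4)` with `S(u) = (1 - e^(-2u^3))/u`
above it (continuous at the knee; the first discharge of a train uses
gain 1, having no preceding interval). Whole-muscle force is the linear
sum over units. Kernels are truncated at `8 T`, where the amplitude is
0.7% of the peak and the discarded tail is about 0.3% of the kernel area
(truncating at `5 T`, sometimes seen, still carries 9% of the peak
amplitude).

## The volume conductor

The muscle is a cylinder (24 mm diameter) under a 3 mm fat/skin
stand-off; the skin is the plane y = 0 and fibers run along z. The medium
is homogeneous and anisotropic (σz = 0.33, σx = 0.06 S/m, anisotropy
ratio Ka = 5.5); the fat layer enters as stand-off distance only. A fiber
action potential is two mirrored triplets of balanced point current
sources (amplitudes 1, -2.6, 1.6; 2 mm spacing) that start collapsed at
the innervation zone (z = 0), travel at 4 m/s to the fiber ends (±60 mm)
and collapse there — charge balance makes the surface potential vanish
exactly before generation and after extinction. The potential of one pole
at an electrode is `P / (2 pi sigma_x sqrt(Ka (dx^2 + y^2) + dz^2))`.
A motor unit action potential (MUAP) is the sum over the unit's fibers;
fibers are uniform at 20 fibers/mm² in a disc intersected with the
cross-section, so territory area grows with innervation number. EMG is
the superposition of MUAP trains of all active units — an interference
signal with physiological cancellation.

The exact pole magnitudes, spacings and the electrode position are not
constrained by the physiology; we place the single study electrode on the
muscle midline **10 mm from the innervation zone** along the fibers. Off
the zone, the generation phases of the two travelling triplets do not
cancel; and at 10 mm the axial term `dz^2` does not yet swamp the
anisotropically weighted depth term `Ka y^2`, so the conductor
discriminates source depth sharply. (At 40 mm the depth contrast washes
out visibly.) All of these are configurable (`tripole_spec()`,
`muscle_geometry()`, `sim_study_config()`).

The analysis RMS for the simulation study is computed on the raw
synthesized monopolar potential. A monopolar potential referenced at
infinity has a physically real quasi-static mean offset under sustained
firing; keeping it reproduces a near-linear EMG-force relation in the
random-depth condition, the anchor result of this model family. The
synthetic *experiment* pipeline, by contrast, demeans each analysis
segment, emulating the AC-coupled amplifiers that real high-density
recordings pass through (see below) — with hardware coupling the slope is
carried by the interference (AC) energy.

## Depth conditions

`assign_depths()` draws territory centre depths as a linear trend in peak
twitch force plus Gaussian jitter (2 mm SD), redrawn into the muscle:

* **superficial**: slope -0.13 mm/au — the largest units lie ~13 mm
  shallower than the mean, the smallest slightly deeper;
* **random**: slope 0;
* **deep**: slope +0.12 mm/au.

The slopes are specified in *millimetres of depth per au of twitch
force*. On normalised (0-1) axes the same numbers would displace even the
largest units by only ~3 mm, far too little to move the EMG-force slope
by the several tenths that depth stratification demonstrably produces —
so the mm/au reading is the physically coherent one, and the fitted
regression of depth (mm) on twitch force (au) recovers the stated
magnitudes. Transverse centres are uniform across the chord at the drawn
depth.

## The depth-condition study

`run_depth_condition_study()` runs, per repetition: build pool → place
units per condition → for each excitation level (10-100%, step 10)
simulate 3 s of discharges → whole-muscle force and single-electrode EMG
→ mean force and RMS on a centred 2 s window → normalise both to the
maximum level (this moves `ln a`, never *b* — a property the test suite
asserts exactly) → fit the log-log slope. Spike trains are shared across
conditions within a repetition, so the comparison is paired. At the
default geometry the condition means are approximately **1.25
(superficial), 1.01 (random), 0.85 (deep)** — ordering and spacing
robust across seeds; the per-condition distributions pass a
Lilliefors-corrected normality check and differ strongly (one-way ANOVA
with Bonferroni post-hocs, all pairwise contrasts significant).

Repetition counts: the package default is 50; the acceptance script and
test suite use 10 per condition, which already pins the condition means
to within ±0.01 (SE of the mean) while keeping a full study run around
half a minute.

## The synthetic grid experiment

`generate_grid_session()` emulates a high-density recording session: a
13-row × 6-column monopolar grid (8 mm pitch, 2048 Hz) centred over the
innervation zone, rows along the fibers (negative z = proximal);
isometric contractions at 20/40/60/80 %MVC, each %MVC target mapped to an
excitation level by root-finding on the noise-free expected force
(`calibrate_excitation_for_mvc()`). The default pool uses the 80%
recruitment range appropriate to large limb muscles.

Subjects differ by geometry seed and a subject-level jitter (SD 0.02) on
the **proximal-distal depth gradient**, the generator's ground truth: a
fiber inclination of `gradient * P/P_max` mm of depth per mm along z, so
large units rise toward the surface proximally. The default gradient of
0.12 mm/mm tilts the largest units by about ±6 mm across the grid span
and produces a proximal-minus-distal slope difference near 0.1 with
paired significance at n = 9 — the magnitude of regional contrast such
experiments report. With the gradient at zero and no jitter the geometry
is mirror-symmetric in z and the regional difference is identically zero;
the subject jitter is what gives the null cohort a proper sampling
distribution. Analysis segments are demeaned per channel before the RMS
(AC-coupled amplifier emulation). Regions follow the conventional blocks:
proximal rows 3-4, distal rows 10-11, lateral columns 1-2, medial columns
5-6 (all configurable via `region_spec()`); the two physical 5-column
arrays such systems use are represented as one logical 6-column grid so
the column blocks are meaningful. The analysis segment is configured in
seconds and defaults to exactly 2 s (4096 samples at 2048 Hz).

What the generator does *not* emulate: electrode-skin impedance and
noise, innervation-zone scatter across fibers, motor unit
synchronisation, fatigue, force tremor beyond ISI variability, layered
conductor boundaries, electrode surface area, and real anatomical
variability beyond the seeded geometry. Passing recovery tests on this
generator therefore shows the *analysis chain* is correct and sensitive
to depth gradients of the modelled kind — not that real biceps data will
show a gradient.

## Numerical choices

* Twitch kernels truncated at `8 T`; MUAP templates end naturally at pole
  extinction. Tilted fibers are clamped so they never pierce the skin.
* The log-log fit is ordinary least squares on `(ln X, ln Y)` via QR
  (`stats::lm.fit`); channels whose fit fails are marked missing in slope
  maps rather than aborting.
* The Wilcoxon signed-rank test drops zero differences, averages tied
  ranks, applies a continuity correction and tie-corrected variance in
  the normal approximation, and reports `r = |Z|/sqrt(n)` with n the
  number of pairs supplied. An exact enumeration mode (all `2^m` sign
  assignments) exists for small samples and is cross-checked against
  brute-force enumeration and `stats::wilcox.test` in the tests.
* Normality is tested with the Lilliefors correction
  (`nortest::lillie.test`) since mean and SD are estimated from the
  sample; the naive one-sample KS p would be conservative.
* All randomness flows from explicit seeds through a deterministic
  seed-derivation chain; identical master seeds give bit-identical study
  results.
* Every waveform container is written as plain text (full-precision CSV +
  JSON sidecars) and round-trips bit-exactly.

## Known limitations

The absolute scale of the simulated potentials is arbitrary (it cancels
in *b*). The homogeneous-conductor tripole is a far-field approximation:
very superficial territories (< 1 mm under the fat layer) are handled by
redraw/clamping rather than by a layered model. The condition magnitudes
depend on unprinted geometry conventions (pole set, electrode offset,
territory density); the package freezes one physically motivated choice
and exposes all of them in configuration.
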