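# emgforce

Simulation and analysis of the **log-transformed surface EMG–force
relation** and its sensitivity to where motor units lie within a muscle.

When a muscle contracts isometrically at a series of levels, the relation
between EMG amplitude (RMS, *Y*) and force (*X*) is summarised by the
log-log regression

```
ln Y = b · ln X + ln a        (equivalently  Y = a · X^b)
```

The slope *b* tells whether EMG grows linearly with force (*b* = 1), faster
(*b* > 1) or slower (*b* < 1). Because surface electrodes see superficial
sources far better than deep ones, *b* carries information about the
*spatial distribution* of motor units: if the large, high-threshold units
sit superficially, EMG accelerates as they are recruited and *b* rises;
if they sit deep, *b* falls below 1. `emgforce` packages both halves of
that argument:

* a **motor neuron pool simulator** — 150 units with exponentially graded
  recruitment thresholds, innervation numbers (22–2137 fibers) and twitch
  forces (1–100 au); linear rate coding from 8 Hz to unit-specific peak
  rates (onion-skin or reverse onion-skin organisation); Gaussian
  inter-spike-interval variability; twitch summation with a nonlinear
  fusion gain,
* a **volume conductor** — cylindrical muscle (24 mm diameter, 3 mm
  fat/skin stand-off, anisotropic conductivity σz = 0.33, σx = 0.06 S/m)
  with each fiber's action potential modelled as two mirrored travelling
  tripoles, summed over fibers into motor unit action potentials and over
  discharge trains into monopolar surface EMG,
* the **slope analysis** — RMS amplitudes, the log-log fit, per-channel
  slope maps on high-density electrode grids, regional means
  (proximal/distal, lateral/medial), Wilcoxon signed-rank tests with
  effect size r = |Z|/√n, one-way ANOVA with Bonferroni post-hocs and a
  Lilliefors-corrected normality check,
* a **synthetic grid-session generator** — emulated isometric contraction
  sessions (13×6 monopolar grid, 8 mm pitch, 2048 Hz, 20/40/60/80 %MVC)
  with a controllable proximal–distal depth gradient as ground truth for
  parameter-recovery studies.

It is aimed at researchers studying EMG–force relations, motor unit
spatial organisation, or validating amplitude-based EMG measures against
a controllable ground truth.

## Worked example

Three depth conditions, same pool, same discharges — only unit placement
differs:

```r
library(emgforce)

study <- run_depth_condition_study(sim_study_config(repetitions = 10,
                                                    seed = 1))
study
#> EMG-force slope study: 10 repetitions per condition
#>   superficial  b = 1.248 +/- 0.014
#>   random       b = 1.006 +/- 0.013
#>   deep         b = 0.853 +/- 0.011
#>   one-way ANOVA: F(2,27) = 2534.23, p = 1.89e-31
```

With the large units superficial, EMG RMS rises faster than force
(*b* ≈ 1.25); random placement is nearly linear (*b* ≈ 1.0); deep
placement saturates (*b* ≈ 0.85). The ANOVA confirms the condition effect;
`study$anova$pairwise` holds the Bonferroni-corrected contrasts.

A synthetic high-density grid cohort with a positive proximal–distal depth
gradient, analysed for regional slope differences:

```r
cohort <- generate_grid_cohort(grid_session_config(duration = 1.5,
                                                   segment = 1, seed = 11))
analyze_grid_session(cohort)
#> Grid study: 9 subjects
#>   whole_array  b = 1.028 +/- 0.065
#>   proximal     b = 1.076 +/- 0.065
#>   distal       b = 0.994 +/- 0.066
#>   lateral      b = 1.025 +/- 0.091
#>   medial       b = 1.025 +/- 0.058
#>   proximal vs distal: Z = 2.61, p = 0.0092, r = 0.87
#>   lateral vs medial:  Z = 0.00, p = 1.0000, r = 0.00
```

The proximal region (where the gradient pulls large units toward the
surface) shows the higher slope; the lateral–medial contrast, which the
generator leaves symmetric, does not reach significance.

A shell front-end wrapping the same functions lives in
`inst/cli/emgforce.R`:

```sh
Rscript inst/cli/emgforce.R simulate-study --out results --reps 10 --seed 7
Rscript inst/cli/emgforce.R generate-session --out sessions --subjects 9 --seed 3
Rscript inst/cli/emgforce.R analyze-session --session sessions --out analysis
```

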