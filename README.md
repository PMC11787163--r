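# swaydyn

Postural sway dynamics under cognitive load and auditory noise.

`swaydyn` is an R package plus a set of analysis drivers for force-plate
posturography in dual-task experiments: standing participants perform a
working-memory task of varying difficulty while auditory white noise is
played or withheld, and the question is how cognitive load and additive
sensory noise shape the center-of-pressure (CoP) trajectory. The package
implements the full analysis chain for such experiments and a synthetic
cohort generator, so every stage runs and is testable without human data.

## What it computes

For each trial with anterior–posterior and medial–lateral CoP components
x(t), y(t) sampled at 200 Hz:

- **Radial sway**: RSᵢ = √(xᵢ² + yᵢ²) after centering each axis on its trial
  mean; the trial average of RS summarises bidirectional sway variability.
- **Band decomposition**: zero-phase 4th-order Butterworth filtering at
  0.3 Hz splits sway into a low-frequency band (sensory-feedback-related
  drift) and a high-frequency band (fast corrective adjustments), each
  summarised by its own mean RS.
- **Detrended fluctuation analysis (DFA)**: the RS series is integrated,
  windowed, linearly detrended, and the fluctuation function F(n) ~ n^α
  yields the scaling exponent α. For healthy standing, 1 < α < 1.5:
  anti-persistent fractional Brownian motion.
- **Condition comparison**: each metric is modelled with a random-intercept
  linear mixed model, `metric ~ stimulus * condition + (1 | subject)`
  (REML), and the six condition × stimulus cells are compared through
  estimated marginal means with Tukey-adjusted pairwise contrasts
  (Kenward-Roger degrees of freedom).

Preprocessing follows the conventions of this literature: the first 4 s of
each 90-s trial are discarded (startle window), and trials whose mean RS
falls more than 2 SD from their subject × condition cell mean are excluded
(one pass).

The package also implements the modified n-back task used as the cognitive
load: sequences of letters (A–Z without X) separated by fixation crosses,
scored by counting lag-1 (Easy) or lag-2 (Hard) repetitions, with the
participant's absolute count error as the performance measure.

The synthetic cohort generator produces anti-persistent fractional Brownian
CoP sway by spectral synthesis (power spectral density ∝ f^(−β) with
β = 2α − 1), calibrated so each trial's mean RS and the DFA exponent of its
radial-sway series hit configurable condition-cell targets, with
subject-level random intercepts and trial-level noise.

## Worked example

```r
library(swaydyn)

# scoring the two documented task examples
score_nback(c("A","A","F","K","R","R","T","P"), lag = 1)            # 2
score_nback(c("A","R","A","K","T","R","T","P","F","P"), lag = 2)    # 3

# a full synthetic study and its analysis
run <- run_pipeline(run_config(input = sway_model_config(seed = 20260926),
                               out_dir = "results/main"))
run$fits$broadband_rs$fixed_effects
```

On the default cohort (28 subjects × 30 trials of 90 s) this prints, for
broadband radial sway:

```
        term estimate     se     df       t         p
1  intercept  6.30377 0.3540  35.71 17.8061 2.425e-19
2      noise -0.98881 0.1970 807.43 -5.0196 6.372e-07
3       easy  0.29205 0.1989 807.37  1.4680 1.425e-01
4       hard  0.95584 0.1946 806.75  4.9107 1.099e-06
5 noise:easy  0.51878 0.2821 808.53  1.8391 6.627e-02
6 noise:hard  0.09911 0.2788 807.46  0.3554 7.224e-01
```

Reading: the baseline (no task, silence) trial-mean radial sway is ≈ 6.3
length units for this cohort draw; auditory noise lowers sway by ≈ 1.0
units (p < 10⁻⁶) while the hard task raises it by a similar amount —
the estimates recover the generator's configured effects (5.726, −1.273,
+0.144, +0.753, …) up to the cohort's sampling variability. The run
directory also holds the analogous tables for low/high-frequency RS and
DFA α, the 15-row Tukey contrast table per response, box-plot figures
(median line, mean dot, min/max whiskers), an exclusion report and a
manifest.

## Analysis workflow

The numbered drivers under `analysis/` narrate the study end to end and
write their outputs under `results/` (and bulky intermediates under
`scratch/`):

1. `01_simulate_cohort.R` — cohort configuration, cell targets, on-disk
   format demo (trial CSVs, design table, YAML config, WAV stimulus).
2. `02_run_pipeline.R` — the full pipeline at study scale.
3. `03_nback_session.R` — task sequence generation, simulated responses,
   absolute-error scoring.
4. `04_parameter_recovery.R` — three replicate cohorts refitted against the
   generating truth.

Run each with `Rscript analysis/0X_*.R` from the repository root.

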