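---
title: "Methods: synthetic sway cohorts and the dual-task analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic sway cohorts and the dual-task analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`swaydyn`: what the synthetic cohort generator emulates and deliberately
does not, how each metric is computed, and where the design was genuinely
open and a choice had to be made.

## The experimental situation being modelled

A participant stands quietly on a force platform for 90-s trials while (a)
performing a modified n-back letter task at one of three levels (none,
easy = lag-1 repeat counting, hard = lag-2) and (b) hearing either silence
or continuous auditory white noise. The platform records the
center-of-pressure (CoP) trajectory at 200 Hz in the anterior–posterior (x)
and medial–lateral (y) directions. A session is 30 trials: 10 per cognitive
condition, with the no-task trials split 4/2/4 into blocks at the start,
middle and end (a fatigue control), the easy/hard blocks counterbalanced,
and stimulus randomised under a 15-noise / 15-silent constraint. The
analysis asks how cognitive load and additive noise shift (i) the overall
magnitude of sway, (ii) its slow and fast components, and (iii) its temporal
correlation structure.

## Metrics

**Radial sway.** RS~i~ = sqrt(x~i~² + y~i~²) per sample. By default both
axes are centered on their trial means first, so RS measures excursion
about the mean stance point; the raw formula contains no centering term,
but its originating definition measures distance from the mean CoP, and an
uncentered radial distance would conflate stance position with sway. The
choice is exposed (`demean`) and recorded in results. The trial mean of RS
is the per-trial summary.

**Band decomposition.** The x and y components are filtered with a
4th-order Butterworth at 0.3 Hz, low- and high-pass, applied
forward–backward for zero phase. Zero-phase filtering squares the magnitude
response (effective order 8); the stated order refers to the one-pass
design. Edges use reflective padding of length `3 × order × rate / cutoff`
samples — at 0.3 Hz and 200 Hz that is 8000 samples (40 s), enough to let
the slow band settle. Whether the *components* or the RS series itself
should be filtered is ambiguous in this literature's shorthand
("filtered high and low frequency RS"); component filtering is the default
because RS is a nonlinear (rectified) functional whose own spectrum mixes
bands, and band-RS is then computed per band — demeaned for the low band
(which keeps the trial offset), not demeaned for the already zero-mean high
band.

**DFA.** First-order detrended fluctuation analysis in the standard
formulation: center, integrate to a profile, split into ⌊N/n⌋
non-overlapping windows from the start for each window size n, detrend each
window by ordinary least squares (linear by default), pool squared
residuals into F(n), and take α as the OLS slope of log₁₀F on log₁₀n. The
window grid is ~16 log-spaced sizes from 10 samples to N/4, fitted over the
full grid. The exact grid used by the posturography papers this mirrors is
not published; all of these parameters are exposed
(`window_sizes`, `detrend_order`, `n_windows`, `two_sided`). The tail
samples that do not fill a window are discarded by default (deterministic,
simple); a `two_sided` flag adds the reversed pass. DFA is applied to the
broadband RS series, not to x or y separately, because the condition
comparison is defined on the dynamics of RS. The profile integration is
applied even though RS is already a displacement-like series: that is the
standard formulation, and it places healthy sway in the fractional-Brownian
interpretive band 1 < α < 1.5 (anti-persistent: successive increments tend
to reverse).

## Preprocessing

The first 4 s of each trial are dropped (startle response to stimulus
onset). A trial is excluded when its mean RS lies strictly more than 2
sample SDs (n−1 denominator) from its cell mean, where the cell is
subject × condition × stimulus. The split by stimulus is a package choice:
the grouping most consistent with the six-cell analysis; the coarser
subject × condition grouping is available via `by_stimulus = FALSE`, and the
report always states the cell used. The rule is one-pass — cell statistics
are computed once, including the candidate trial, and not recomputed after
removals — because an iterative rule is order-dependent and nothing in the
source conventions requires it. Cells with fewer than 3 trials are skipped
(an SD from 2 points is meaningless) with a warning. One shared exclusion
set, computed on broadband trial means, feeds all four response models;
recomputing exclusions per band would let the four analyses see different
trials and complicate any single "trials removed" statement.

## The synthetic cohort generator

No public dataset exists for this design, so the generator is a first-class
module. It emulates exactly the features the analysis measures, and no
more:

- **Fractal sway.** Each axis is synthesised spectrally: random-phase
  Fourier amplitudes with power ∝ f^(−β), β = 2α − 1, inverse-transformed,
  synthesised at twice the needed length and truncated to break circular
  periodicity. This gives direct, well-conditioned control of the DFA
  exponent — the only dynamical property the analysis quantifies. It is
  *not* a biomechanical model: no inverted pendulum, no sensory channels,
  no intermittent control.
- **Exponent calibration.** The DFA exponent of the *radial* series of two
  independent fractal components sits systematically below the component
  exponent (the norm is a rectifying nonlinearity). The generator therefore
  maps the requested radial α target through a quadratic inverse map,
  calibrated once by simulation under the study trial geometry (90 s,
  200 Hz, 4-s trim, default grid), to the component exponent it synthesises
  (`alpha_scale = "radial"`, the default; `"component"` disables the map).
  Residual calibration error is below ~0.01 across the 1.19–1.30 band the
  condition cells occupy.
- **Amplitude calibration.** The per-trial pair is rescaled so the demeaned
  mean RS equals the trial's target exactly. Trial-to-trial spread enters
  through explicit target noise, not through calibration slack: the target
  is cell mean + subject offset + trial noise.
- **Variance components.** Defaults `subject_sd = 1.73`, `trial_sd = 1.70`
  (RS, length units), `alpha_subject_sd = 0.078`, `alpha_trial_sd = 0.096`
  were derived by inverting the standard-error structure of the reported
  study-scale mixed models: with 28 subjects and ~140 trials per cell, a
  fixed-effect SE of ~0.20 on RS implies a residual SD of
  0.203·√70 ≈ 1.70, and the intercept SE of 0.357 then implies a
  between-subject SD of ≈ 1.73; the α model's SEs (0.012, 0.017) give a
  residual SD ≈ 0.100 — of which DFA estimation noise at this trial length
  contributes ≈ 0.03, so 0.096 is injected — and a subject SD ≈ 0.078.
- **Effect defaults.** The condition-cell targets default to the reported
  fixed effects of the study this package mirrors (RS: 5.726 baseline,
  −1.273 noise, +0.144 easy, +0.753 hard, +0.831/+0.458 interactions;
  α: 1.293, −0.098, −0.020, −0.031, +0.063, +0.073). One printed
  easy-condition triplet in that source is internally inconsistent (its t
  statistic duplicates the hard row's); the estimate is used as the
  generator default and the inconsistency is simply noted here. RS units
  are treated as opaque length units (plausibly millimetres); none are
  printed in the source.
- **Axes.** x and y are independent with equal amplitude by default; real
  A–P and M–L sway usually differ in amplitude and are correlated, which is
  why `amplitude_ratio` exists but defaults to 1 — the analysis chain is
  insensitive to the ratio because RS pools the axes.
- **Seeding.** One master seed; per-trial seeds derive from it by a counter
  scheme (`derive_seed`), and the drawn offsets are persisted in the design
  table, so any trial regenerates in isolation.
- **Stimulus.** The auditory stimulus is iid Gaussian noise at a stated RMS
  fraction of full scale, exported as 16-bit PCM WAV; its nominal 75 dB SPL
  playback level is a property of the playback chain and is carried as a
  metadata label only.

Because the generator injects the condition effects directly into the RS
and α targets, a passing parameter-recovery test shows that the *analysis
chain is unbiased for data of this correlation structure and variance
composition* — it does not show that real sway has this structure. In
particular, the generator's band composition (low/high RS split) is a
by-product of the fractal spectrum, not separately calibrated, so the
low/high-frequency models are exercised structurally but their effect sizes
are not targets.

## Statistics

Each response (broadband RS, low-band RS, high-band RS, DFA α) is fitted
with `lmerTest` as `response ~ stimulus * condition + (1 | subject)` by
REML — a random intercept only, since no random slopes are reported in this
design's literature and 10 trials per condition support little more.
Estimated marginal means and the 15 pairwise contrasts among the six cells
come from `emmeans`, with Tukey (studentized-range) family-wise adjustment
and Kenward-Roger denominator degrees of freedom; if `pbkrtest` were
unavailable the code falls back to Satterthwaite *with a warning* and
records the method in `df_method` — results never switch silently.

## Problem sizes and numerical tolerances

The test suite exercises the chain at three scales, chosen as the smallest
sizes at which each property is stable: unit tests use 10–60-s trials and
series of 2¹²–2¹³ samples; exponent-recovery checks average 20 seeds at
2¹³–2¹⁴ samples (the white-noise and Brownian limits are recovered within
0.05 and 0.07, intermediate targets within 0.08); the acceptance-level
parameter-recovery check simulates three replicate cohorts at full study
scale (28 × 30 × 90 s) and requires the replicate-averaged coefficient
estimates to land within 2 SE of the generating truth for all twelve
coefficients of the RS and α models. Filter behaviour is checked against
the closed-form zero-phase Butterworth magnitude response (bilinear
transform with prewarped cutoff) to within 0.01 absolute; DFA agrees with a
naive window-by-window reference implementation to 10⁻⁹ on shared grids and
is affine-invariant to the same tolerance.

Degenerate inputs fail loudly rather than silently: constant series in DFA
(F(n) = 0), trials shorter than the trim window, cutoffs at or above
Nyquist, empty design cells in the mixed model, infeasible n-back target
counts.

## Known limitations

- The sway model is phenomenological; it cannot support inference about
  mechanism (stochastic resonance, attentional arousal, reinvestment),
  only about the measurement/analysis chain.
- The α calibration map is tied to the default trial geometry; for very
  different durations or grids the map extrapolates and cell-level α
  targets may drift by a few hundredths.
- Exclusion rates in synthetic cohorts (< 1% at defaults) are lower than
  plausible human rates, because the trial-mean distribution is thin-tailed
  by construction; the exclusion *rule* is fully exercised regardless.
- The n-back response model (rounded Gaussian error, truncated at zero)
  matches only the spread of real self-reports, not their shape or bias;
  nothing downstream depends on it.
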