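---
title: "Concurrent biomechanical and physiological fatigue analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concurrent biomechanical and physiological fatigue analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runfatigue)
```

## The scientific problem

Prolonged running induces acute fatigue that manifests simultaneously in
the musculoskeletal system (how the runner moves) and the cardiovascular
system (how the heart beats). Wearable sensors make both visible in the
field: a foot-mounted inertial unit resolves each gait cycle, a chest
strap or ECG patch yields the beat-to-beat RR interval series, a GNSS
receiver supplies speed and elevation, and periodic rating-of-fatigue
(ROF) prompts on a 1--10 scale anchor the perceived state. The analysis
question is twofold:

1. Do biomechanical and physiological parameters evolve systematically
   over a race, and does that evolution track perceived fatigue?
2. Are the two families coupled -- do gait parameters co-vary with
   heart-rate dynamics within race segments?

`runfatigue` implements the full chain for this question: a synthetic
multi-sensor race generator with exact ground truth, ingest and
synchronization, heart-rate dynamics and gait-mechanics feature
extraction, race segmentation against the ROF log, a non-parametric
statistical battery with mixed-effects modelling, and a
linear-plus-distance-correlation association stage.

## The synthetic cohort

Because field recordings of this kind are scarce and carry no usable
ground truth, the package ships a generator (`sim_config()`,
`simulate_subject()`, `simulate_cohort()`) whose default emulates a
13-runner half-marathon cohort with finishing times spanning roughly
82--118 minutes, so that five runners fall under the 90-minute "fast"
threshold and five over the 105-minute "slow" threshold.

Per subject the generator produces:

* **RR intervals** -- baseline around 0.42 s with a downward linear
  drift (`rr_drift_slope = -0.05` s per race fraction, i.e.
  cardiovascular drift of roughly +12% heart rate), sinusoidal LF
  (0.1 Hz) and HF (0.3 Hz) modulation, and fractional-Gaussian-noise
  beat-to-beat variability with a target short-term DFA exponent
  `hurst_alpha_target = 0.75`. Optionally 2% of beats are perturbed
  into missed/extra-beat artifacts (halved or doubled intervals), the
  classic chest-strap failure mode.
* **ECG** -- a template-based trace at 250 Hz built from the beat
  times, with additive white noise at a configurable SNR; "SNR" here is
  the ratio of signal power to noise power over the whole trace, in dB.
* **Gait cycles** -- one row per right-foot stride at 85 strides/min,
  with contact time `t_c`, flight time `t_f`, foot strike/end angles,
  swing angular velocity and trunk acceleration ratios, each following
  a linear fatigue trend plus white noise. Default trend signs follow
  what is commonly reported for prolonged running: contact time and
  anteroposterior trunk acceleration up (+5%, +10%), flight time, foot
  strike angle and swing velocity down.
* **Foot and chest IMU traces** (optional) built around those cycles,
  with a configurable clock offset (`sync_lag = 0.35` s) between chest
  and foot sensors for the synchronization stage.
* **GNSS track** at 10 Hz along a great-circle-ish course with optional
  climbing sections specified as (start, length, grade%).
* **ROF schedule** -- integer ratings at fixed prompt intervals
  (600 s in the emulated protocol), non-decreasing from 3 to 9 by
  default.

Everything is deterministic given the master seed: per-subject,
per-signal substreams are derived from it, and two runs of the full
pipeline are byte-identical (`serialize()`-level).

**Realism limits.** The generator is a statistical emulator, not a
biomechanical simulator: trends are linear, noise is stationary within
a run, the ECG is template-based (no morphology change with fatigue),
and ROF is a deterministic schedule rather than a perceptual model. It
is designed so that every downstream estimate has a known target -- not
so that individual traces would fool a physiologist.

## Ingest and synchronization

* `estimate_lag()` aligns chest and foot streams by cross-correlation of
  their resampled envelopes; the sign convention is the shift that must
  be *added* to the second stream's clock to match the first.
* `haversine_m()` / `detect_slopes()` compute great-circle distances and
  flag course sections whose smoothed grade strictly exceeds 5% over a
  100 m window; flagged intervals are excluded from all parameter
  streams (`exclusion_mask()`, `exclude_intervals()`), because climbing
  mechanics would otherwise masquerade as fatigue.
* `remove_outliers_2sd()` replaces per-segment outliers beyond 2 SD
  with the segment median, the standard cleaning step for stride
  parameters.

## Heart-rate dynamics

`hr_features()` slides 120 s windows with 110 s overlap (10 s step)
over the RR series and computes, per window:

* time-domain: mean BPM, SDNN, RMSSD;
* frequency-domain: Lomb-Scargle power in LF (0.04--0.15 Hz) and an HF
  band widened to 0.15--1.5 Hz because breathing frequency during
  running far exceeds the resting 0.4 Hz convention; `pLF + pHF = 1` by
  construction;
* non-linear: Poincare SD1/SD2 and DFA short- and long-range exponents
  `DFA_a1` (box sizes 4--16) and `DFA_a2` (16--64), with the
  finite-size correction `F(n)/sqrt(1 - 4/n^2)` that removes the
  small-box bias of detrended fluctuation analysis;
* cardiac cost: beats per metre when a speed stream is available.

Two conventions deserve a note. SD1 uses the root-mean-square of
successive differences divided by `sqrt(2)` (a zero-mean convention),
which makes the identity `SD1 = RMSSD / sqrt(2)` exact rather than
approximate. And a window is valid only when the fraction of
artifact-flagged beats is strictly below 5%.

`detect_qrs()` recovers beat times from ECG via a squared-derivative
energy envelope with a MAD-adaptive threshold, a 250 ms refractory
period, and a second plausibility pass that drops detections whose
enhanced-peak height falls below 10% of the median detected height
(true and false peaks separate by orders of magnitude). `correct_rr()`
flags physiologically implausible intervals and successive-ratio
outliers and replaces them by local medians.

## Gait mechanics

`vertical_stiffness()` implements the sine-wave spring-mass
approximation from contact time, flight time and body mass:

* peak force `F_max = m g (pi/2) (t_f/t_c + 1)`,
* CoM displacement `dz = F_max t_c^2 / (m pi^2) - g t_c^2 / 8`,
* `k_vert = F_max / dz` (reported in kN/m).

Since `dz` is mass-independent, `k_vert` is exactly proportional to
mass. `temporal_params()` derives stride, step, duty-factor and
cadence conventions from the cycle table; `trim_steps()` removes the
first and last 10 strides (acceleration and deceleration phases).

## Race segmentation and the fatigue designs

`split_race()` cuts the race into 8 equal-duration segments (half-open
intervals, last one closed). `aggregate_segments()` reports per-segment
medians and IQRs; `normalize_segments()` expresses each parameter
relative to its first-segment median so subjects are comparable.
The ROF log maps onto segments three ways:

* **segments** design: S1 vs S5 vs S8;
* **rof_levels**: pooled Low/Mid/High ROF tertiles;
* **drof_states**: change-from-baseline states 0, [1,2], [3,4], >= 5.

## Statistics

`friedman_W()` is the tie-corrected Friedman test with Kendall's
`W = chi^2 / (n (k-1))` as effect size. `wilcoxon_es()` is the paired
signed-rank test reporting `|Z|/sqrt(N)`; the p-value uses the exact
signed-rank distribution for tie-free samples up to N = 50 (the normal
approximation is off by up to ~0.009 at N = 12) and the tie- and
continuity-corrected normal approximation otherwise. Stars follow the
usual `*` / `**` / `***` convention at 0.05 / 0.01 / 0.001.

`fit_lme()` fits `responder ~ drof * performance + (drof | subject)` by
maximum likelihood (lme4), refitting with a random intercept only when
the slope model is singular. Intervals and p-values use a *t* reference
with subject-level degrees of freedom (subjects minus two): plain
Wald-z intervals undercover noticeably at 10--13 subjects. Conditional
and marginal R-squared follow the variance-partition formula.

## Association analysis

For each of the default 5 x 4 = 20 (gait, heart-rate) parameter pairs,
per subject and segment, `align_series()` averages the dense gait
stream onto the 10 s heart-rate window grid and `association_records()`
stores Pearson r with its p-value plus the distance correlation
(`distance_correlation()`, the biased V-statistic form), which also
captures non-monotone coupling that Pearson misses entirely -- e.g. a
symmetric quadratic has r = 0 but dCor > 0.3.

## Problem sizes

The package's own default problem sizes are chosen for a desk-scale
rerun: the `analysis/` drivers simulate 13 runners at 20-minute race
length (the generators and features scale linearly, so full-length
races only cost proportionally more time), while `scripts/acceptance.R`
runs the full-length 13-runner cohort in a few minutes. Calibration
checks (DFA exponents, test sizes, interval coverage) use 100--500
Monte-Carlo replicates, enough to pin means to a few percent.

## A minimal worked example

```{r example}
cfg <- sim_config(n_subjects = 2, race_duration = c(600, 620),
                  rof_interval_s = 60, seed = 7)
cohort <- simulate_cohort(cfg)
an <- analyze_subject(cohort[[1]])
head(an$sfm[an$sfm$parameter == "t_c",
            c("segment", "median", "normalized", "rof", "delta_state")])
```

Contact time rises across segments while the normalized column shows
the relative drift; the cohort-level battery, mixed models and
association summary come from `analyze_cohort(cohort)`.

## Limitations

Results on synthetic data validate the *estimators*, not the
physiology; effect sizes produced by the default generator are by
construction large and clean compared to field recordings. The slope
exclusion assumes GNSS elevation good to a few metres; the mixed model
assumes linearity of the responder in delta-ROF; and the association
stage treats segments as independent replicates, which overstates
degrees of freedom if within-subject autocorrelation survives the
segment cut.
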