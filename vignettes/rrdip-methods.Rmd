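---
title: "Detecting respiratory-related heart-rate changes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting respiratory-related heart-rate changes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrdip)
```

## The physiological signal and the screening problem

Obstructive and central respiratory events during sleep end, typically,
with a burst of sympathetic activation: the heart transiently
accelerates, which in the ECG appears as a short run of shortened R-R
intervals (an "RRI dip" in the tachogram) and in the pulse-oximeter
pulse-rate trace as a brief rise in beats per minute. Counting these
accelerations over a night gives a severity index that tracks the
polysomnographic apnea-hypopnea index (AHI) while needing only a heart
rate signal — attractive for screening, because pulse rate is available
from home sleep tests and wearables where full polysomnography is not.

`rrdip` implements this detector and everything needed to validate it:
readers for the relevant formats, the detection engine, linkage of
detections to pre-scored respiratory events and arousals, the four
severity indices, a synthetic study generator with known ground truth,
and the agreement statistics (ICC, Bland-Altman, kappa, ROC) used to
compare an index against AHI over a cohort.

## The detection algorithm

Given a beat-to-beat interval series (ms against seconds from recording
start), detection proceeds in five deterministic stages:

1. **Segment baselines.** The recording is cut into fixed, non-overlapping
   1-minute windows anchored at time 0. The baseline of each beat is the
   mean interval of the non-artifact beats in its window. Windows with
   fewer than 3 valid beats provide no baseline; their beats cannot be
   marked. The final partial window is used as-is under the same rule.
2. **Relative-threshold marking.** A beat is marked when its interval is
   *strictly* below `threshold_fraction` times its baseline — 0.90 for
   ECG-derived RR intervals, 0.95 (a 5% acceleration) for pulse-derived
   intervals. A beat exactly at the threshold is not marked.
3. **Grouping with singleton rejection.** Maximal runs of consecutively
   marked beats form candidate groups; runs shorter than
   `min_consecutive` (default 2) are noise — counted, marked, and never
   analyzed further. Artifact beats are never marked and therefore break
   runs.
4. **Merging.** Adjacent groups whose gap (first marked-beat time of the
   later minus last marked-beat time of the earlier) is strictly less
   than 10 s are unioned, transitively left to right. Beats between
   merged groups are absorbed into the span but are not re-marked, and
   rejected noise beats stay excluded — in particular they can never
   host the extremum of a merged group.
5. **Extremum selection.** Each merged group contributes exactly one
   event: the marked beat with the smallest interval, earliest beat on
   ties.

The index is the event count divided by total *recording* time in hours
(the AHI denominator, by contrast, is total sleep time). Linking a
detection to a scored respiratory event uses the nadir beat as anchor: a
dip is respiratory-related when its nadir lies in the half-open window
`[start, start + duration + 30 s)`; when several windows cover the nadir
the nearest preceding event wins. Arousal linkage applies the same rule
to arousal records, with the same default 30-s window — the symmetric
choice, since no separate arousal window is established; it is
configurable and recorded in run manifests.

Four indices result per study: total and respiratory-related RRDI (from
ECG) and HRAI (from pulse rate), plus the arousal-related pair.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold_fraction` | 0.90 (RRI), 0.95 (pulse) | relative dip depth that counts |
| `segment_length` | 60 s | baseline window |
| `merge_gap` | 10 s | strict merge distance between groups |
| `min_consecutive` | 2 beats | singleton-noise rejection |
| `post_window` | 30 s | linkage window after event end |
| physiological limits | 300–2000 ms | artifact flagging (30–200 bpm) |
| quality gate | 0.10 | maximum unanalyzable fraction of TRT |

All thresholds are strict (`<`), matching the convention "below 90%".
The 0.95 pulse threshold is applied to the converted intervals
(`60000 / HR`); the alternative reading — HR more than 5% above baseline
HR, i.e. an interval threshold of `1/1.05 = 0.9524` — is available via
`detector_params(hr_relative = TRUE)`. The default follows the
convert-then-analyze order of operations. On intervals the 0.95 rule is
algebraically a "HR rise above 5.26%" rule, which the test suite checks
pointwise.

The physiological limits 300–2000 ms are a configurable default: the
upstream procedure this implements sets per-study limits during visual
review, which a library cannot reproduce; 30–200 bpm brackets plausible
sleeping heart rates with margin. Artifacts are flagged, never deleted,
so every beat remains auditable and baselines can exclude them
explicitly.

**Quality gate.** `quality_fraction()` measures the fraction of
recording time covered by artifact-flagged beats plus inter-beat gaps
longer than 3 s; `run_detect()` rejects studies above 0.10. The 3-s
per-gap criterion operationalizes "unanalyzable signal" at the series
level: a stretch with no credible beats for 3 s cannot contribute a
baseline or a dip.

## What the synthetic generator emulates — and what it does not

`simulate_study()` builds an overnight study in which every downstream
quantity has known ground truth: scored respiratory events (Poisson
placement thinned by a refractory margin so events never overlap),
event-locked heart-rate responses (a run of `dip_width_beats` beats at
`dip_depth` of baseline, starting a uniform lag after event end, inside
the 30-s linkage window), arousal-locked and spontaneous responses
placed outside every event's linkage window, Gaussian beat noise, and
signal-dropout bursts of non-physiological intervals. The pulse trace is
derived from the tachogram by 1-Hz sampling of instantaneous heart
rate, so ECG- and pulse-based detection can be compared on one study.

Defaults describe a moderately severe overnight study: 8 h recording,
15 events/h, 90% response probability, depth 0.85 × baseline over
4 beats (about a 18% momentary heart-rate rise, typical of
post-event sympathetic bursts), lags of 5–20 s (circulatory delay),
2 spontaneous responses/h, 5 arousals/h, 25 ms beat noise on a 1000 ms
baseline, 1% per-beat dropout-burst probability.

Three deliberate idealizations make ground truth exact, and they bound
what passing tests prove:

* **Separation by construction.** Responses are spaced by more than the
  merge gap and spontaneous responses avoid linkage windows, so on
  noise-free settings recall, precision and linkage are exactly 1 and
  any deviation is a detector defect. Real nights have overlapping
  physiology; the detector's merge rule then *defines* the event count
  rather than recovering a unique truth.
* **Step responses.** The planted response is a step drop in intervals,
  not a smooth physiologic curve. The detector is threshold-based and
  insensitive to response shape, so this exercises every code path, but
  timing precision on smooth responses is untested.
* **Truncated noise.** Beat noise is clipped at ±8% of baseline so that
  noise alone never crosses the 90% threshold; only planted structures
  generate detections. Real tachograms contain respiratory sinus
  arrhythmia and ectopy that produce genuine spontaneous sub-threshold
  runs; the spontaneous-response rate stands in for these explicitly.

Consequently, passing the clean-recovery suite shows algorithmic
correctness, not field performance on clinical recordings; the
cohort-level statistics of clinical datasets are not reproducible from
synthetic data and are out of scope for the test suite.

`simulate_cohort()` draws per-study AHI from the three-bin severity
mixture (11% / 31% / 58% for below 5 / 5–15 / above 15 events/h, the
composition of a large community validation sample), with demographics
to match (age ≈ 62 ± 9, 39% male, BMI ≈ 28 ± 5, TRT ≈ 7.8 h). By
default, per-study index values come from a calibrated response model
(detected responses ≈ response probability × events during sleep over
recording time, plus spontaneous and arousal contributions with more
dispersion for the ECG index); with `simulate_signals = TRUE` each
study is synthesized and run through the full pipeline. The default
keeps cohort-scale statistical tests fast while preserving the
structural relations (RE index ≤ total index, index tracks severity);
the signal-backed mode is exercised on small cohorts in the tests.

## Statistical machinery

* **Confusion matrices** over half-open severity bins `[lo, hi)` at the
  conventional AHI cuts 5/10/15/30; collapsing to 2×2 at any pair of
  bin-edge cutoffs is pure cell summation, so totals are conserved.
* **Diagnostics**: sensitivity, specificity, PPV, NPV, percent
  agreement, and Cohen's kappa from the marginals. Zero-denominator
  ratios are reported `NA`, never 0.
* **ICC**: the absolute-agreement single-measurement form under a
  two-way random-effects model — ICC(A,1) — from the two-way ANOVA mean
  squares with the F-based confidence interval. The form is recorded in
  the output; interpretation bands are below 0.50 poor, 0.50–0.75
  moderate, 0.75–0.90 good, above 0.90 excellent. The implementation is
  cross-checked against an external reference on a frozen fixture.
* **Bland-Altman**: differences as estimate − reference, limits at
  mean ± 1.96 SD.
* **ROC/AUC** by the midrank Mann-Whitney statistic, which equals the
  trapezoidal area and is invariant under monotone transformation of
  the score — the reason a single-predictor logistic ROC and the rank
  formulation coincide. The installed `pROC` package serves as an
  independent cross-check in the tests, never as the implementation.
* **Correlations**: Pearson/Spearman with asymptotic two-sided p-values;
  covariate adjustment (age, BMI, sex) by residualising both variables
  on a linear model (ranks first for Spearman), with
  partial-correlation degrees of freedom.

## Numerical choices and degenerate inputs

* All comparisons at the thresholds are strict; boundary cases (a beat
  at exactly 90%, a 10.0-s gap, a nadir at exactly event end + 30 s, a
  singleton mark) are pinned by tests.
* Nadir ties resolve to the earliest beat — determinism over any
  physiological claim.
* Empty series yield quality fraction 1 (fully unanalyzable); an
  all-gap pulse series is an error, not an empty result.
* EDF signals are encoded as 16-bit integers with per-signal physical
  scaling; round-trips are exact to within one quantization step of the
  signal's range. Constant signals get an artificial 1-unit physical
  range to avoid division by zero.
* Windows are anchored at recording time 0. Anchoring at lights-off is
  a plausible alternative; it changes window membership for a handful
  of beats per study and is not exposed as an option.

## Problem sizes used in the validation suite

The bundled validation suite runs the detector-vs-reference comparison
on 1000 random series of 1–10 minutes, clean planted-event recovery on
one 8-h synthetic night (~28,800 beats, ~100 events) for both signals,
ICC/AUC/limits calibration at n = 1000 pairs, and cohort machinery at
n = 400 studies; the whole suite completes in well under a minute of
CPU. These sizes give the stochastic checks comfortable margins (for
example, ICC recovery at n = 1000 pairs has a standard error around
0.02 against a ±0.05 band) while staying quick to re-run.

## Known limitations

* Respiratory events and arousals must be pre-scored; the package
  attributes heart-rate responses to them but never scores airflow or
  EEG itself.
* Arrhythmias are not classified. Atrial fibrillation or frequent
  ectopy inflates any interval-threshold index; the quality gate and
  the physiological limits catch gross noise, not rhythm pathology.
* The R-peak detector is a plain amplitude/refractory peak picker,
  adequate for clean single-lead ECG and the stylized test signals; it
  is not a clinical QRS detector.
* The generator's realism caveats above: validation on synthetic data
  bounds correctness, not clinical accuracy.
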