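---
title: "Hypertension screening from ballistocardiogram signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypertension screening from ballistocardiogram signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ballistocardiography (BCG) records the micro-vibrations the body produces
each time the heart ejects blood. Pressure sensors built into a mattress
pick these vibrations up without electrodes or skin contact, which makes
BCG attractive for long-term, home-based cardiovascular monitoring.
`bcgscreen` implements a complete screening pipeline that takes
multi-channel 100 Hz BCG recordings labeled *hypertensive* or
*normotensive* and trains classifiers to separate the two groups from
summary statistics of short signal windows.

Because clinical BCG recordings of this kind are not publicly available,
the package ships a synthetic generator that plays the role of the data
source. Everything downstream — preprocessing, feature extraction, the
classifiers and the validation harness — is written for real recordings
and merely *tested* on synthetic ones.

## The synthetic generator

`generate_recording()` builds each channel as a sum of five components:

* **heartbeat complexes** — a Gaussian-windowed 7 Hz cosine (sd 30 ms),
  one per beat, a deliberately minimal stand-in for the BCG IJK complex.
  It reproduces the 1–50 Hz band that the preprocessing filters target
  without claiming morphological fidelity. Beat times follow a
  quasi-periodic process: the recording's heart rate is drawn from the
  class distribution, and each period is jittered by a Gaussian with sd
  equal to 3% of the period;
* **respiration** — a 0.25 Hz sinusoid (amplitude 0.3) with random phase;
* **slow drift** — two sinusoids at 0.03 and 0.07 Hz (total amplitude
  0.3), emulating postural baseline movement;
* **broadband noise** — white Gaussian noise, sd 0.15;
* **artifacts** — 100 ms half-sine bursts of amplitude ±5, Poisson in
  time at 2 per minute, shared across channels like real whole-body
  movements.

The two classes differ only in heart rate (normotensive 73.6 ± 8.3 bpm,
hypertensive 77.1 ± 9.2 bpm — the clinical values reported for mattress
BCG cohorts) and in beat amplitude (1.0 vs 1.5). The amplitude separation
is what makes the cohort learnable: per-recording and per-channel min–max
normalisation later removes absolute scale, but a larger beat-to-noise
ratio survives normalisation as a different signal *shape* (higher
kurtosis, different spread statistics). A heart-rate shift of 3.5 bpm
against an 8–9 bpm between-subject sd is, by itself, nearly
uninformative — exactly as in real cohorts.

What the generator does **not** emulate: realistic IJK morphology and its
beat-to-beat variability, sensor-specific transfer functions, apnoea or
posture changes, or any within-class physiological covariates (age, BMI).
A passing test suite therefore demonstrates that the pipeline's machinery
is correct and that its classifiers can recover a known class signal; it
does not certify clinical performance on real recordings.

`null_config()` gives both classes the normotensive parameters. Cohorts
generated from it carry no class signal at all and are used to verify
that every model evaluates at chance — a guard against leakage anywhere
in the pipeline (e.g. segment twins straddling a split).

## Preprocessing

`preprocess_recording()` applies four stages in a fixed order:

1. **Filter cascade** — 4th-order Butterworth high-pass at 1 Hz, then
   low-pass at 50 Hz. Both are applied forward–backward
   (`signal::filtfilt`) so the waveform timing is untouched; the package
   pads with odd reflection before filtering to keep edge transients away
   from the data. A 50 Hz cutoff equals the Nyquist frequency at 100 Hz
   sampling and is unrealizable, so it is clamped to 0.99 × Nyquist
   (49.5 Hz) with a warning — the intent (remove high-frequency noise) is
   preserved while the design stays well-posed.
2. **Anomaly removal** — per channel, samples strictly above
   `mean + 2·sd` (population sd, computed on the whole recording before
   masking) are flagged. The rule is one-sided by design: large negative
   excursions are left alone. Flagged samples are replaced by linear
   interpolation between the nearest clean neighbours, which preserves
   the uniform grid the later filters require. A paper-literal `drop`
   mode that deletes rows is provided, but the downstream filter stages
   refuse the resulting non-uniform recording.
3. **Baseline correction** — a second high-pass at 0.5 Hz removes
   residual respiratory and postural wander.
4. **Min–max normalisation** — per recording and channel onto `[0, 1]`;
   a constant channel maps to all zeros by convention.

## Features

Recordings are cut into non-overlapping 30-s windows (3,000 samples at
100 Hz; a trailing remainder is dropped) and each window is summarised,
per channel, by 11 statistics: mean, standard deviation, median, maximum,
minimum, range, Q1, Q3, IQR, kurtosis and skewness. Conventions, fixed so
tests are bit-stable: population (divisor-*n*) central moments, Fisher
excess kurtosis `m4/m2² − 3`, Fisher–Pearson skewness `m3/m2^{3/2}`
without small-sample correction, linear-interpolation quantiles, and
shape statistics of a constant channel defined as 0. Channels are
concatenated (two channels give 22 features per segment) rather than
averaged, to preserve information.

Before any model sees the features they are standardised to zero mean and
unit variance with parameters fitted on the training side only
(`standardize_features()`); a constant column's sd is treated as 1.

## Classifiers

Four families are implemented. The two neural models are written from
scratch in R (forward pass, analytic backpropagation, Adam) with a small
compiled kernel for the optimiser update; their gradients are verified
against central finite differences in the test suite.

**FC + LSTM network.** `x → FC(512) → ReLU → FC(256) → two-layer LSTM
(hidden 128) → FC(64) → Dropout(0.1) → FC(2)`. The 256-unit projection is
reshaped into a sequence for the LSTM; since no tokenization is inherent
in tabular features, the default sequence length is 1 (the whole
projection as one step), with `lstm_seq_len` exposing longer reshapes
(any divisor of 256) through a full BPTT implementation. Training:
cross-entropy, Adam at lr 0.001, 50 epochs, batch 32, with the rate
multiplied by 0.1 every 10 epochs.

**Transformer encoder.** `x → linear embedding to 256 → Dropout(0.1) → 3
encoder layers (4-head self-attention, 512-unit feed-forward, post-norm
residuals, LayerNorm) → mean pooling over tokens → FC(2)`. By default the
feature vector is a single token — attention weights then collapse to 1
and the encoder acts as a residual MLP — while `tokenize = "per_feature"`
feeds one token per input feature through the full attention mechanism
(both modes share one implementation and one gradient check). No
positional encoding is used; it would be meaningless at sequence length 1
and the per-feature mode treats features as an unordered set. Training:
cross-entropy, Adam at lr 0.0005, 50 epochs, batch 32, rate halved after
3 epochs without improvement of the training loss.

**Stacking.** Base learners: random forest (100 trees), a classic
gradient-boosting machine (shallow depth-3 trees, shrinkage 0.1, no
column subsampling — realised via xgboost with the regularisation
disabled), and extreme gradient boosting with its usual defaults. The
logistic-regression meta-learner is fitted on out-of-fold base
probabilities from 5-fold cross-fitting, so it never scores a row its
inputs were trained on. (The two probability columns per base sum to one;
the aliased columns are dropped automatically by the GLM fit.)

**Soft voting.** The same base pool, probabilities averaged uniformly;
ties at 0.5 resolve to the negative (normotensive) class.

Hypertensive is class 1 (positive) throughout.

## Validation and metrics

`evaluate_model()` supports hold-out validation at any test fraction
(50% and 25% being the canonical settings) and stratified k-fold
cross-validation (5 and 10). Splits are **group-aware by default**: all
segments of one recording land on the same side. Thirty-second segments
of one night's recording are near-duplicates, and letting them straddle a
split inflates every metric; segment-level splitting remains available
via `group_aware = FALSE` for comparison. Cross-validation reports
per-fold metrics and their unweighted mean.

Metrics are computed from the confusion matrix with the positive class
hypertensive: accuracy, precision, sensitivity, specificity, F1, Jaccard
score, and Cohen's kappa `(Po − Pe)/(1 − Pe)`. ROC curves enumerate all
score thresholds; the AUC is the trapezoidal integral, which equals the
Mann–Whitney rank statistic with ties counted one half — the test suite
asserts that identity to 1e-10. `compare_models()` runs McNemar's paired
test on the discordant error counts, `χ² = (b − c)²/(b + c)` with 1 df,
continuity correction off by default and `b + c = 0` giving p = 1.
Degenerate 0/0 rate cases return 0 rather than erroring so that
cross-validation loops survive a pathological fold.

## Numerical and design choices

* Neural weights start from uniform `(−1/√fan_in, 1/√fan_in)` draws under
  a seeded RNG; every stochastic element (initialisation, shuffling,
  dropout, splits, the generator) derives from a single user seed through
  a fixed integer derivation, so identical configurations reproduce
  byte-identical feature tables and identical eval-mode predictions.
* LayerNorm uses eps 1e-5; dropout is inverted (scaling at train time);
  softmax is computed with the row-max subtracted.
* The plateau scheduler monitors the *training* loss (no validation split
  exists inside a fold) with patience counted in epochs.
* Quantile and moment conventions are stated above and frozen by tests.
* Ties in the voting argmax resolve toward class 0; the same rule applies
  wherever probabilities are thresholded.

## Problem sizes used by the tests

The learnability checks train on a cohort of 30 recordings per class of
5 minutes each (600 segments); the null-cohort checks use 30 recordings
per class of 2.5 minutes (300 segments) so that a full five-model 5-fold
cross-validation stays comfortably inside a desk-scale run. These sizes
are the package's own choice of a realistic desk-scale experiment; the
acceptance script prints the sizes it used alongside every number it
reports.

## Known limitations

* The beat template is schematic; none of the features exploit beat-level
  timing (no heart-rate-variability features), matching the pipeline's
  statistical-feature design.
* Only the enumerated time-domain statistics are implemented; no
  frequency-domain features.
* The stacking meta-learner is a plain GLM; no calibration analysis or
  confidence intervals beyond the listed metrics.
* With a single token the Transformer's attention is degenerate by
  construction; the per-feature mode exercises real attention but is not
  the default because no token order is defined for tabular features.
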