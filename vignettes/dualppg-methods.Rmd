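---
title: "Dual-wrist PPG blood-pressure estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-wrist PPG blood-pressure estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualppg)
```

## The measurement problem

Cuffless continuous blood-pressure monitoring from a wrist wearable faces a
well-known obstacle: the photoplethysmogram (PPG) depends not only on
hemodynamics but on skin tone, tissue optics, and how tightly the device is
worn, so models trained on one group of people transfer poorly to new
subjects. The approach implemented here attacks the problem with *dual* PPG
sensors on the palmar and dorsal sides of the same wrist. Both sensors share
the subject- and wear-specific optical conditions, so the **difference of
their DC (baseline) components** cancels those personal offsets while
retaining stroke-volume-related information: the two measured arterioles are
branches of the same interosseous artery, and the split of flow between them
reflects cardiac output. Systolic pressure (SBP) rises with stroke volume;
diastolic pressure (DBP) tracks peripheral resistance, which shapes the
pulse waveform (dicrotic notch timing and amplitude, waveform K value).
Contact pressure and skin temperature, read by interface sensors co-located
with each PPG sensor, are confounders of the optical signal and are measured
and fed to the model as compensating inputs.

The estimator is deliberately simple: per 10-s analysis window (shifted by
2 s, so an estimate appears every 2 s) a feature vector is assembled and a
small multilayer perceptron maps it to SBP or DBP. The SBP model uses 11
inputs — the dual-channel baseline difference, two contact pressures, two
skin temperatures, heart rate, and the subject's physical characteristics
(age, height, weight, BMI, sex). The DBP model appends the 7 pulse-waveform
features (cardiac period CP, systolic time ST, diastolic time DT, ST/DT,
systolic/diastolic area ratio, K value, AC/DC ratio), 18 inputs in total.

## Synthetic sessions: what the generator emulates

No public recording of this device exists, so the package ships a
first-class synthetic session generator (`simulationConfig()`,
`generateCohort()`) whose role is to produce data with the statistical
structure the method assumes, together with the exact ground truth needed to
score every stage. Each session draws a latent hemodynamic state — stroke
volume SV (mL), peripheral resistance index R, heart rate, contact pressures
(Pa), skin temperatures (deg C) — around subject-level means, and builds:

* **PPG channels (1 kHz, ADC counts):** `alpha_subj + beta_ch * SV +
  gamma * P_contact + A_ch * SV * pulse(t) + drift + noise`. The subject
  optical offset `alpha_subj` (SD 1500 counts by default) is common to both
  channels, so the dorsal-minus-palmar baseline difference cancels it
  exactly — the simulator-level statement of the differential-sensing claim.
  A multiplicative-gain mode exists for stress testing. Respiratory drift is
  a 0.25-Hz sinusoid common to both channels (one respiration source);
  white noise at SD 3 counts gives roughly 20 dB SNR against the pulsatile
  component.
* **Beat morphology:** each cycle is the sum of two positive compact-support
  lobes — a quadratic percussion bump on `[0, fn * T]` and a beta-shaped
  (1.4, 2.6) dicrotic bump on `[fn * T, T]`. The notch fraction
  `fn = 0.22 + 0.09 R` (clamped to [0.25, 0.45]) and the dicrotic/percussion
  amplitude ratio `0.6 R / (1 + R)` both increase with peripheral
  resistance, so the waveform features carry recoverable information about
  R. Because the waveform is exactly zero at onset, notch and end, the true
  fiducial times are known analytically — they are the oracle for the beat
  detector.
* **Interface sensors (125 Hz):** voltage `V = Vsat (1 - exp(-P / p0))`
  (Vsat = 1 V, p0 = 2000 Pa), a monotone saturating response over the
  0-4 kPa wear range, plus noise; temperature channels are the latent skin
  temperatures plus noise.
* **Ground-truth blood pressure:** the forward model
  `SBP = 40 + 0.8 SV + 0.2 HR - 1.5 (T - 33) + 0.002 (Pp + Pd) + eps`,
  `DBP = 20 + 40 R + 0.15 HR - 1.0 (T - 33) + eps`, `eps ~ N(0, 2 mmHg)`
  per window. The coefficients are simulator choices encoding the
  qualitative physiology (SBP up with stroke volume, down with skin
  temperature; DBP up with peripheral resistance), not measured values.
  Cuff reference readings are emitted at the 2-s window cadence — denser
  than a real cuff, a deliberate simplification so every window has a
  nearby reference. An optional per-subject intercept (`subjectBpSd`,
  default 0) can inject subject-level physiology invisible to the sensors
  for stress tests.

Cohort defaults (18 subjects, ages ~N(25, 3), BMI ~N(21.1, 2.6), 70% male,
4 sessions each of 120 s) mirror a small healthy-adult study. What the
generator does **not** emulate: motion artifacts, arrhythmia, optical tissue
physics (no Beer-Lambert model), realistic cuff timing error, and skin-tone
distributions. Passing tests on this data therefore demonstrates that the
pipeline recovers the structure the method posits when it is present — not
clinical accuracy on real wearers.

## Signal conditioning

Each PPG channel passes through (`conditionChannel()`):

1. **Zero-phase Butterworth low-pass**, order 4, cutoff 10 Hz (pulse energy
   lies below ~10 Hz). Forward-backward filtering with odd reflection
   padding; the filter state is initialized around the edge value so a
   constant passes exactly.
2. **Wavelet denoising**: 8-tap Daubechies filter bank, 4 decomposition
   levels at 1 kHz, universal soft threshold `sigma * sqrt(2 log N)` with
   `sigma` estimated from the MAD of the finest detail coefficients.
3. **Baseline extraction** at a 0.4-Hz band edge (below the slowest
   plausible heart rate): the signal is decimated to ~20 Hz for numerical
   robustness at the very low normalized corner frequency, low-pass
   filtered zero-phase (order 2), and interpolated back. The pulsatile (AC)
   component is the residual, so `denoised = baseline + pulsatile` holds
   pointwise by construction.
4. **Z-score standardization** of the pulsatile path (population SD). The
   baseline path deliberately stays in absolute ADC counts: the dual-channel
   baseline difference is the central feature and standardization would
   destroy it. Standardization is applied per analysis window at estimation
   time, matching the estimation unit.

The first and last baseline period (2.5 s at the 0.4-Hz edge) of each
session carry filter edge transients; analysis windows overlapping them are
excluded.

Downsampling (`downsampleSeries()`) is restricted to integer decimation
factors with a zero-phase anti-alias filter; waveform features are extracted
at 500 Hz.

## Beat analysis and features

Systolic peaks are local maxima above an adaptive amplitude threshold
(45% of the interior 98th percentile) separated by at least 0.3 s. Each
beat onset is the waveform foot, located by the intersecting-tangent rule
(tangent at the steepest upstroke point intersected with the level of the
preceding minimum), which stays within a few milliseconds of the true foot
even after low-pass smoothing flattens the valley. The dicrotic notch is the
most prominent local minimum between the systolic peak and 80% of the
cardiac period, with a second-derivative fallback in
(peak + 0.1 CP, peak + 0.5 CP); beats where both fail are excluded from the
notch-dependent features rather than guessed.

Feature definitions (`computeBeatFeatures()`): `CP = end - onset`,
`ST = notch - onset`, `DT = end - notch` (so ST + DT = CP identically),
`K = (mean - min) / (max - min)` over the beat, areas above the beat minimum
split at the notch (trapezoid rule), and AC/DC = peak-to-peak pulsatile
amplitude over the mean baseline level. K and the areas are computed on the
pulsatile component; both are shift-invariant, and within one beat the
baseline is essentially constant, so this equals the denoised-signal value.
Waveform features come from the dorsal channel (the higher-SNR side in the
emulated device) and are averaged over the valid beats of each window; a
window with fewer than 5 valid beats is flagged invalid. The heart-rate
feature is `60 / mean(CP)` computed from the PPG itself, keeping the
pipeline self-contained. The baseline difference is the window mean of
(dorsal - palmar) baselines in ADC counts. Interface voltages are converted
to Pa through a monotone piecewise-cubic calibration curve
(`calibrationCurve()`); each window reports per-channel mean pressures and
temperatures. The voltage *sum* used in some wear-tightness analyses is not
a model input here; per-channel pressures and temperatures are the four
interface features.

Each window is paired with the nearest-in-time cuff reference reading
(window center to reading time) — an interpretation, since the cadence of
cuff readings against the 2-s estimates is not otherwise pinned down.

## The fusion model

`trainModel()` fits an MLP with two hidden layers of 80 and 12 ReLU units,
20% dropout after each hidden layer, a linear output unit, MSE loss and
Adam at learning rate 0.001 (`mlpConfig()`). Feature scaling is a z-score
fitted on training rows only; the output bias is initialized at the training
mean. The schedule — default 500 epochs maximum, batch 32, early stopping
after 30 epochs without validation improvement, best-validation weights
retained — is a desk-scale choice exposed in the config; dropout is active
only during training, and one seed drives weight initialization, shuffling
and dropout, so training is deterministic. Experiments in this package use
shorter schedules (e.g. 300 epochs, patience 30, batch 64) that reach the
same accuracy in a fraction of the time; the vignette's and acceptance
suite's cohort sizes (18 subjects x 4 sessions x 120 s, ~3700 windows) are
the package's standard experiment scale.

## Evaluation protocol

`losoFolds()` implements leave-one-subject-out validation: each subject's
sessions in turn form the test set; the remaining subjects' sessions are
shuffled and split 85/15 into training and validation at the session level.
`pooledSplit()` is the non-LOSO comparison (70/15/15 across all sessions).
Test errors are pooled across folds before computing statistics — one
scatter of estimate/reference pairs, not fold-averaged statistics.

Error statistics: `ME = mean(estimate - reference)`, SD with the n-1
denominator. Bland-Altman limits of agreement are
`[mu - 1.96 sigma, mu + 1.96 sigma]`, exact, rounded only for display. The
AAMI criterion uses strict inequalities (|ME| < 5 mmHg and SD < 8 mmHg;
ties fail). BHS grades use the protocol table (A: 60/85/95, B: 50/75/90,
C: 40/65/85 percent of absolute errors within 5/10/15 mmHg).

On the default synthetic cohort the LOSO error SD for SBP sits well below
the 2 x window-noise bound and far below the training-mean baseline
predictor, and LOSO SD consistently exceeds pooled-split SD. The gap needs
no injected subject effect: held-out subjects sit at the edges of the
training distribution of stroke volume and physical characteristics, so
cross-subject extrapolation alone produces per-subject biases — the same
qualitative ordering reported for real cohorts.

## Numerical choices and degenerate inputs

* Window layout: a window is emitted iff it fits entirely in the session;
  the count is `floor((duration - length) / shift) + 1`, computed with a
  1e-9 slack against floating-point jitter.
* Standardization refuses zero-variance inputs; the conditioning chain
  tolerates a constant pulsatile path by omitting the standardized series.
* The scaler refuses constant feature columns by name; the experiment
  driver drops zero-variance columns per fold (e.g. `sex` when all training
  subjects share one in a small cohort) before fitting.
* Degenerate beats (zero peak-to-peak amplitude, nonpositive DC level) are
  errors at the single-beat API and exclusions in the window aggregator.
* Non-finite samples are refused at session write time and reported (not
  raised) by `validateSession()`.
* Session serialization writes 17 significant digits; round trips are
  bit-exact for doubles.

## Known limitations

* The generator's linear forward model makes blood pressure fully
  recoverable from the latents by design; real PPG-BP relations are noisier
  and drift over time. Accuracy figures on synthetic cohorts are upper
  bounds of pipeline correctness, not device validation.
* The dicrotic notch in the synthetic waveform touches zero, which is
  sharper than real notches; the delineator's prominence rule has an easier
  task here than on real data.
* Only integer-factor downsampling is supported.
* Beat detection assumes near-periodic rhythms; arrhythmia is out of scope.
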