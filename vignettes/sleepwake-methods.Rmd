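---
title: "Methods: single-epoch sleep-wake classification and OSA screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-epoch sleep-wake classification and OSA screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Obstructive sleep apnea (OSA) severity is quantified by the apnea-hypopnea
index (AHI): respiratory events per hour of *sleep*. Estimating sleep time
at home therefore matters, but home-grade cardiorespiratory sensors suffer
data loss and movement artifacts, so classifiers that need long stretches
of contiguous good-quality signal are unrealistic. `cardiosleep`
classifies each 30 s epoch **independently** as Sleep (class 0) or Wake
(class 1) from two channels: the ECG-derived instantaneous heart rate
(IHR) and thoracic respiratory effort (RIP). From the predicted sleep
architecture it derives total sleep time (TST) and two screening metrics
that flag patients whose predictions are unreliable in ways characteristic
of OSA — precisely the patients who should be prioritized for clinical
polysomnography rather than monitored at home.

## Preprocessing

Both channels are cut into non-overlapping 30 s segments and every segment
is processed in isolation, so one noisy interval never contaminates its
neighbours.

**ECG.** R peaks are detected per segment with a Pan-Tompkins-style
detector (zero-phase 5–15 Hz band-pass, squared derivative, 150 ms
moving-window integration, adaptive threshold at 25% of the integrated
maximum, 250 ms refractory period). The literature source the pipeline
follows does not spell out its R-peak detector, so this standard,
dependency-free construction sits behind `detect_r_peaks()` and can be
swapped. Segments with fewer than 15 beats are discarded. The IHR
(60 / interbeat interval, bpm) is assigned at beat times; to avoid border
extrapolation the first beat time is moved to the second beat time minus
the mean of the 2nd and 3rd interbeat intervals (symmetrically for the
last), and a shape-preserving piecewise-cubic (PCHIP) interpolant is
evaluated on the 4 Hz grid, giving 120 samples. Outliers are flagged in a
single joint pass against the pre-flagging segment median and SD: outside
40–180 bpm, more than 20 bpm from the median, or more than 3 SDs from the
median. Flagged runs of at most 10 samples (2.5 s) are filled by mirroring
the preceding samples; longer runs, or runs without enough preceding
samples (including any run touching the first sample — a conservative
choice, since there is nothing to mirror), invalidate the epoch. Finally
the median over all valid samples of the subject is subtracted, removing
inter-subject heart-rate level while keeping stage-related variability.

**RIP.** Each segment is band-pass filtered to 0.04–2 Hz and resampled to
the same 4 Hz/120-sample grid by cubic spline. The filter is realized in
the frequency domain with a Butterworth magnitude response (order 4,
configurable): a real, symmetric transfer function is zero-phase by
construction — phase distortion would shift breath timing against the
tachogram — and it is numerically robust at the very low normalized
high-pass corner where a time-domain band-pass polynomial is
ill-conditioned. 5 s of each segment are reflected at the borders before
filtering to suppress edge transients. Per recording, every sample is
normalized by the 50th percentile of per-epoch medians and the 50th
percentile of per-epoch SDs (computed over *all* candidate epochs, before
any discard propagation — robust to which modality failed), then each
epoch's own median is subtracted, making every epoch median exactly zero.
Epochs discarded on the ECG side are discarded from the RIP stream, so
the classifier always consumes valid pairs.

Two numeric conventions are fixed so thresholds reproduce bit-for-bit:
medians of even-length vectors are the mean of the two central order
statistics (R's default), and all segment SDs use the population formula
(n divisor). The PCHIP interpolant is evaluated with the 4 Hz grid clamped
to the border-shifted beat span, i.e. constant-hold extrapolation at the
ends.

## Network

Each modality has a convolutional branch: (8,7,2)-Conv → (16,5,2)-Conv →
(32,3,2)-Conv, ReLU activations, valid padding — mapping 120 samples to a
416-dimensional feature vector — followed by a (64)-Dense layer, 50%
dropout and Softmax over the 2 classes. The exact filter counts and
kernel sizes are package defaults exposed in `default_layer_spec()`, not
sacred values. The two unimodal networks are trained first; the
multimodal network copies both convolutional branches **frozen**
(bit-exactly non-trainable — tested) and trains a fresh dense head on the
concatenated features. Training uses Adam (learning rate 1e-3, standard
moment coefficients), class-balanced shuffled batches of 16 epochs drawn
independently of temporal order (minority over-sampled with replacement),
up to a configurable number of passes with early stopping on validation
loss (default patience 10), keeping the best-validation-loss weights. An
epoch is predicted Wake iff p(Wake) ≥ 0.5; boundary equality goes to
Wake. The whole fit is a pure function of (data, spec, control, seed):
initialization, batch sampling and dropout all derive from one seeded
stream, and repeated fits are bit-identical.

The fitting interface follows the classic R modelling idiom:
`sleepwake_cnn()` returns a classed object with `print`, `summary`,
`coef`, `predict`, `plot` and `simulate` methods.

## Uncertainty metrics and OSA screening

Pooling the valid epochs of a reference cohort, the sleep confidence
threshold is `T_s = median(p(Sleep) | predicted Sleep) − SD(...)` and the
wake threshold `T_w = median(p(Wake) | predicted Wake) − SD(...)`
(population SDs, pooled across subjects; a per-subject aggregation mode
is a documented alternative but pooled is the default). An epoch is an
*uncertain sleep* prediction iff predicted Sleep with p(Sleep) below
`T_s`, analogously for wake. Per patient:

* **%USE / %UWE** — uncertain sleep/wake epochs over all valid predicted
  epochs;
* **%SWT** — label changes between adjacent valid epochs (invalid epochs
  removed first) over the number of valid epochs;
* **TST** — half a minute per valid epoch predicted Sleep. Because
  discarded epochs carry no prediction, an extrapolated TST rescaled by
  the total/valid ratio is reported alongside, clearly labelled.

A patient is flagged as likely OSA iff %USE **strictly** exceeds its
threshold *or* %SWT strictly exceeds its threshold (boundary equality is
negative; defaults 64% and 24%). Operating points are chosen by ROC
analysis: candidate thresholds are midpoints between sorted unique metric
values, the feasible set is specificity ≥ 0.95, and among feasible points
the most sensitive (ties: more specific, then lower threshold) is chosen;
if the floor is unattainable the most specific point is returned with a
warning flag. AUROC is the trapezoid area under the empirical curve; it
is cross-checked against an independent implementation in the tests.

The mechanism that makes these metrics informative: the classifier is
trained only on low-AHI patients (AHI < 10, split 70/30 by patient for
training/validation), so apnea physiology — sympathetic activation after
events producing wake-like cardiorespiratory behaviour during sleep — is
out of its training distribution and yields low-confidence or flickering
predictions. Severity of the trained classifier is assessed by Cohen's
kappa on a fixed test set; when several models are trained from different
split seeds, `select_model()` keeps the highest test kappa (ties to the
lowest seed; using the same fixed set for selection and reporting follows
the published protocol, and the package makes the choice explicit).

## Synthetic cohort generator

Clinical recordings cannot be redistributed, so the package ships a
simulator rich enough to exercise every stage:

* **Hypnogram**: sticky first-order Markov chain over W/N1/N2/N3/REM with
  persistence 0.9 and exact stationary distribution W 17%, N1 4%, N2 40%,
  N3 22%, REM 17% — proportions of a typical low-AHI clinical training
  cohort.
* **Beats**: integrate-and-fire on a stage-dependent instantaneous rate
  (means 78/66/60/55/67 bpm for W/N1/N2/N3/REM — wake highest, deep sleep
  lowest, REM and N1 "active") with AR(1) epoch-level wander,
  respiratory sinus arrhythmia coupling (amplitude largest in deep
  sleep), and per-beat timing jitter. The ECG is a train of Gaussian
  QRS-like pulses (SD 10 ms, unit amplitude) plus white noise.
* **Respiration**: amplitude- and rate-modulated oscillation; wake
  breathing is faster and much more irregular than sleep.
* **Apnea events**: onsets placed by rejection sampling inside sleep
  epochs only (never overlapping; durations uniform on 10–40 s, within
  the ≥10 s scoring convention), realized counts tracking a Poisson
  target at the requested events/hour. During an event respiratory
  effort is reduced by 70%; after it the heart rate surges by up to
  18 bpm, decaying over 10 s — wake-like physiology during sleep, the
  stated mechanism behind the uncertainty metrics, with no claim of
  waveform realism.
* **Artifacts**: movement-noise bursts and flat spans on both channels.

Stage-dependent parameter defaults are chosen once for physiological
plausibility and class separability and documented as modelling choices.
Default rates are 256 Hz (ECG) and 32 Hz (RIP), typical PSG values; unit
tests use reduced rates (128/16 Hz), which changes compute only, not
statistics. What the simulator does **not** emulate: realistic ECG
morphology (P/T waves, ectopy), hypopneas vs apneas, SpO2, first-night
effects, or inter-patient anatomy. Passing the synthetic recovery tests
therefore demonstrates that the pipeline's machinery is correct and that
the uncertainty mechanism behaves as designed — not clinical-grade
performance on real patients.

## Problem sizes in the shipped checks

The reproduction script and the acceptance-level tests train on a
simulated low-AHI pool of 28 patients x 720 epochs (about 20,000 epochs,
6 h nights), evaluate epoch agreement on 6 held-out low-AHI patients, and
assess the severity trend and detection on a 40-patient cohort (10 per
severity class at 2/10/20/60 events per hour, 4 h nights). Nights shorter
than a clinical 8 h keep the runs desk-scale; all sizes are package
choices stated here and in the script.

## Degenerate inputs and tie-breaks

Empty or single-class pools raise classed errors (`cohort_error`,
`balance_error`, `threshold_error`) rather than silently degrading. A
recording with zero valid epochs is an `empty_recording_error`; an
all-constant RIP channel a `degenerate_recording_error`. Model-selection
ties go to the lowest seed; the posterior decision boundary goes to Wake;
the screening rule's boundary equality is negative. Kappa returns 1 when
observed and chance agreement are both 1.

## Known limitations

Epoch-independent classification ignores sleep continuity, bounding
achievable agreement below sequence models. The confidence thresholds are
cohort-dependent; transferring them to a different sensor or population
requires refitting. The simulator's separability means synthetic kappas
exceed what clinical recordings yield; published clinical numbers for
this family of methods are moderate (epoch kappa near 0.5) and are not
reproducible from synthetic data — the package's checks are correctness
and mechanism checks, not clinical claims.
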