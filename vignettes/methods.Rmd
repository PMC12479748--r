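---
title: "Methods: a hybrid ECG-image classification pipeline on synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid ECG-image classification pipeline on synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Single-lead ECGs are often available only as plot images. `ecgfusion`
implements a complete two-subsystem diagnostic pipeline for such images,
aimed at the binary question of whether a cardiac patient's ECG carries the
morphological signature associated with systemic lupus erythematosus
involvement — in practice, a widened, higher-amplitude QRS complex consistent
with ventricular hypertrophy.

The pipeline has two independent branches joined by a weighted ensemble:

1. **Feature-matrix branch.** The plot image is digitized to a 1-D trace
   (grayscale → Gaussian blur → adaptive threshold → largest 8-connected
   component → column-wise amplitude). A Pan–Tompkins-style detector finds R
   peaks; per-beat features (R-R interval, P amplitude, QRS peak-to-peak,
   QRS peak index, QRS maximum) are assembled into a zero-padded N × 5
   matrix and classified by residual blocks feeding a bidirectional-RNN
   encoder–decoder with a softmax head.
2. **Audio/spectrogram branch.** The digitized trace is mean-centered,
   scaled into [−1, 1], resampled to an audio rate, converted to a log-Mel
   spectrogram (Hann STFT, 1024-point window, hop 512, 128 Mel bands at
   22,050 Hz), rendered as a 224 × 224 × 3 image, and classified by a
   compact convolutional network.

Grad-CAM heatmaps of the spectrogram classifier are scored against
ground-truth QRS zones with two quantitative metrics: Region Attention
Accuracy (does the most-activated connected region hit an expected zone?)
and QRS overlap (what share of the activated area falls inside the QRS
zone?).

Because no public dataset exists for this clinical question, the package
ships a synthetic generator that is itself first-class, tested code: every
downstream contract is validated against its ground truth.

## The synthetic generator

Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) with per-wave
amplitude (mV), width (s, as a Gaussian standard deviation) and center
offset relative to the R peak. Beats repeat at `60/heart_rate` s; white
noise (default sd 0.05 mV) and a slow sinusoidal baseline wander (default
0.05 mV at 0.33 Hz) are added. Defaults: 10 s records at 250 Hz, heart rate
drawn uniformly in [60, 100] bpm for both classes so the class contrast
lives in beat morphology, not rhythm.

The two presets encode the study contrast:

* `normal` (`le_negative`): R amplitude 1.0 mV, QRS component widths
  10–12 ms.
* `qrs_wide` (`le_positive`): R amplitude 1.5 mV, QRS widths 18–20 ms
  (≥ 1.5× normal) with wider Q/S offsets — a ground-truth QRS window about
  1.5× longer.

What the generator does **not** emulate: physiologic rhythm variability and
arrhythmia, multi-lead geometry, electrode artifacts, pathological T/ST
changes, and real scanner/photograph distortions (perspective, shadows,
JPEG artifacts). Passing tests therefore demonstrate that the pipeline's
machinery is correct and that its attention behaves sensibly under a known
morphological contrast — not clinical performance on real ECGs.

Rendering draws a dark trace (thickness 2 px) on a light background with an
optional faint grid (intensity 248 of 255). The grid must stay within the
adaptive-threshold offset (default 10 intensity units) of the background so
that the largest-component step isolates the trace; real ECG paper's faint
pink grid behaves the same way under a luminance threshold.

## Digitization choices

* **Column reducer**: the mean row of foreground pixels per column (robust
  to trace thickness); median and topmost are available.
* **Connectivity**: 8-connected pixel components operationalize "largest
  contour", ranked by pixel count with a row-major tie-break. EBImage's
  4-connected labeler would sever thin diagonal strokes, so the labeling is
  done by an internal BFS.
* **Gaps**: columns with no foreground are filled by linear interpolation
  (`hold_last` available).
* **Calibration**: pixel columns never map to seconds implicitly; callers
  must pass `columns_per_second`. The round-trip fidelity helper aligns on
  the drawn region and excludes the margin, because a 12-px misalignment is
  enough to decorrelate sharp R spikes even when the waveform is perfectly
  recovered.

## Audio and spectrogram choices

Normalization offers two modes. The plain formula
`(x − mean(x)) / max|x|` ("verbatim") does not actually bound mean-centered
values by 1, so the default "strict" mode divides by `max|x − mean(x)|`,
which guarantees [−1, 1]. Resampling is polyphase band-limited with the
output length pinned to `round(L · target/source)`. WAV export is 16-bit
PCM mono (quantization error ≤ 1/32768); the reader/writer is a minimal
RIFF implementation because no audio I/O package is available in the
dependency set.

Spectrogram parameters: Hann window (periodic), reflect center-padding so
`n_frames = 1 + floor(L/hop)`, one-sided spectrum, triangular unit-peak Mel
filters with centers equally spaced on the `2595·log10(1 + f/700)` scale,
dB conversion referenced to the per-spectrogram maximum with a −80 dB
floor, then min–max scaling, bilinear resize to 224 × 224 and channel
replication. dB conversion precedes resizing. The 8000 Hz audio export rate
and the 22,050 Hz spectrogram rate coexist: the pipeline resamples to the
spectrogram rate immediately before the STFT.

## The classifiers

**Subsystem 1** lifts the five feature columns to 32 channels and applies
three pre-activation residual blocks (BN → ReLU → W, twice, plus the skip)
at widths 32/64/128 with max-pooling after the first two blocks only;
channel jumps between blocks use 1 × 1 projections so the in-block skip
stays shape-compatible. A bidirectional tanh-RNN encoder (hidden 16) feeds
a bidirectional decoder whose per-step outputs are averaged into class
logits. Feature matrices are z-scored per column with training-set
statistics: the QRS-peak-index column is on a scale of thousands of samples
while R-R intervals are about one second, and the first dense layer sits
before any batch normalization.

Batch normalization uses per-record statistics along the time (beat) axis
during training — records are processed singly because their lengths differ
— and running statistics in inference mode. Classifier output layers are
zero-initialized (uniform softmax at initialization); all other weights are
He-normal.

**Subsystem 2** preserves the published input contract (224 × 224 × 3
log-Mel images) but is a compact trainable CNN rather than a large
pretrained audio-spectrogram transformer: verifying the pipeline does not
require borrowed weights, and a plug-in model with the same contract can
replace it by implementing `predict`. The stem averages the three channels
and block-pools anisotropically to 28 frequency × 112 time cells. Time is
pooled only 2× deliberately: a square stem cell would span ~0.46 s of a
10 s record — wider than a QRS complex — making beat-level attribution
impossible by construction. Three 3 × 3 convolutions (1→8, pool, 8→16,
16→16) give the Grad-CAM target layer a receptive field of roughly half a
second, matching the widened-QRS scale. Stem cells are standardized with a
per-pixel training mean and one global standard deviation; a per-pixel
standard deviation was rejected because most of a log-Mel image sits at the
dB floor with near-zero variance, which turns any perturbation there into
enormous z-scores.

Training uses AdamW (decoupled weight decay 0.01, skipped for biases and
BN parameters), cross-entropy, early stopping on validation loss with
best-checkpoint retention, and a two-phase schedule for subsystem 2
(head-only warm-up, then full fine-tuning). The published learning rates
(1e-4 and 2e-5) describe fine-tuning of large pretrained networks; with
Adam-normalized steps, 2e-5 over the few hundred updates available here
moves weights by about 0.01 — far too little to train a randomly
initialized network — so the desk-scale defaults are 1e-2 with 25 (subsystem
1) and 60 (subsystem 2) epoch caps. The published values remain one
`train_config()` call away.

SpecAugment-style masking is implemented and tested (`spec_augment()`), but
defaults to off in `train_subsystem2`: the masking widths are not specified
anywhere, the compact model trained on abundant synthetic data shows no
overfitting gap for it to close, and masking at or above beat scale
measurably diffuses the attention maps that the region metrics evaluate
(accuracy is unchanged either way). Enable it when fine-tuning a large
plug-in model on scarce data.

Class imbalance is corrected by SMOTE on the flattened, zero-padded feature
matrices — inside training folds only, never before splitting.

## Explainability metrics

Grad-CAM weights each channel of the target layer by the spatial mean of
the class-score gradient, rectifies the weighted sum, upsamples bilinearly
to the input grid and min–max normalizes. Heatmaps explain the **predicted**
class: with a two-class GAP-linear head the two class maps are near
complements, so forcing one fixed target class anti-localizes on the other
class's samples by construction.

Ground-truth QRS windows (generator annotations, ±3 SD of the QRS
components) are mapped to image columns through the audio chain
(`frame = sample · rate_ratio / hop`), spanning all frequency rows. The
activation threshold is 0.5 after normalization (configurable). Because the
zones come from the generator rather than a cardiologist, the metrics
measure ground-truth agreement, not expert agreement. The overlap property
is tested with a one-sided sign-flip permutation test of the per-sample
excess `overlap − 100 · area_fraction`.

## Evaluation protocol

Confusion counts follow the standard 2 × 2 layout with a declared positive
class. Sensitivity, specificity, accuracy and F1 are carried at full
precision; display rounding is configurable per metric (the conventional
presets are 1, 0, 2 and 1 decimals respectively). AUC uses the
rank-statistic (midrank) formulation, which equals trapezoidal integration
with tie averaging; the test suite verifies exact agreement with a
brute-force pair-counting oracle and with an independent ROC implementation.
Stratified 80/20 splits take `round(class_size · fraction)` test samples per
class. Stratified 5-fold cross-validation keeps per-fold class counts within
one sample of proportionality, restricts SMOTE and all fitting to training
folds, and reports per-fold metrics with mean and sample standard deviation.

## Problem sizes and numerical notes

The default experiment uses 100 records per class (10 s, 250 Hz, noise sd
0.05), 80/20 stratified split, and up to 50 test-set heatmaps for the
region metrics; cross-validation examples run at 30 records per class with
10-epoch fits. These sizes were chosen as the smallest at which every
property of interest is stable across seeds. All randomness flows from one
seed through `derive_seed(seed, stream)`, so every artifact is bit-exactly
reproducible; training is single-threaded deterministic R.

Degenerate inputs are handled explicitly: constant traces render as a
mid-plot line and normalize (with a warning) to silence; all-zero
spectrograms clamp to the dB floor; constant heatmaps normalize to zero with
a warning; zero metric denominators yield `NA` with a warning rather than a
crash; beats whose feature windows cross record edges shrink their windows.

## Known limitations

* The Gaussian-bump generator underrepresents real ECG variability; all
  performance numbers are synthetic-world numbers.
* The digitizer assumes one monotone-time trace per image: no multi-lead
  segmentation, rotation correction, or OCR of calibration marks.
* The compact spectrogram classifier is a stand-in contract-wise, not a
  re-implementation of a pretrained transformer; absolute accuracy is not
  comparable to fine-tuned large models on real data.
* Grad-CAM resolution is bounded by the conv-layer grid (~0.1 s per cell in
  time after upsampling); structures narrower than that blur together.
* Adaptive thresholding hollows out solid regions thicker than its block
  (31 px): on very noisy records the drawn band can fragment into outline
  components, and the largest-component step then recovers only part of the
  trace. The median round-trip fidelity is unaffected, but individual noisy
  records can digitize poorly; a larger `adaptive_block_size` trades this
  against grid suppression.

## Worked example

```{r}
library(ecgfusion)
res <- run_pipeline(pipeline_config(n_per_class = 100, seed = 1))
print(res)
res$subsystem1$metrics
res$region_metrics$summary
```
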