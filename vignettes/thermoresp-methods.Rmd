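---
title: "Respiration rate from thermal facial video: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiration rate from thermal facial video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Breathing warms and cools the skin around the nostrils (or the surface of a
face mask) with every exhalation and inhalation, and a long-wave infrared
camera sees this as a periodic intensity modulation. `thermoresp`
implements an end-to-end pipeline that turns a thermal facial video into a
respiration rate (RR) estimate:

1. **ROI tracking** — a face detector is run on every frame
   (track-by-detection); the per-frame crops are stacked into a stabilized
   face video.
2. **Preprocessing** — the video is temporally downsampled from 30 Hz to a
   5 Hz analysis rate by block averaging, cut into 10 s clips with 5 s
   overlap (50 frames of 128×128 at the defaults); within each clip every
   pixel's temporal mean is removed, then the clip is z-scored as a whole.
   A respiratory-effort belt recorded at 2048 Hz serves as the reference;
   it is anti-alias filtered, resampled onto the clip grid, and z-scored.
3. **Signal estimation** — a temporal encoder–decoder 3D CNN followed by a
   bi-directional LSTM and a per-step linear head regresses the 1-D
   respiratory waveform from each clip.
4. **Readout** — the estimate is bandpass filtered (third-order
   Butterworth, 0.05–0.7 Hz, applied forward–backward) and RR is the
   frequency of peak periodogram power within that band, in breaths per
   minute (BPM; 0.05–0.7 Hz is 3–42 BPM, the physiological range from
   meditation to fast breathing).

The chest belt and the facial heat signal measure the same respiratory
process at different places on the body, so they are systematically **out
of phase** with one another. That asynchrony is the scientific crux of the
training objective below.

## The phase-tolerant objective

Pointwise regression losses (RMSE) punish a correct waveform that is
merely shifted in time, and with a lagged reference they drag the model
toward the wrong compromise. The objective used here combines two
phase-tolerant terms:

$$\mathrm{loss} = \alpha\,\mathrm{NMCC} +
  (1-\alpha)\,\min\!\left(1, \frac{\mathrm{AFD}}{3\ \mathrm{BPM}}\right),
  \qquad \alpha = 0.5 .$$

**NMCC** (negative maximum cross-correlation). Both signals are
zero-meaned, transformed with the DFT at the clip length, restricted to
the respiration band by a brick-wall mask, and circularly
cross-correlated over all lags via the inverse transform of
$f(A')\,f(B')^{*}$. The array is normalized by the product of the
band-filtered signals' Euclidean norms, so it lies in $[-1, 1]$ and its
maximum is exactly 1 when one signal is a circular shift and/or positive
rescaling of the other. NMCC is the negated maximum. It is
shift-invariant *exactly* and differentiable almost everywhere; the
package trains through an analytic gradient (quotient rule at the argmax
lag, with the band projection acting as identity on its own range),
verified against finite differences in the test suite.

A note on transform length: the cross-correlation is computed at the
signal length $n$ (not zero-padded), because the exact properties above
are properties of the circular shift theorem *at length n* — padding
would break the unit autocorrelation and exact lag invariance. Fine
frequency resolution is needed elsewhere (below) and is obtained by
zero-padding there.

**AFD** (absolute frequency difference). The in-band peak frequencies of
the two zero-padded periodograms (default `fft_len = 4096`, i.e.
0.073 BPM bins at 5 Hz — a raw 50-point spectrum would have 6 BPM bins)
are compared in BPM and the difference saturates at 3 BPM: any separation
at or beyond 3 BPM contributes the full unit penalty. The hard argmax
carries no gradient; by default gradients flow only through NMCC. An
optional softmax expected-frequency surrogate (`soft_afd = TRUE`,
temperature on the sum-normalized periodogram) makes the AFD term
differentiable for experimentation; its analytic gradient is also
finite-difference tested.

Two honest caveats, both visible in the test suite:

* The hard AFD is phase-tolerant only to first order: the periodogram of
  a 10 s clip carries phase-dependent spectral leakage, so the AFD of a
  shifted copy of a signal is not exactly 0 (typically well under
  1.5 BPM, far below saturation). The NMCC term is what supplies exact
  shift invariance.
* With `alpha = 0` and the hard AFD the loss has no differentiable term;
  `fit_rr_estimator()` refuses to start rather than silently not learn.

## The estimator

The network is deliberately shallow: vanilla 3D conv blocks (3×3×3 conv,
ReLU, spatial-only average pooling) extract local spatio-temporal
features without touching sequence length; exactly **one encoder block**
additionally pools time with stride 2, and exactly **one decoder block**
(transposed 3D convolution, temporal stride 2, implemented as zero-stuffing
followed by convolution) restores it. After global spatial average
pooling the 50-step, 64-channel sequence is processed by a bi-directional
LSTM (64 units per direction) and a per-step linear head.

Why exactly one temporal pooling: at the 5 Hz analysis rate, $k$
temporal-stride-2 poolings leave an internal rate of $5/2^k$ Hz. Only
$k = 1$ (internal 2.5 Hz, Nyquist 1.25 Hz) still covers the 0.7 Hz band
edge. The configuration validates this at build time and refuses a
second temporal pooling stage.

Channel widths, block counts and the nonlinearity are not architectural
necessities; the defaults (`vanilla_pre = c(16, 32)`, encoder/decoder 64,
`vanilla_post = c(64, 64, 64)`, bi-LSTM 64/direction) give ≈ 0.58 M
parameters, in the size class of compact published video vital-sign
estimators (roughly 0.5–2 M), and every width is exposed in
`model_config()`. No batch normalization is used: at batch size 2 its
train/eval statistics discrepancy outweighs its benefit, and keeping the
network purely feed-forward makes evaluation bit-deterministic.

The network, its backpropagation (im2col + GEMM 3D convolutions,
pooling, BPTT through the LSTM) and the Adam optimizer are implemented in
this package (R with C++ kernels). Gradient correctness for every layer
type is pinned by finite-difference tests on a tiny configuration.

## Training protocol

`train_config()` defaults follow the standard protocol for this
estimator family: Adam at learning rate 0.001, batch size 2, 15 epochs,
and five repeats of subject-wise 18/2/2 train/validation/test splits —
all clips of a subject stay in one fold, so no subject appears on both
sides of a split (checked programmatically every run). The returned
weights are those of the best validation epoch; model selection by
validation loss is this package's policy choice. Evaluation bandpasses
the *prediction* but compares against the unfiltered normalized target,
mirroring the filter's position after the model in the pipeline.

## The synthetic data generator

The real datasets in this field pair thermal video with belt references
under research-ethics restrictions and cannot be redistributed, so the
package ships a generator (`simulate_recording()`, `simulate_cohort()`)
that reproduces the statistical structure the pipeline relies on — and is
itself first-class, tested code:

* a face-shaped warm ellipse on a cooler background;
* a breathing patch whose intensity oscillates at the configured RR:
  the nostril region (small, crisp) without a mask, or a larger,
  lower-contrast region for mask conditions (a mask spreads exhaled heat
  over its surface);
* a non-sinusoidal respiratory waveform — fundamental plus decaying
  harmonics ($a_k \propto 1/k$, default 2 harmonics) — so the
  peak-frequency readout is exercised honestly rather than on pure
  tones;
* a belt reference that is the same waveform delayed by `belt_lag_s`
  (default drawn from U(0.2, 1.5) s; the real lag distribution between
  torso and face is not published, so this is an explicit, configurable
  placeholder);
* body sway as an Ornstein–Uhlenbeck displacement of the whole face
  (relaxation time 2 s), with twice the amplitude for standing
  conditions (6 px vs 3 px at 480-px frame height);
* i.i.d. Gaussian sensor noise (default sd 1 on a 0–255 intensity
  scale, against a breathing modulation depth of ±5 — comparable to the
  headroom a cooled thermal camera has over nostril temperature
  swings);
* per-subject RR drawn once from U(8, 22) BPM and shared across that
  subject's conditions, so subject identity is a real nuisance factor
  for subject-wise splits.

What the generator does **not** emulate: facial texture and anatomy,
radiometric calibration, drift and dead pixels, out-of-plane head pose,
occlusions, or motion that correlates with breathing (e.g. shoulder
rise). Tests passing on synthetic cohorts therefore demonstrate that the
pipeline is implemented correctly and that the training signal is
learnable under the stated noise model — not that the accuracy figures
transfer to real thermal recordings.

## Numerical and design choices

* **Boxes** are 0-based, half-open pixel intervals everywhere; bilinear
  crop-resize aligns pixel centers, so a full-frame box at native size is
  an exact identity and constants are preserved exactly.
* **Detector**: the bundled `intensity_detector()` blurs lightly (5 px
  box blur), thresholds at the lower of the 95th percentile and Otsu's
  cut (so warm regions larger than 5 % of the frame are segmented
  whole), and takes the largest 4-connected component. It is a
  deterministic stand-in exercising the same interface a learned
  thermal-face detector would implement (`function(frame) -> box`);
  frames with no detection inherit the nearest previous valid box.
  Detector jitter is damped by a centered moving-median box smoother
  (default window 5; optional, since whether the original system needed
  one depends on the detector).
* **Downsampling** is block averaging, not stride subsampling — it
  anti-aliases for free.
* **Clip normalization** removes each pixel's temporal mean within the
  clip before the per-clip z-score. The static thermal structure of the
  face carries no respiratory information but dominates the raw clip's
  variance; with it left in, the input-to-output coupling is so weak that
  a short training budget converges to a degenerate input-independent
  oscillator in the respiration band (every clip receives the same RR
  estimate). Mean removal makes the breathing modulation the dominant
  input content — the same role frame differencing plays in RGB
  video-physiology networks — and the estimator then tracks the per-clip
  frequency. The z-score contract itself (clip mean 0, sd 1) is
  unchanged.
* **Belt resampling** decimates 2048 Hz by block means to ~32 Hz before
  a 4th-order Butterworth low-pass at 2 Hz (designing the IIR directly at
  2048 Hz would put the cutoff at 0.2 % of Nyquist, numerically
  fragile), then interpolates at the clip timestamps.
* **Bandpass** readout filtering is a third-order Butterworth applied
  forward–backward: the peak-power readout must not depend on filter
  phase. Butterworth is the package's choice of IIR family.
* **Ties** in the periodogram argmax break toward the lower frequency.
* **Degenerate inputs** fail loudly and early: constant clips and belt
  segments cannot be z-scored; signals whose in-band power is a
  negligible fraction (< 0.1 %) of total power have no defined peak; boxes
  of ≤ 1 px cannot be resized.
* **Determinism**: every stochastic stage (generator, weight init, batch
  shuffling, splits) is seeded, and seeded runs are bit-reproducible;
  the simulation helpers restore the caller's RNG state.

## Problem sizes used in the shipped experiments

The full protocol (22 subjects × 4 conditions × 90 s at 640×480,
128×128 clips, 15 epochs, 5 repeats) is what the defaults describe. The
shipped tests and the acceptance script run the package's **scaled
reference experiment** (`run_reference_experiment()`): 8 subjects under
two conditions (seated/no-mask and standing/mask), 40 s recordings at
120×160 px, 64×64 clips, a narrower model (≈ 50 k parameters), 5 epochs,
one subject-wise 6/1/1 split — 112 clips in all, 14 of them from the
held-out test subject. These sizes are the package's choice of a
desk-scale demonstration; all rate/band/window constants that define the
method are kept at full-protocol values. Protocol-count checks (88
recordings, 1496 clips) run the generator at 16×16 px since only
durations and window arithmetic are consumed.

## Known limitations

* On clean synthetic cohorts the RMSE baseline also converges to usable
  RR estimates: the readout metric is itself phase-tolerant, so a model
  that learns the *average* belt lag still reads out the right
  frequency. The advantage of NMCC+AFD over RMSE is therefore modest
  here (and can vary with the cohort seed), whereas on real, noisy
  recordings pointwise losses are reported to fail outright. The
  generator's benign noise model is the difference.

* The Grad-CAM map explains a scalar summary (in-band output energy) of
  a signal-valued model; other scalar choices would weight channels
  differently.
* The hard AFD term is non-differentiable and contributes no gradient;
  training is driven by NMCC alone at the default settings, with AFD
  acting through model selection and evaluation.
* Cross-correlation is circular (all lags searched); a physiological
  maximum-lag cap is available (`band_limited_xcorr` searches all lags by
  design — restricting lags would require an explicit windowing of the
  correlation array by the caller).
* The transformer-based face detector used on real data is out of scope;
  the detector interface is the integration point.

## Grad-CAM for signal-valued models

Classic Grad-CAM averages activation gradients over all non-channel axes
to weight channels. For a model whose output is an oscillating signal,
the gradient of an energy-type scalar oscillates in phase with that
signal, and a time average cancels precisely the channels that carry the
respiration information. `grad_cam()` therefore averages gradients over
space only, keeps per-time-step channel weights, rectifies the weighted
activation sum, and averages the resulting map over time before
upsampling. On trained synthetic models this concentrates the heatmap on
the simulated breathing patch (nostril region, or mask region in mask
conditions).
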