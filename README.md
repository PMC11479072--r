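# thermoresp

Contactless respiration-rate (RR) estimation from thermal facial video,
as an R package. Breathing warms and cools the nostril region (or the
surface of a face mask) with each breath; a long-wave infrared camera
records this as a periodic intensity modulation. `thermoresp` implements
the full pipeline from raw thermal frame stacks to an RR in breaths per
minute (BPM), for researchers in remote vital-sign monitoring who want a
tested, reproducible reference implementation that runs end to end
without access to restricted participant data.

## The method

1. **Dynamic ROI cropping** — a face detector runs on every frame
   (track-by-detection, pluggable `function(frame) -> box` interface; a
   deterministic intensity/Otsu detector is bundled), boxes are
   median-smoothed over time, and the crops are bilinearly resized and
   stacked into a stabilized face video.
2. **Preprocessing** — block-average temporal downsampling from 30 Hz to
   a 5 Hz analysis rate, 10 s sliding windows with 5 s overlap (50-frame
   clips), per-clip z-normalization; the 2048 Hz respiratory-effort belt
   reference is anti-alias filtered and resampled onto the same grid.
3. **Signal estimation** — a temporal encoder–decoder 3D CNN (exactly one
   temporal-stride-2 encoder/decoder pair, so the internal Nyquist still
   covers the 0.7 Hz band edge) followed by a bi-directional LSTM and a
   per-step linear head regresses the 1-D respiratory waveform.
   The network, its backpropagation and the Adam optimizer are
   implemented in the package (R + C++ kernels), with finite-difference
   gradient tests.
4. **Phase-tolerant training objective** — the belt and the facial heat
   signal measure the same process out of phase, so training minimizes

   `loss = α·NMCC + (1−α)·min(1, AFD/3 BPM)`, `α = 0.5`,

   where NMCC is the negative maximum of the band-limited (0.05–0.7 Hz)
   normalized circular cross-correlation between prediction and target
   (exactly invariant to circular time shifts and positive rescaling),
   and AFD is the absolute in-band periodogram peak-frequency difference
   in BPM, saturating at 3 BPM.
5. **Readout** — third-order Butterworth bandpass (0.05–0.7 Hz, zero
   phase), then RR = periodogram peak frequency × 60, on a zero-padded
   spectrum with 0.073 BPM bins.

A synthetic thermal-recording generator (warm face ellipse, oscillating
nostril/mask patch, belt with configurable phase lag, Ornstein–Uhlenbeck
body sway, sensor noise, the four sitting/standing × mask/no-mask
conditions) makes every stage testable; see
`vignettes/thermoresp-methods.Rmd` for the model, its assumptions and
what the generator does and does not emulate.

## Worked example

```r
library(thermoresp)

rec <- simulate_recording(sim_config(subject_id = "S01", condition = "sit_nomask",
                                     duration_s = 30, frame_size = c(120, 160),
                                     rr_bpm = 14, rng_seed = 42))
rec
#> <thermal_recording> subject S01, sit_nomask: 900 frames of 120x160 @ 30 fps (30.0 s)
#>   true RR 14.0 BPM; belt 61440 samples @ 2048 Hz, lag 1.39 s

clips <- make_clips(rec, out_size = c(64, 64))   # detect, crop, downsample, window
length(clips)
#> [1] 5
clips[[1]]
#> <clip_sample> S01_sit_nomask_000: 64x64x50, target 50 samples @ 5 Hz, true RR 14.0 BPM

estimate_rr(bandpass(clips[[1]]$target))
#> <spectral_estimate> peak 0.229 Hz = 13.77 BPM (band 0.05-0.70 Hz)

## evaluation scaffolding accepts any predictor; the belt itself is the oracle
evaluate(function(cl) cl$target$samples, clips)
#> <eval_report> 5 clips (5 evaluated)
#>   RR error: 0.24 +/- 0.16 BPM
#>   max x-corr: 1.00 +/- 0.00
#>   clips with < 2 BPM error: 100.0%
```

The true rate is 14 BPM; the 13.77 BPM readout is the periodogram peak
of a single 10 s clip (spectral leakage on a 10 s window accounts for
the 0.2 BPM offset). `max x-corr` is the phase-tolerant waveform metric
(1.0 means the waveform is exact up to a time shift and scale), and
`clips with < 2 BPM error` is the fraction of clips whose RR error is
below 2 BPM.

Training the estimator end to end on a synthetic cohort, with
subject-wise train/validation/test splits:

```r
ex <- run_reference_experiment(seed = 1)   # ~10 min on one CPU
ex
#> <rr_experiment> 1 repeats, 112 clips total
#>   RR error: 0.62 +/- NA BPM (mean +/- sd across repeats)
#>   max x-corr: 0.94 +/- NA
#>   clips with < 2 BPM error: 100.0%
```

With the same cohort and seeds but the RMSE baseline loss
(`run_reference_experiment(seed = 1, loss = "rmse")`) the error rises to
0.95 BPM and the maximum cross-correlation drops to 0.89 — the
phase-tolerant objective wins even on clean synthetic data, where RMSE
must additionally model each recording's belt lag.

`fit_rr_estimator()` returns a classed model object with `print`,
`summary`, `coef`, `predict`, `plot` (loss history) and `residuals`
methods; `grad_cam()` produces a heatmap of the spatial regions driving
the estimate (on synthetic cohorts it concentrates on the simulated
breathing patch).

A thin command-line front end is installed with the package
(`inst/cli/thermoresp`): subcommands `simulate`, `describe` and
`experiment`.

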