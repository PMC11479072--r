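## Post-processing, RR readout, evaluation, explainability ----------------

## forward-backward (zero-phase) IIR filtering; signal::filtfilt pads
## internally, which behaves well even on short (50-sample) clips
filtfilt_padded <- function(bf, x) signal::filtfilt(bf, x)

#' Bandpass filter a respiratory signal
#'
#' Third-order Butterworth IIR bandpass over the respiration band
#' (0.05-0.7 Hz, i.e. 3-42 BPM), applied forward-backward so the output is
#' zero phase -- the downstream peak-power readout must not depend on the
#' filter's phase response. Output length equals input length.
#'
#' @param x A [resp_signal()] (or numeric vector with `fs` supplied).
#' @param band Passband `c(f_lo, f_hi)` in Hz (default `c(0.05, 0.7)`).
#' @param order Filter order (default 3).
#' @param fs Sampling rate if `x` is a bare vector.
#' @return Filtered signal, same type and length as the input.
#' @export
bandpass <- function(x, band = c(0.05, 0.7), order = 3, fs = NULL) {
  s <- as_samples(x)
  fs <- if (inherits(x, "resp_signal")) x$fs else fs
  if (is.null(fs)) stopf("supply `fs` for a bare numeric signal")
  if (band[2] >= fs / 2)
    stopf("band upper edge %g Hz must lie below the Nyquist rate %g Hz",
          band[2], fs / 2)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- filtfilt_padded(bf, s)
  if (inherits(x, "resp_signal")) resp_signal(y, fs, normalized = x$normalized) else y
}

#' Respiration-rate readout by periodogram peak
#'
#' Zero-padded periodogram of the (zero-meaned) signal; the peak is the
#' argmax restricted to the respiration band, ties broken toward the lower
#' frequency. With the default `fft_len = 4096` at 5 Hz the frequency bins
#' are 0.073 BPM wide.
#'
#' @param x A [resp_signal()] or numeric vector.
#' @param fft_len Zero-padded transform length (default 4096).
#' @param band Search band in Hz (default `c(0.05, 0.7)`, i.e. 3-42 BPM).
#' @param fs Sampling rate if `x` is a bare vector.
#' @return An object of class `spectral_estimate`: list with `freqs`,
#'   `power` (in-band periodogram), `peak_freq` (Hz) and `peak_bpm`.
#' @export
estimate_rr <- function(x, fft_len = 4096, band = c(0.05, 0.7), fs = NULL) {
  s <- as_samples(x)
  fs <- if (inherits(x, "resp_signal")) x$fs else fs
  if (is.null(fs)) stopf("supply `fs` for a bare numeric signal")
  n <- length(s)
  L <- max(fft_len, n)
  z <- c(s - mean(s), numeric(L - n))
  P <- Mod(stats::fft(z))^2
  f <- (0:(L - 1)) * fs / L
  keep <- which(f >= band[1] - 1e-12 & f <= band[2] + 1e-12 & f <= fs / 2)
  if (length(keep) == 0) stopf("no frequency bin inside the band")
  Pk <- P[keep]
  ## refuse when in-band power is a negligible fraction of the total
  ## (leakage from out-of-band components only)
  if (sum(Pk) <= 1e-3 * max(sum(P), .Machine$double.xmin))
    stopf("no usable in-band energy; RR undefined")
  i <- which.max(Pk)   # first maximum = lowest frequency on ties
  structure(list(freqs = f[keep], power = Pk, peak_freq = f[keep][i],
                 peak_bpm = hz_to_bpm(f[keep][i])),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> peak %.3f Hz = %.2f BPM (band %.2f-%.2f Hz)\n",
              x$peak_freq, x$peak_bpm, min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Evaluate an estimator on a set of clips
#'
#' For each clip: predict the respiratory signal, bandpass it, read out the
#' RR as the periodogram peak, and compare with the true rate. The maximum
#' band-limited cross-correlation against the (unfiltered) normalized
#' target is recorded as a waveform-quality metric (phase-tolerant by
#' construction). Clips whose prediction has no in-band energy are
#' recorded as missing with a reason rather than failing the run.
#'
#' @param model An `rr_model`, an `rr_estimator`, or a plain function
#'   `clip_sample -> numeric signal` (e.g. an oracle predictor for
#'   self-consistency checks).
#' @param clips List of `clip_sample` objects.
#' @param loss_cfg A [loss_config()] (band, fft length, sampling rate).
#' @return An object of class `eval_report`: `$per_clip` data frame
#'   (`clip_id, subject_id, condition, true_bpm, est_bpm, abs_error_bpm,
#'   max_xcorr`), and `$aggregates` (mean/sd error, mean/sd max x-corr,
#'   `pct_under_2bpm`, counts).
#' @export
evaluate <- function(model, clips, loss_cfg = loss_config()) {
  if (inherits(model, "rr_estimator")) model <- model$model
  predictor <- if (is.function(model)) model
    else function(cl) forward_one(model, clip_frames(cl))$y
  stopifnot(length(clips) > 0)
  rows <- vector("list", length(clips))
  for (i in seq_along(clips)) {
    cl <- clips[[i]]
    row <- data.frame(clip_id = cl$clip_id %||% sprintf("clip%03d", i),
                      subject_id = cl$subject_id %||% NA_character_,
                      condition = cl$condition %||% NA_character_,
                      true_bpm = cl$truth_rr_bpm,
                      est_bpm = NA_real_, abs_error_bpm = NA_real_,
                      max_xcorr = NA_real_, note = "")
    res <- tryCatch({
      y <- predictor(cl)
      yf <- bandpass(y, band = loss_cfg$band, fs = loss_cfg$fs)
      est <- estimate_rr(yf, fft_len = loss_cfg$fft_len, band = loss_cfg$band,
                         fs = loss_cfg$fs)
      mx <- -nmcc(y, cl$target, loss_cfg)
      list(est = est$peak_bpm, mx = mx)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$note <- conditionMessage(res)
    } else {
      row$est_bpm <- res$est
      row$abs_error_bpm <- abs(res$est - cl$truth_rr_bpm)
      row$max_xcorr <- res$mx
    }
    rows[[i]] <- row
  }
  per_clip <- do.call(rbind, rows)
  ok <- !is.na(per_clip$abs_error_bpm)
  agg <- list(
    n_clips = nrow(per_clip), n_evaluated = sum(ok), n_missing = sum(!ok),
    mean_abs_error_bpm = mean(per_clip$abs_error_bpm[ok]),
    sd_abs_error_bpm = stats::sd(per_clip$abs_error_bpm[ok]),
    mean_max_xcorr = mean(per_clip$max_xcorr[ok]),
    sd_max_xcorr = stats::sd(per_clip$max_xcorr[ok]),
    pct_under_2bpm = 100 * sum(per_clip$abs_error_bpm[ok] < 2) / sum(ok)
  )
  structure(list(per_clip = per_clip, aggregates = agg), class = "eval_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eval_report <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("<eval_report> %d clips (%d evaluated)\n", a$n_clips, a$n_evaluated))
  cat(sprintf("  RR error: %.2f +/- %.2f BPM\n", a$mean_abs_error_bpm, a$sd_abs_error_bpm))
  cat(sprintf("  max x-corr: %.2f +/- %.2f\n", a$mean_max_xcorr, a$sd_max_xcorr))
  cat(sprintf("  clips with < 2 BPM error: %.1f%%\n", a$pct_under_2bpm))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Per-clip table as CSV and aggregates as JSON.
#' @param report An `eval_report`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return The report, invisibly.
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_clip, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report$aggregates, json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Grad-CAM heatmap for one clip
#'
#' Gradient-weighted class activation mapping on the final 3D convolution
#' layer (the last layer that retains spatial structure). The scalar
#' differentiated is the in-band energy of the output signal; gradients at
#' the final conv activations are averaged over space to give channel
#' weights per time step (for an oscillatory output the gradients
#' oscillate in phase with the signal, so averaging them over time as
#' well would cancel exactly the respiration-carrying channels), the
#' weighted activation sum is rectified, averaged over time, bilinearly
#' upsampled to the input size and min-max scaled to \[0, 1\] (an
#' identically zero map, e.g. from a zeroed head, stays zero).
#'
#' @param model An `rr_model` or `rr_estimator`.
#' @param clip A `clip_sample` or H x W x T array.
#' @param loss_cfg A [loss_config()] (defines the band).
#' @return An H x W matrix in \[0, 1\] matching the clip's spatial size.
#' @export
grad_cam <- function(model, clip, loss_cfg = loss_config()) {
  if (inherits(model, "rr_estimator")) model <- model$model
  stopifnot(inherits(model, "rr_model"))
  x <- clip_frames(clip)
  cam_layer <- length(model$plan)
  fwd <- forward_one(model, x, keep_cache = TRUE)
  y <- fwd$y
  ## scalar: in-band energy E = || band_filter(y) ||^2; dE/dy = 2 * B y
  by <- band_filter(y - mean(y), loss_cfg$fs, loss_cfg$band)
  dy <- 2 * by
  dy <- dy - mean(dy)   # through the zero-meaning
  bwd <- backward_one(model, fwd, dy, cam_layer = cam_layer)
  A <- fwd$cache[[cam_layer]]$relu_out
  G <- bwd$cam_grad
  d <- dim(A)
  W <- apply(G, c(3, 4), mean)   # spatially averaged gradients, per (t, channel)
  cam <- array(0, dim = d[1:3])
  for (t in seq_len(d[3])) for (c in seq_len(d[4]))
    cam[, , t] <- cam[, , t] + W[t, c] * A[, , t, c]
  cam <- pmax(cam, 0)
  cam2 <- apply(cam, c(1, 2), mean)   # average over time
  out_size <- dim(x)[1:2]
  cam_up <- cpp_crop_resize(array(cam2, dim = c(d[1], d[2], 1)),
                            matrix(c(0, 0, d[2], d[1]), 1), out_size[1], out_size[2])[, , 1]
  rng <- range(cam_up)
  if (rng[2] > rng[1]) (cam_up - rng[1]) / (rng[2] - rng[1]) else cam_up * 0
}
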