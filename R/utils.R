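#' Convert between breaths per minute and Hertz
#'
#' Respiration rates are reported in breaths per minute (BPM); spectral
#' machinery works in Hz. 1 Hz corresponds to 60 BPM.
#'
#' @param bpm Respiration rate in breaths per minute.
#' @param hz Frequency in Hz.
#' @return The converted value.
#' @examples
#' bpm_to_hz(42)  # 0.7 Hz, the upper edge of the respiration band
#' hz_to_bpm(0.05)
#' @export
bpm_to_hz <- function(bpm) bpm / 60

#' @rdname bpm_to_hz
#' @export
hz_to_bpm <- function(hz) hz * 60

## physiological respiration band used throughout: 3--42 BPM
RESP_BAND_HZ <- c(0.05, 0.7)

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' seeded simulation helpers do not disturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## derive a child seed < 2^31 from a base seed and stream indices
derive_seed <- function(base, i, j = 0L) {
  (as.double(base) * 7919 + i * 104729 + j * 1299721) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == round(x)

#' Construct a sampled respiratory waveform
#'
#' A `resp_signal` is a 1-D sampled waveform with its sampling rate and a
#' flag recording whether it has been z-score normalized. It is the common
#' currency between the belt reference, the clip targets and the model
#' output.
#'
#' @param samples Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param normalized Logical; has the signal been z-scored?
#' @return An object of class `resp_signal`.
#' @export
resp_signal <- function(samples, fs, normalized = FALSE) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stopf("`fs` must be a single positive number")
  if (length(samples) < 2) stopf("a resp_signal needs at least 2 samples")
  structure(list(samples = samples, fs = fs, normalized = isTRUE(normalized)),
            class = "resp_signal")
}

#' @export
print.resp_signal <- function(x, ...) {
  cat(sprintf("<resp_signal> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
length.resp_signal <- function(x) length(x$samples)

## coerce numeric vector or resp_signal to samples, checking fs if given
as_samples <- function(x, fs = NULL) {
  if (inherits(x, "resp_signal")) {
    if (!is.null(fs) && abs(x$fs - fs) > 1e-9)
      stopf("signal sampling rate (%g Hz) does not match expected %g Hz", x$fs, fs)
    x$samples
  } else as.numeric(x)
}

signal_fs <- function(x, default) if (inherits(x, "resp_signal")) x$fs else default

#' Z-score normalize a respiratory signal
#'
#' @param x A `resp_signal` or numeric vector.
#' @return Same type as input, zero mean and unit (sample) standard deviation.
#' @export
normalize_signal <- function(x) {
  s <- as_samples(x)
  sdv <- stats::sd(s)
  if (!is.finite(sdv) || sdv == 0)
    stopf("cannot normalize a constant signal (zero variance)")
  out <- (s - mean(s)) / sdv
  if (inherits(x, "resp_signal")) resp_signal(out, x$fs, normalized = TRUE) else out
}
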