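## Phase-tolerant training objective --------------------------------------
##
## The estimator is trained against a chest-belt reference that is not
## phase aligned with the facial heat signal, so pointwise losses (RMSE)
## penalize a correct but shifted waveform. The objective used here is
##
##   loss = alpha * NMCC + (1 - alpha) * min(1, AFD / 3 BPM)
##
## where NMCC is the negative maximum of the band-limited, normalized
## circular cross-correlation between prediction and target (invariant to
## circular time shifts and positive rescaling), and AFD is the absolute
## difference between the two in-band periodogram peak frequencies,
## saturating at 3 BPM. The respiration band is 0.05-0.7 Hz (3-42 BPM).

#' Loss configuration
#'
#' @param alpha Weight of the NMCC term in \[0, 1\] (default 0.5, equal
#'   importance of waveform correlation and peak-frequency agreement).
#' @param band Respiration band `c(f_lo, f_hi)` in Hz (default
#'   `c(0.05, 0.7)`, i.e. 3-42 BPM).
#' @param afd_saturation AFD saturation in BPM (default 3): any peak
#'   separation at or above this contributes the full unit penalty.
#' @param fs Signal sampling rate in Hz (default 5).
#' @param fft_len Zero-padded transform length for peak-frequency
#'   estimation (default 4096; at 5 Hz this gives 0.073 BPM bins -- a raw
#'   50-point spectrum would have 6 BPM bins, far too coarse).
#' @param soft_afd Use the softmax expected-frequency surrogate for AFD so
#'   that it carries gradients (default `FALSE`: the literal hard argmax,
#'   through which no gradient flows).
#' @param soft_temp Softmax temperature for `soft_afd` (applied to the
#'   sum-normalized periodogram; default 0.01).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.5, band = c(0.05, 0.7), afd_saturation = 3,
                        fs = 5, fft_len = 4096, soft_afd = FALSE,
                        soft_temp = 0.01) {
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2))
    stopf("need 0 < f_lo < f_hi < fs/2; got [%g, %g] at fs = %g", band[1], band[2], fs)
  if (afd_saturation <= 0) stopf("afd_saturation must be positive (BPM)")
  if (!is_count(fft_len)) stopf("fft_len must be a positive count")
  structure(list(alpha = alpha, band = band, afd_saturation = afd_saturation,
                 fs = fs, fft_len = as.integer(fft_len),
                 soft_afd = isTRUE(soft_afd), soft_temp = soft_temp),
            class = "loss_config")
}

## brick-wall DFT mask at length n: 1 on [f_lo, f_hi] and its mirror image
band_mask <- function(n, fs, band) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  as.numeric(f >= band[1] - 1e-12 & f <= band[2] + 1e-12)
}

## brick-wall band filter (also removes the mean: bin 0 is out of band)
band_filter <- function(x, fs, band) {
  n <- length(x)
  Re(stats::fft(stats::fft(x) * band_mask(n, fs, band), inverse = TRUE)) / n
}

check_pair <- function(a, b, cfg) {
  fa <- signal_fs(a, cfg$fs); fb <- signal_fs(b, cfg$fs)
  if (abs(fa - fb) > 1e-9) stopf("signals have different sampling rates")
  if (abs(fa - cfg$fs) > 1e-9)
    stopf("signal rate %g Hz does not match loss_config fs = %g Hz", fa, cfg$fs)
  a <- as_samples(a); b <- as_samples(b)
  if (length(a) != length(b)) stopf("signals have different lengths")
  if (length(a) < 4) stopf("signals too short")
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b)))
    stopf("non-finite values in input signals")
  list(a = a, b = b)
}

#' Band-limited normalized circular cross-correlation
#'
#' Both signals are zero-meaned, transformed, restricted to the respiration
#' band by a brick-wall spectral mask, and cross-correlated over all
#' circular lags via the inverse transform of `f(A') * f(B')*` (the
#' conjugate spectrum product). The result is normalized by the product of
#' the band-filtered signals' Euclidean norms, so values lie in \[-1, 1\]
#' and the maximum over lags is 1 exactly when one signal is a circular
#' shift (and/or positive rescaling) of the other.
#'
#' @param a,b Equal-length signals ([resp_signal()] or numeric vectors) at
#'   the configured sampling rate.
#' @param cfg A [loss_config()].
#' @return Numeric vector of correlations, one per circular lag
#'   `0 .. n-1` (attribute `lags_s` gives lags in seconds).
#' @export
band_limited_xcorr <- function(a, b, cfg = loss_config()) {
  p <- check_pair(a, b, cfg)
  n <- length(p$a)
  m <- band_mask(n, cfg$fs, cfg$band)
  if (sum(m) == 0) stopf("no DFT bin falls inside the band; signal too short")
  A <- stats::fft(p$a - mean(p$a)) * m
  B <- stats::fft(p$b - mean(p$b)) * m
  na <- sqrt(sum(Mod(A)^2) / n)   # Parseval: ||band-filtered a||
  nb <- sqrt(sum(Mod(B)^2) / n)
  tot_a <- sqrt(sum((p$a - mean(p$a))^2)); tot_b <- sqrt(sum((p$b - mean(p$b))^2))
  if (na <= 1e-10 * max(tot_a, .Machine$double.xmin) || na == 0)
    stopf("signal `a` has no in-band energy; correlation undefined")
  if (nb <= 1e-10 * max(tot_b, .Machine$double.xmin) || nb == 0)
    stopf("signal `b` has no in-band energy; correlation undefined")
  r <- Re(stats::fft(A * Conj(B), inverse = TRUE)) / n / (na * nb)
  attr(r, "lags_s") <- (0:(n - 1)) / cfg$fs
  r
}

#' Negative maximum cross-correlation (NMCC)
#'
#' The negated peak over all circular lags of [band_limited_xcorr()].
#' Equals -1 exactly when the two signals agree up to a circular time
#' shift and positive scaling; lies in \[-1, 1\].
#'
#' @inheritParams band_limited_xcorr
#' @return A scalar.
#' @export
nmcc <- function(a, b, cfg = loss_config()) {
  -max(band_limited_xcorr(a, b, cfg))
}

## gradient of nmcc(a, b) with respect to `a` (analytic; the band filter
## is a self-adjoint projection, so it acts as identity on the
## band-limited factors of the quotient rule)
nmcc_grad <- function(a, b, cfg = loss_config()) {
  p <- check_pair(a, b, cfg)
  n <- length(p$a)
  fa <- band_filter(p$a, cfg$fs, cfg$band)
  fb <- band_filter(p$b, cfg$fs, cfg$band)
  na <- sqrt(sum(fa^2)); nb <- sqrt(sum(fb^2))
  if (na == 0 || nb == 0) stopf("no in-band energy; gradient undefined")
  r <- band_limited_xcorr(p$a, p$b, cfg)
  k <- which.max(r) - 1L
  cmax <- r[k + 1L]
  ## r[k] = sum_t fa[t] fb[(t - k) mod n] / (na nb); s = fb shifted by +k
  s <- fb[((0:(n - 1)) - k) %% n + 1L]
  -(s / (na * nb) - cmax * fa / na^2)
}

## in-band periodogram peak frequency (zero-padded; ties -> lower freq)
peak_frequency <- function(x, fs, band, fft_len) {
  x <- as_samples(x)
  n <- length(x)
  L <- max(fft_len, n)
  z <- c(x - mean(x), numeric(L - n))
  P <- Mod(stats::fft(z))^2
  f <- (0:(L - 1)) * fs / L
  keep <- which(f >= band[1] - 1e-12 & f <= band[2] + 1e-12 & f <= fs / 2)
  if (length(keep) == 0 ||
      sum(P[keep]) <= 1e-3 * max(sum(P), .Machine$double.xmin))
    stopf("no usable in-band energy; peak frequency undefined")
  f[keep[which.max(P[keep])]]   # which.max returns the first = lowest freq
}

#' Absolute frequency difference (AFD) in BPM
#'
#' The absolute difference between the in-band periodogram peak
#' frequencies of the two signals, converted to breaths per minute.
#' Spectra are zero-padded to `cfg$fft_len` bins so that the peak
#' resolution (0.073 BPM at the defaults) is far below the 3 BPM
#' saturation.
#'
#' @inheritParams band_limited_xcorr
#' @return A scalar in BPM (>= 0).
#' @export
afd_bpm <- function(a, b, cfg = loss_config()) {
  p <- check_pair(a, b, cfg)
  if (cfg$soft_afd) {
    abs(soft_peak_frequency(p$a, cfg)$f - soft_peak_frequency(p$b, cfg)$f) * 60
  } else {
    abs(peak_frequency(p$a, cfg$fs, cfg$band, cfg$fft_len) -
        peak_frequency(p$b, cfg$fs, cfg$band, cfg$fft_len)) * 60
  }
}

## softmax expected in-band frequency (differentiable AFD surrogate);
## returns the expectation and the pieces needed for its gradient
soft_peak_frequency <- function(x, cfg) {
  n <- length(x)
  L <- max(cfg$fft_len, n)
  z <- c(x - mean(x), numeric(L - n))
  X <- stats::fft(z)
  f <- (0:(L - 1)) * cfg$fs / L
  keep <- which(f >= cfg$band[1] - 1e-12 & f <= cfg$band[2] + 1e-12 & f <= cfg$fs / 2)
  P <- Mod(X[keep])^2
  if (sum(P) <= 0) stopf("no in-band energy; peak frequency undefined")
  q <- P / sum(P)
  w <- exp((q - max(q)) / cfg$soft_temp)
  w <- w / sum(w)
  list(f = sum(w * f[keep]), w = w, q = q, P = P, X = X, keep = keep, L = L,
       fgrid = f[keep])
}

## gradient of the soft expected frequency with respect to x
soft_peak_frequency_grad <- function(x, cfg) {
  n <- length(x)
  sp <- soft_peak_frequency(x, cfg)
  ## dP_k/dz_t = 2 Re(conj(X_k) exp(-2 pi i k (t-1) / L))
  kk <- sp$keep - 1L
  tt <- 0:(n - 1)
  ang <- 2 * pi * outer(kk, tt) / sp$L           # |keep| x n
  dP <- 2 * (Re(sp$X[sp$keep]) * cos(ang) - Im(sp$X[sp$keep]) * sin(ang))
  sP <- sum(sp$P)
  dq <- (dP - sp$q %o% colSums(dP)) / sP          # |keep| x n
  ## softmax jacobian: dw_j = w_j (dq_j - sum_l w_l dq_l) / temp
  wdq <- colSums(sp$w * dq)
  dw <- (sp$w * sweep(dq, 2, wdq)) / cfg$soft_temp
  g <- colSums(sp$fgrid * dw)
  g - mean(g)                                     # through the zero-meaning
}

#' Combined phase-tolerant loss
#'
#' `alpha * NMCC + (1 - alpha) * min(1, AFD / saturation)`. For the default
#' `alpha = 0.5` the range is \[-0.5, 1\]; identical (or circularly
#' shifted, or positively rescaled) signals give -0.5, and any peak
#' separation >= 3 BPM contributes the full `(1 - alpha)` penalty. For
#' batches (lists of signal pairs) the loss is the mean over clips.
#'
#' @param pred,target Signals as in [band_limited_xcorr()], or lists of
#'   such signals (a batch).
#' @param cfg A [loss_config()].
#' @return A scalar loss.
#' @seealso [loss_components()] for the two terms separately.
#' @export
combined_loss <- function(pred, target, cfg = loss_config()) {
  if (is.list(pred) && !inherits(pred, "resp_signal")) {
    stopifnot(length(pred) == length(target))
    return(mean(mapply(function(p, t) combined_loss(p, t, cfg), pred, target)))
  }
  lc <- loss_components(pred, target, cfg)
  cfg$alpha * lc$nmcc + (1 - cfg$alpha) * lc$afd_unit
}

#' Loss components
#'
#' @inheritParams combined_loss
#' @return A list with `nmcc` (in \[-1, 1\]), `afd_bpm`, and `afd_unit`
#'   (`min(1, afd_bpm / saturation)`).
#' @export
loss_components <- function(pred, target, cfg = loss_config()) {
  v_nmcc <- nmcc(pred, target, cfg)
  v_afd <- afd_bpm(pred, target, cfg)
  list(nmcc = v_nmcc, afd_bpm = v_afd,
       afd_unit = min(1, v_afd / cfg$afd_saturation))
}

## gradient of the combined loss with respect to `pred`; the hard-argmax
## AFD carries no gradient (only NMCC drives learning unless soft_afd)
combined_loss_grad <- function(pred, target, cfg = loss_config()) {
  g <- cfg$alpha * nmcc_grad(pred, target, cfg)
  if (cfg$soft_afd && cfg$alpha < 1) {
    p <- check_pair(pred, target, cfg)
    fa <- soft_peak_frequency(p$a, cfg)$f
    fb <- soft_peak_frequency(p$b, cfg)$f
    afd <- abs(fa - fb) * 60
    if (afd < cfg$afd_saturation) {
      g <- g + (1 - cfg$alpha) * (60 * sign(fa - fb) / cfg$afd_saturation) *
        soft_peak_frequency_grad(p$a, cfg)
    }
  }
  g
}
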