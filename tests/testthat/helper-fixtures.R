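# Shared fixtures (memoized so several test files can reuse one small
# recording) and independent brute-force oracles for the spectral checks.

fixture_env <- new.env()

fixture <- function(name, expr) {
  if (!exists(name, envir = fixture_env, inherits = FALSE))
    assign(name, expr, envir = fixture_env)
  get(name, envir = fixture_env, inherits = FALSE)
}

tiny_recording <- function() fixture("tiny_rec", simulate_recording(
  sim_config(duration_s = 20, frame_size = c(60, 80), rr_bpm = 15,
             belt_lag_s = 0.8, rng_seed = 7)))

tiny_clips <- function() fixture("tiny_clips",
  make_clips(tiny_recording(), out_size = c(32, 32)))

tiny_model_config <- function(seed = 3, spatial = 16, ...) {
  model_config(vanilla_pre = c(2), encoder_channels = 3, decoder_channels = 3,
               vanilla_post = c(3), lstm_hidden = 4,
               spatial_in = c(spatial, spatial), rng_seed = seed, ...)
}

tiny_model <- function() fixture("tiny_model",
  build_model(tiny_model_config(), quiet = TRUE))

# clips matched to the tiny model's 16x16 input
tiny_clips16 <- function() fixture("tiny_clips16",
  make_clips(tiny_recording(), out_size = c(16, 16)))

## ---- independent oracles (explicit-sum DFT, O(n^2); no stats::fft) ----

oracle_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  drop(W %*% x)
}

oracle_idft <- function(X) {
  n <- length(X)
  k <- 0:(n - 1)
  W <- exp(2i * pi * outer(k, k) / n)
  drop(W %*% X) / n
}

oracle_band_filter <- function(x, fs, band) {
  n <- length(x)
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  m <- as.numeric(f >= band[1] - 1e-12 & f <= band[2] + 1e-12)
  Re(oracle_idft(oracle_dft(x - mean(x)) * m))
}

# normalized circular cross-correlation of band-filtered signals,
# computed directly in the time domain
oracle_band_xcorr <- function(a, b, fs = 5, band = c(0.05, 0.7)) {
  n <- length(a)
  fa <- oracle_band_filter(a, fs, band)
  fb <- oracle_band_filter(b, fs, band)
  r <- vapply(0:(n - 1), function(k) {
    sum(fa * fb[((0:(n - 1)) - k) %% n + 1])
  }, numeric(1))
  r / sqrt(sum(fa^2)) / sqrt(sum(fb^2))
}

oracle_nmcc <- function(a, b, fs = 5, band = c(0.05, 0.7)) {
  -max(oracle_band_xcorr(a, b, fs, band))
}

# periodogram of a series by explicit sums, zero-padded; returns peak
# frequency restricted to [lo, hi]
oracle_peak_freq <- function(x, fs, band, pad = 4096) {
  n <- length(x)
  L <- max(pad, n)
  z <- x - mean(x)
  f <- (0:(L - 1)) * fs / L
  keep <- f >= band[1] & f <= band[2] & f <= fs / 2
  fk <- f[keep]
  P <- vapply(fk, function(ff) {
    Mod(sum(z * exp(-2i * pi * ff * (0:(n - 1)) / fs)))^2
  }, numeric(1))
  fk[which.max(P)]
}

circshift <- function(x, k) x[((seq_along(x) - 1 - k) %% length(x)) + 1]
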