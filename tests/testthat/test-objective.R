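# The FFT-based band-limited cross-correlation is checked against an
# explicit-sum, time-domain oracle (helper-fixtures.R) that shares no code
# with the implementation.

cfg <- loss_config()
t50 <- (0:49) / 5

test_that("FFT cross-correlation matches the O(n^2) time-domain oracle", {
  set.seed(10)
  for (i in 1:50) {
    a <- rnorm(50); b <- rnorm(50)
    r_fft <- band_limited_xcorr(a, b, cfg)
    r_oracle <- oracle_band_xcorr(a, b)
    expect_lt(max(abs(as.numeric(r_fft) - r_oracle)), 1e-8)
  }
})

test_that("normalized autocorrelation peaks at exactly 1", {
  x <- sin(2 * pi * 0.25 * t50) + 0.4 * sin(2 * pi * 0.4 * t50 + 1)
  expect_equal(nmcc(x, x, cfg), -1)
  r <- band_limited_xcorr(x, x, cfg)
  expect_true(all(r <= 1 + 1e-12 & r >= -1 - 1e-12))
})

test_that("circular shifts leave the maximum at 1 and move the argmax lag", {
  x <- sin(2 * pi * 0.2 * t50) + 0.2 * cos(2 * pi * 0.5 * t50)
  for (k in c(1, 7, 25, 49)) {
    b <- circshift(x, k)
    r <- band_limited_xcorr(x, b, cfg)
    expect_equal(max(r), 1)
    ## r[j] = sum fa[t] fb[t - j]; fb[t] = fa[t - k] has argmax at lag n - k
    expect_equal(which.max(r) - 1L, (50 - k) %% 50)
    expect_equal(nmcc(x, b, cfg), -1)
  }
})

test_that("a sign flip is absorbed by a lag for in-band sinusoids", {
  ## 0.3 Hz = 3 cycles in the 10 s window: a half-period is an integer
  ## number of samples, so some circular lag aligns x with -x exactly
  x <- sin(2 * pi * 0.3 * t50)
  expect_equal(nmcc(x, -x, cfg), oracle_nmcc(x, -x), tolerance = 1e-10)
  expect_equal(nmcc(x, -x, cfg), -1, tolerance = 1e-9)
})

test_that("signals without in-band energy are rejected", {
  inband <- sin(2 * pi * 0.25 * t50)
  outband <- sin(2 * pi * 2 * t50)      # 2 Hz: outside [0.05, 0.7]
  expect_error(band_limited_xcorr(inband, outband, cfg), "in-band energy")
  expect_error(nmcc(outband, inband, cfg), "in-band energy")
  expect_error(afd_bpm(rep(0, 50), inband, cfg), "in-band energy")
})

test_that("AFD reports peak separations in BPM with fine resolution", {
  ## 60 s signals: the fft_len = 4096 grid (0.073 BPM bins) then resolves
  ## 0.05 Hz separations exactly; 10 s clips carry ~0.4 BPM of leakage
  t300 <- (0:299) / 5
  s020 <- sin(2 * pi * 0.20 * t300)
  s025 <- sin(2 * pi * 0.25 * t300)
  s050 <- sin(2 * pi * 0.50 * t300)
  bin_bpm <- 60 * 5 / 4096
  expect_equal(afd_bpm(s020, s020, cfg), 0)
  expect_lt(abs(afd_bpm(s020, s025, cfg) - 3), 2 * bin_bpm + 1e-9)
  expect_lt(abs(afd_bpm(s020, s050, cfg) - 18), 2 * bin_bpm + 1e-9)
  ## clip-scale (50-sample) signals stay well inside the 3 BPM saturation
  expect_lt(abs(afd_bpm(sin(2 * pi * 0.20 * t50), sin(2 * pi * 0.25 * t50),
                        cfg) - 3), 0.5)
})

test_that("combined loss identities and saturation", {
  x <- sin(2 * pi * 0.25 * t50) + 0.3 * sin(2 * pi * 0.45 * t50)
  expect_equal(combined_loss(x, x, cfg), -0.5)
  ## phase tolerance: the NMCC term absorbs a circular shift exactly; the
  ## hard AFD of a 10 s clip carries phase-dependent spectral leakage that
  ## stays far below its 3 BPM saturation (on-grid tones keep the shifted
  ## clip free of wrap-around discontinuities)
  xg <- sin(2 * pi * 0.2 * t50) + 0.3 * sin(2 * pi * 0.4 * t50)
  for (k in c(5, 11, 23)) {
    lc <- loss_components(xg, circshift(xg, k), cfg)
    expect_equal(lc$nmcc, -1)
    expect_lt(lc$afd_bpm, 1.5)
    expect_lt(combined_loss(xg, circshift(xg, k), cfg), -0.25)
  }

  ## saturated AFD: 0.2 vs 0.5 Hz is 18 BPM >= 3 BPM -> unit penalty
  s020 <- sin(2 * pi * 0.20 * t50); s050 <- sin(2 * pi * 0.50 * t50)
  lc <- loss_components(s020, s050, cfg)
  expect_equal(lc$afd_unit, 1)
  expect_equal(combined_loss(s020, s050, cfg),
               0.5 * oracle_nmcc(s020, s050) + 0.5, tolerance = 1e-8)
})

test_that("loss is invariant to positive rescaling and bounded", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(50); b <- rnorm(50)
    l <- combined_loss(a, b, cfg)
    expect_equal(combined_loss(3.7 * a, b, cfg), l, tolerance = 1e-9)
    expect_equal(combined_loss(a, 0.2 * b, cfg), l, tolerance = 1e-9)
    expect_gte(l, -cfg$alpha)
    expect_lte(l, cfg$alpha + (1 - cfg$alpha))
  }
})

test_that("the AFD term is non-decreasing up to saturation and flat beyond", {
  base <- sin(2 * pi * 0.20 * t50)
  seps <- c(0, 0.5, 1, 2, 3.5, 6, 12)   # BPM; peak estimates carry up to
  units <- vapply(seps, function(d) {   # ~0.15 BPM of leakage error
    other <- sin(2 * pi * (0.20 + d / 60) * t50)
    loss_components(base, other, cfg)$afd_unit
  }, numeric(1))
  expect_true(all(diff(units) >= -0.05))
  expect_true(all(units[seps >= 3.5] == 1))   # saturation is exact
})

test_that("batch loss is the mean over clips", {
  a1 <- sin(2 * pi * 0.2 * t50); a2 <- sin(2 * pi * 0.4 * t50)
  l1 <- combined_loss(a1, a1, cfg); l2 <- combined_loss(a1, a2, cfg)
  expect_equal(combined_loss(list(a1, a1), list(a1, a2), cfg), (l1 + l2) / 2)
})

test_that("the NMCC gradient matches finite differences", {
  ns <- asNamespace("thermoresp")
  set.seed(5)
  a <- rnorm(30); b <- rnorm(30)
  g <- ns$nmcc_grad(a, b, cfg)
  num <- vapply(seq_along(a), function(i) {
    e <- 1e-6; ap <- a; am <- a
    ap[i] <- a[i] + e; am[i] <- a[i] - e
    (nmcc(ap, b, cfg) - nmcc(am, b, cfg)) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(g - num)), 1e-7)
})

test_that("the soft AFD surrogate is differentiable and near the hard AFD", {
  ns <- asNamespace("thermoresp")
  scfg <- loss_config(soft_afd = TRUE, soft_temp = 0.05, fft_len = 256)
  set.seed(6)
  a <- rnorm(40)
  g <- ns$soft_peak_frequency_grad(a, scfg)
  num <- vapply(seq_along(a), function(i) {
    e <- 1e-6; ap <- a; am <- a
    ap[i] <- a[i] + e; am[i] <- a[i] - e
    (ns$soft_peak_frequency(ap, scfg)$f - ns$soft_peak_frequency(am, scfg)$f) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(g - num)), 1e-7)

  ## for a sharply peaked spectrum the surrogate agrees with the hard peak
  sharp <- loss_config(soft_afd = TRUE, soft_temp = 0.005)
  s020 <- sin(2 * pi * 0.20 * (0:199) / 5); s030 <- sin(2 * pi * 0.30 * (0:199) / 5)
  expect_lt(abs(afd_bpm(s020, s030, sharp) - 6), 0.3)
})

test_that("loss configuration validates its fields", {
  expect_error(loss_config(alpha = 1.5), "alpha")
  expect_error(loss_config(band = c(0.7, 0.05)), "f_lo")
  expect_error(loss_config(band = c(0.05, 3), fs = 5), "f_lo")
  expect_error(loss_config(afd_saturation = 0), "positive")
})
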