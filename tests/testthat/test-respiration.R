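test_that("the third-order bandpass passes the band and rejects outside it", {
  fs <- 5
  t <- (0:149) / fs
  inband <- sin(2 * pi * 0.25 * t)
  y <- bandpass(inband, fs = fs)
  expect_length(y, length(inband))
  expect_lt(abs(sd(y) / sd(inband) - 1), 0.05)     # passband: within 5%

  outband <- sin(2 * pi * 2.0 * t)
  expect_lt(sd(bandpass(outband, fs = fs)) / sd(outband), 0.1)  # > 90% attenuated

  expect_equal(bandpass(rep(0, 100), fs = fs), rep(0, 100))
  expect_error(bandpass(inband, fs = 1.2), "Nyquist")

  ## resp_signal in, resp_signal out
  rs <- bandpass(resp_signal(inband, fs))
  expect_s3_class(rs, "resp_signal")
})

test_that("estimate_rr recovers pure sinusoids across the whole band", {
  fs <- 5
  bin_bpm <- 60 * fs / 4096
  t <- (0:299) / fs                 # 60 s of signal
  for (bpm in seq(3, 42, by = 3)) {
    x <- sin(2 * pi * (bpm / 60) * t + 0.7)
    est <- estimate_rr(x, fs = fs)
    expect_lt(abs(est$peak_bpm - bpm), bin_bpm + 1e-9)
  }
  ## band edge: 0.7 Hz reads out as 42 BPM
  est <- estimate_rr(sin(2 * pi * 0.7 * t), fs = fs)
  expect_lt(abs(est$peak_bpm - 42), bin_bpm + 1e-9)
  expect_equal(est$peak_bpm, est$peak_freq * 60)

  ## clip-scale signal (50 samples): the 10 s window's spectral leakage
  ## dominates the padded bin width, but stays well under 0.5 BPM
  est50 <- estimate_rr(sin(2 * pi * 0.25 * (0:49) / fs), fs = fs)
  expect_lt(abs(est50$peak_bpm - 15), 0.5)
})

test_that("the dominant component wins and weak in-band energy errors out", {
  fs <- 5; t <- (0:299) / fs
  two <- sin(2 * pi * 0.2 * t) + 2 * sin(2 * pi * 0.3 * t)
  expect_lt(abs(estimate_rr(two, fs = fs)$peak_bpm - 18), 0.1)
  expect_error(estimate_rr(rep(0, 50), fs = fs), "in-band")
  expect_error(estimate_rr(sin(2 * pi * 2 * t), fs = fs), "in-band")
})

test_that("bandpass + readout shrug off 10x out-of-band interference", {
  fs <- 5; t <- (0:249) / fs
  x <- sin(2 * pi * 0.25 * t) + 10 * sin(2 * pi * 2.0 * t + 0.3)
  y <- bandpass(x, fs = fs)
  expect_lt(abs(estimate_rr(y, fs = fs)$peak_bpm - 15), 0.25)
})

test_that("an oracle predictor yields a degenerate-perfect report", {
  clips <- tiny_clips()
  oracle <- function(cl) cl$target$samples
  rep <- evaluate(oracle, clips)
  expect_equal(rep$aggregates$n_evaluated, length(clips))
  expect_equal(rep$aggregates$pct_under_2bpm, 100)
  expect_equal(rep$aggregates$mean_max_xcorr, 1)
  ## the target is the belt itself: its peak matches the true RR closely
  expect_lt(rep$aggregates$mean_abs_error_bpm, 0.5)
})

test_that("degenerate predictions are recorded as missing, not fatal", {
  clips <- tiny_clips()
  flat <- function(cl) rep(0, 50)
  rep <- evaluate(flat, clips)
  expect_equal(rep$aggregates$n_missing, length(clips))
  expect_true(all(nzchar(rep$per_clip$note)))
})

test_that("pct_under_2bpm follows its definition", {
  clips <- tiny_clips()[1:2]
  clips[[1]]$truth_rr_bpm <- 16   # |15 - 16| = 1 BPM  -> under
  clips[[2]]$truth_rr_bpm <- 18   # |15 - 18| = 3 BPM  -> over
  predictor <- function(cl) sin(2 * pi * 0.25 * (0:49) / 5)  # 15 BPM
  rep <- evaluate(predictor, clips)
  expect_equal(rep$aggregates$pct_under_2bpm, 50)
  expect_equal(rep$aggregates$n_evaluated, 2)
})

test_that("eval reports serialize to CSV + JSON", {
  rep <- evaluate(function(cl) cl$target$samples, tiny_clips())
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, csv, js)
  expect_equal(nrow(utils::read.csv(csv)), length(tiny_clips()))
  agg <- jsonlite::read_json(js)
  expect_equal(agg$pct_under_2bpm, 100)
})

test_that("grad_cam returns a normalized heatmap and zero maps stay zero", {
  m <- tiny_model()
  cl <- tiny_clips16()[[1]]
  heat <- grad_cam(m, cl)
  expect_equal(dim(heat), c(16, 16))
  expect_gte(min(heat), 0)
  expect_lte(max(heat), 1)

  m0 <- m
  m0$params$fc_w[] <- 0; m0$params$fc_b <- 0
  ## a zeroed head gives zero output, hence zero gradients everywhere
  expect_true(all(grad_cam(m0, cl) == 0))
})
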