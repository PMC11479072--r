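test_that("identical configs (including seed) reproduce bit-identical recordings", {
  cfg <- sim_config(duration_s = 4, frame_size = c(40, 48), rng_seed = 7)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$frames, r2$frames)
  expect_identical(r1$belt$samples, r2$belt$samples)
  expect_identical(r1$truth_boxes, r2$truth_boxes)

  r3 <- simulate_recording(sim_config(duration_s = 4, frame_size = c(40, 48),
                                      rng_seed = 8))
  expect_false(identical(r1$frames, r3$frames))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(rr_bpm = 50), "\\[3, 42\\]")
  expect_error(sim_config(rr_bpm = 2), "\\[3, 42\\]")
  expect_error(sim_config(duration_s = -1), "positive")
  expect_error(sim_config(duration_s = 1.03, video_fps = 30), "integer frame count")
  expect_error(sim_config(noise_sd = -1), "non-negative")
})

test_that("frames are bounded and truth boxes stay within the frame", {
  rec <- tiny_recording()
  expect_true(all(rec$frames >= 0))
  expect_true(all(rec$frames <= rec$intensity_max))
  d <- dim(rec$frames)
  expect_equal(nrow(rec$truth_boxes), d[3])
  expect_true(all(rec$truth_boxes$x0 >= 0 & rec$truth_boxes$x1 <= d[2]))
  expect_true(all(rec$truth_boxes$y0 >= 0 & rec$truth_boxes$y1 <= d[1]))
  expect_true(all(rec$truth_boxes$x0 < rec$truth_boxes$x1))
  ## belt duration equals video duration within one belt sample
  expect_lt(abs(length(rec$belt$samples) / rec$belt$fs - d[3] / rec$fps),
            1 / rec$belt$fs + 1e-9)
})

test_that("the breathing patch oscillates at the configured frequency", {
  rec <- simulate_recording(sim_config(duration_s = 20, frame_size = c(60, 80),
                                       rr_bpm = 15, noise_sd = 0,
                                       sway_amp_px = 0, rng_seed = 2))
  ## with zero sway the patch is static; take its spatial mean over time
  pb <- rec$truth_patch[1, ]
  patch <- rec$frames[(pb$y0 + 1):pb$y1, (pb$x0 + 1):pb$x1, ]
  s <- apply(patch, 3, mean)
  ## independent periodogram peak must fall in the bin containing 0.25 Hz
  f_hat <- oracle_peak_freq(s, fs = rec$fps, band = c(0.05, 0.7), pad = 8192)
  expect_lt(abs(f_hat - 0.25), rec$fps / 8192 + 1e-9)
})

test_that("the belt lag is recoverable by a brute-force lag scan", {
  rec <- simulate_recording(sim_config(duration_s = 30, frame_size = c(60, 80),
                                       rr_bpm = 12, noise_sd = 0,
                                       sway_amp_px = 0, belt_lag_s = 1.0,
                                       rng_seed = 4))
  pb <- rec$truth_patch[1, ]
  s30 <- apply(rec$frames[(pb$y0 + 1):pb$y1, (pb$x0 + 1):pb$x1, ], 3, mean)
  face5 <- colMeans(matrix(s30, nrow = 6))              # 5 Hz face signal
  t5 <- (seq_along(face5) - 1) / 5
  tb <- (seq_along(rec$belt$samples) - 1) / rec$belt$fs
  belt5 <- approx(tb, rec$belt$samples, xout = t5)$y    # belt resampled to 5 Hz
  lags <- -10:10                                        # +/- 2 s at 5 Hz
  cc <- vapply(lags, function(k) {
    n <- length(belt5); idx <- (max(1, 1 + k)):(min(n, n + k))
    cor(belt5[idx], face5[idx - k])                     # advance belt by k
  }, numeric(1))
  ## belt(t) = face(t - lag): advancing the belt by +lag aligns the two
  expect_lt(abs(lags[which.max(cc)] / 5 - 1.0), 0.2 + 1e-9)
})

test_that("cohorts share RR within subject and are seed-reproducible", {
  co <- simulate_cohort(2, c("sit_nomask", "stand_mask"), base_seed = 3,
                        duration_s = 2, frame_size = c(24, 32))
  expect_length(co, 4)
  expect_equal(co[[1]]$truth_rr_bpm, co[[2]]$truth_rr_bpm)  # same subject
  expect_false(co[[1]]$truth_rr_bpm == co[[3]]$truth_rr_bpm)
  expect_false(identical(co[[1]]$frames, co[[2]]$frames))   # distinct seeds
  expect_identical(co[[1]]$condition, "sit_nomask")
  expect_identical(co[[2]]$condition, "stand_mask")

  co2 <- simulate_cohort(2, c("sit_nomask", "stand_mask"), base_seed = 3,
                         duration_s = 2, frame_size = c(24, 32))
  expect_identical(co[[4]]$frames, co2[[4]]$frames)

  expect_length(simulate_cohort(1, "sit_mask", base_seed = 1, duration_s = 2,
                                frame_size = c(24, 32)), 1)
})

test_that("standing conditions sway more than sitting", {
  sway <- function(cond) {
    rec <- simulate_recording(sim_config(condition = cond, duration_s = 20,
                                         frame_size = c(60, 80), noise_sd = 0,
                                         rng_seed = 5))
    cx <- (rec$truth_boxes$x0 + rec$truth_boxes$x1) / 2
    cy <- (rec$truth_boxes$y0 + rec$truth_boxes$y1) / 2
    sd(cx) + sd(cy)
  }
  expect_gt(sway("stand_nomask"), sway("sit_nomask"))
})

test_that("recordings round-trip through the PNG/CSV/JSON format", {
  skip_if_not_installed("png")
  rec <- simulate_recording(sim_config(duration_s = 1, video_fps = 10,
                                       frame_size = c(24, 32), rng_seed = 9))
  d <- withr::local_tempdir()
  write_recording(rec, d)
  back <- read_recording(d)
  expect_equal(back$frames, rec$frames, tolerance = 2 / 65535 * 255)
  expect_equal(back$belt$samples, rec$belt$samples)
  expect_identical(back$condition, rec$condition)
  expect_equal(back$truth_boxes, rec$truth_boxes)
})
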