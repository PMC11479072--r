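test_that("the intensity detector boxes a bright ellipse", {
  fr <- matrix(10, 100, 120)
  yy <- outer(((1:100 - 40) / 18)^2, rep(1, 120))
  xx <- outer(rep(1, 100), ((1:120 - 60) / 25)^2)
  fr[yy + xx <= 1] <- 200
  b <- intensity_detector(fr)
  ## box must contain the ellipse center (0-based coords: 59.5, 39.5)
  expect_true(b$x0 <= 59 && b$x1 >= 60)
  expect_true(b$y0 <= 39 && b$y1 >= 40)
  expect_gt(b$confidence, 0)
  expect_lte(b$confidence, 1)
})

test_that("uniform frames yield no detection and all-zero recordings fail", {
  expect_null(intensity_detector(matrix(5, 30, 30)))
  frames <- array(0, dim = c(20, 20, 3))
  expect_error(detect_faces(frames), "every frame")
})

test_that("with several components the larger one wins", {
  fr <- matrix(0, 60, 60)
  fr[5:10, 5:10] <- 100       # 36 px
  fr[30:50, 30:50] <- 100     # 441 px
  b <- intensity_detector(fr)
  expect_true(b$x0 >= 25 && b$y0 >= 25)
})

test_that("candidate tie-breaking prefers confidence, then area, then top-left", {
  multi <- rbind(bounding_box(0, 0, 10, 10, confidence = 0.4),
                 bounding_box(20, 20, 40, 40, confidence = 0.9),
                 bounding_box(5, 5, 15, 15, confidence = 0.9))
  detector <- function(frame) multi
  out <- detect_faces(array(1, dim = c(50, 50, 1)), detector)
  expect_equal(out$x0, 20)  # higher confidence + larger area
  expect_equal(nrow(out), 1)
})

test_that("detected boxes overlap simulator truth with IoU > 0.5 on every frame", {
  rec <- simulate_recording(sim_config(duration_s = 2, frame_size = c(60, 80),
                                       noise_sd = 0, rng_seed = 11))
  boxes <- detect_faces(rec)
  expect_equal(nrow(boxes), dim(rec$frames)[3])
  ious <- vapply(seq_len(nrow(boxes)), function(i)
    box_iou(boxes[i, ], rec$truth_boxes[i, ]), numeric(1))
  expect_true(all(ious > 0.5))
})

test_that("failed frames inherit the nearest previous valid box", {
  rec <- simulate_recording(sim_config(duration_s = 1, video_fps = 5,
                                       frame_size = c(40, 48), noise_sd = 0,
                                       rng_seed = 1))
  rec$frames[, , 3] <- 0          # kill detection on frame 3
  boxes <- detect_faces(rec)
  expect_equal(nrow(boxes), 5)
  expect_equal(boxes$x0[3], boxes$x0[2])
  expect_equal(boxes$y1[3], boxes$y1[2])
  expect_equal(boxes$confidence[3], 0)

  rec$frames[, , 1] <- 0          # leading failure inherits first valid box
  boxes2 <- detect_faces(rec)
  expect_equal(boxes2$x0[1], boxes2$x0[2])
})

test_that("box smoothing is a centered moving median with identity at window 1", {
  const <- do.call(rbind, lapply(0:9, function(i) bounding_box(10, 10, 30, 30, i)))
  expect_equal(smooth_boxes(const, 5)[, c("x0", "y0", "x1", "y1")],
               const[, c("x0", "y0", "x1", "y1")])

  withOutlier <- const
  withOutlier$x0[5] <- 25
  sm <- smooth_boxes(withOutlier, 5)
  expect_equal(sm$x0[5], 10)                     # outlier replaced by median
  expect_identical(smooth_boxes(withOutlier, 1), withOutlier)
  expect_error(smooth_boxes(const, 4), "odd")

  ## smoothing never leaves the frame
  sm2 <- smooth_boxes(withOutlier, 5, frame_size = c(32, 32))
  expect_true(all(sm2$x1 <= 32 & sm2$y1 <= 32 & sm2$x0 >= 0 & sm2$y0 >= 0))
})

test_that("crop_and_resize is exact for identity and constant inputs", {
  rec <- tiny_recording()
  d <- dim(rec$frames)
  full <- do.call(rbind, lapply(seq_len(d[3]) - 1L, function(i)
    bounding_box(0, 0, d[2], d[1], i)))
  out <- crop_and_resize(rec, full, out_size = d[1:2])
  expect_equal(out, rec$frames)                  # exact identity

  const <- array(3.7, dim = c(20, 24, 2))
  cb <- rbind(bounding_box(2, 3, 18, 15, 0L), bounding_box(2, 3, 18, 15, 1L))
  oc <- crop_and_resize(const, cb, out_size = c(8, 8))
  expect_true(all(oc == 3.7))                    # interpolation of a constant
  expect_equal(dim(oc), c(8, 8, 2))

  ## count preservation
  expect_equal(dim(crop_and_resize(rec, detect_faces(rec), c(16, 16)))[3], d[3])

  degenerate <- rbind(bounding_box(0, 0, 10, 10, 0L), bounding_box(5, 5, 6, 15, 1L))
  expect_error(crop_and_resize(const, degenerate, c(8, 8)), "degenerate")
})

test_that("box tracks round-trip through CSV", {
  boxes <- detect_faces(tiny_recording())[1:10, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_boxes_csv(boxes, path)
  back <- read_boxes_csv(path)
  expect_equal(back$x0, boxes$x0)
  expect_equal(back$confidence, boxes$confidence)
})
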