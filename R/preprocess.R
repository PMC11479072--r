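## Clip extraction and alignment ------------------------------------------
##
## Recordings are cut into 10 s training clips with 5 s overlap, the video
## is temporally downsampled from 30 Hz to the 5 Hz analysis rate by block
## averaging (respiration is < 0.7 Hz, far below the 2.5 Hz Nyquist of the
## analysis rate), the belt reference is anti-alias filtered and resampled
## onto the 50-sample clip grid, and both are z-score normalized per clip.

#' Sliding-window clip boundaries
#'
#' Windows `[k*step, k*step + win]` for `k = 0, 1, ...` while the window
#' end does not exceed the recording duration, i.e.
#' `floor((duration - win)/step) + 1` windows. A 90 s recording with the
#' default 10 s window and 5 s step yields 17 windows.
#'
#' @param duration_s Recording duration in seconds.
#' @param win_s Window length in seconds (default 10).
#' @param step_s Step between window starts in seconds (default 5, i.e.
#'   5 s overlap between consecutive 10 s windows).
#' @return A data frame with columns `start_s`, `end_s` (possibly 0 rows
#'   when `win_s > duration_s`).
#' @export
slide_windows <- function(duration_s, win_s = 10, step_s = 5) {
  if (step_s <= 0) stopf("step_s must be positive")
  if (win_s <= 0) stopf("win_s must be positive")
  if (win_s > duration_s)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  k <- 0:floor((duration_s - win_s) / step_s + 1e-9)
  data.frame(start_s = k * step_s, end_s = k * step_s + win_s)
}

#' Temporally downsample a video by block averaging
#'
#' Each output frame is the mean of `factor` consecutive source frames
#' (non-overlapping blocks), which both decimates and anti-aliases. The
#' default pipeline takes 30 fps video to the 5 Hz analysis rate
#' (factor 6), so a 10 s clip becomes exactly 50 frames.
#'
#' @param frames H x W x T array.
#' @param src_fps Source frame rate (Hz).
#' @param target_fps Target frame rate (Hz, default 5). `src_fps /
#'   target_fps` must be an integer.
#' @return H x W x floor(T / factor) array.
#' @export
downsample_video <- function(frames, src_fps, target_fps = 5) {
  stopifnot(length(dim(frames)) == 3)
  factor <- src_fps / target_fps
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stopf("src_fps (%g) must be an integer multiple of target_fps (%g)",
          src_fps, target_fps)
  factor <- as.integer(round(factor))
  d <- dim(frames)
  To <- d[3] %/% factor
  if (To < 1) stopf("fewer than %d frames; cannot downsample", factor)
  x <- array(frames[, , seq_len(To * factor)], dim = c(d[1] * d[2], factor, To))
  out <- array(0, dim = c(d[1], d[2], To))
  for (t in seq_len(To)) out[, , t] <- rowMeans(x[, , t])
  out
}

#' Resample the belt reference onto the clip grid
#'
#' Extracts the belt segment for one clip window, low-pass filters it below
#' the analysis-rate Nyquist and samples it at the clip timestamps, then
#' z-score normalizes. Anti-aliasing is two-stage: block-average decimation
#' of the high-rate belt (2048 Hz) to an intermediate rate, then a 4th-order
#' Butterworth low-pass at 2 Hz applied forward-backward (a direct IIR
#' design at 2048 Hz would put the cutoff at a numerically fragile 0.002 of
#' Nyquist).
#'
#' @param belt A [resp_signal()] (e.g. `recording$belt`).
#' @param window `c(start_s, end_s)` within the belt duration.
#' @param target_fs Clip rate in Hz (default 5).
#' @return A normalized [resp_signal()] with
#'   `round((end_s - start_s) * target_fs)` samples (50 for a 10 s window).
#' @export
resample_belt <- function(belt, window, target_fs = 5) {
  stopifnot(inherits(belt, "resp_signal"))
  dur <- length(belt$samples) / belt$fs
  if (window[1] < 0 || window[2] > dur + 1e-9 || window[2] <= window[1])
    stopf("window [%g, %g] s outside belt duration %g s", window[1], window[2], dur)
  n_out <- as.integer(round((window[2] - window[1]) * target_fs))
  if (n_out < 2) stopf("window too short")

  x <- belt$samples
  fs <- belt$fs
  ## degenerate input: a constant segment cannot be normalized (and would
  ## otherwise only produce filter edge transients)
  seg <- x[max(1, floor(window[1] * fs)):min(length(x), ceiling(window[2] * fs))]
  if (stats::sd(seg) <= 1e-10 * max(abs(seg), 1))
    stopf("belt segment is constant in [%g, %g] s; cannot normalize",
          window[1], window[2])
  ## stage 1: block-average to an intermediate rate <= ~32 Hz
  dec <- max(1L, floor(fs / 32))
  if (dec > 1) {
    nb <- length(x) %/% dec
    x <- colMeans(matrix(x[seq_len(nb * dec)], nrow = dec))
    fs <- fs / dec
  }
  ## stage 2: zero-phase Butterworth low-pass at 2 Hz (below 2.5 Hz Nyquist
  ## of the 5 Hz clip grid)
  if (fs > 4.5) {
    bf <- signal::butter(4, 2 / (fs / 2), type = "low")
    x <- filtfilt_padded(bf, x)
  }
  t_src <- (seq_along(x) - 1) / fs
  t_out <- window[1] + (seq_len(n_out) - 1) / target_fs
  y <- stats::approx(t_src, x, xout = pmin(t_out, max(t_src)), rule = 2)$y
  if (stats::sd(y) <= 1e-10 * max(abs(y), 1))
    stopf("belt segment is constant in [%g, %g] s; cannot normalize", window[1], window[2])
  normalize_signal(resp_signal(y, target_fs))
}

#' Z-score normalize a video clip
#'
#' Per-clip normalization over all voxels (subtract the clip mean, divide
#' by the clip standard deviation). Affine transforms of the input yield
#' identical output, so the arbitrary linear intensity scale of the camera
#' drops out.
#'
#' @param frames Numeric array (any shape).
#' @return Array of the same shape with mean 0, sd 1.
#' @export
normalize_clip <- function(frames) {
  sdv <- stats::sd(frames)
  if (!is.finite(sdv) || sdv == 0) stopf("constant clip: zero variance, cannot normalize")
  (frames - mean(frames)) / sdv
}

#' Extract aligned training clips from a recording
#'
#' Runs the full preprocessing chain: per-frame face detection
#' (track-by-detection), temporal box smoothing, dynamic cropping and
#' bilinear resizing, block-average temporal downsampling to the analysis
#' rate, sliding-window clip extraction, belt resampling onto the clip
#' grid, and per-clip z-normalization of both video and target.
#'
#' @param recording A `thermal_recording`.
#' @param out_size Spatial clip size `c(height, width)` (default
#'   `c(128, 128)`).
#' @param analysis_fps Analysis rate in Hz (default 5).
#' @param win_s,step_s Sliding-window parameters (defaults 10 s / 5 s).
#' @param smooth_window Box-smoothing window in frames (odd; default 5;
#'   1 disables smoothing).
#' @param detector Face detector function (default [intensity_detector()]).
#' @param boxes Optional precomputed per-frame boxes (skips detection).
#' @return A list of `clip_sample` objects. Each holds `frames`
#'   (normalized `out_h x out_w x n` array, `n = win_s * analysis_fps`),
#'   `target` (normalized [resp_signal()] on the same grid),
#'   `truth_rr_bpm`, `subject_id`, `condition`, `window_start_s`,
#'   `clip_id`, and `patch_box` (the true breathing-patch box mapped into
#'   clip pixel coordinates, for localization checks).
#' @export
make_clips <- function(recording, out_size = c(128, 128), analysis_fps = 5,
                       win_s = 10, step_s = 5, smooth_window = 5,
                       detector = intensity_detector, boxes = NULL) {
  stopifnot(inherits(recording, "thermal_recording"))
  d <- dim(recording$frames)
  if (is.null(boxes)) boxes <- detect_faces(recording, detector)
  boxes <- smooth_boxes(boxes, smooth_window, frame_size = d[1:2])
  face <- crop_and_resize(recording, boxes, out_size)
  face <- downsample_video(face, recording$fps, analysis_fps)
  duration <- d[3] / recording$fps
  wins <- slide_windows(duration, win_s, step_s)
  n_per <- as.integer(round(win_s * analysis_fps))

  ## true breathing patch mapped into clip coordinates (mean over frames)
  pb <- NULL
  if (!is.null(recording$truth_patch)) {
    sx <- out_size[2] / (boxes$x1 - boxes$x0)
    sy <- out_size[1] / (boxes$y1 - boxes$y0)
    pb <- c(mean((recording$truth_patch$x0 - boxes$x0) * sx),
            mean((recording$truth_patch$y0 - boxes$y0) * sy),
            mean((recording$truth_patch$x1 - boxes$x0) * sx),
            mean((recording$truth_patch$y1 - boxes$y0) * sy))
    pb <- pmin(pmax(pb, 0), c(out_size[2], out_size[1], out_size[2], out_size[1]))
  }

  clips <- vector("list", nrow(wins))
  for (k in seq_len(nrow(wins))) {
    i0 <- as.integer(round(wins$start_s[k] * analysis_fps)) + 1L
    fr <- face[, , i0:(i0 + n_per - 1L), drop = FALSE]
    ## remove each pixel's temporal mean within the clip: the static
    ## thermal structure of the face carries no respiratory information,
    ## and with it removed the breathing modulation (not the face
    ## geometry) dominates the normalized clip
    fr <- fr - as.vector(rowMeans(matrix(fr, ncol = dim(fr)[3])))
    target <- resample_belt(recording$belt, c(wins$start_s[k], wins$end_s[k]),
                            analysis_fps)
    clips[[k]] <- structure(list(
      frames = normalize_clip(fr),
      target = target,
      truth_rr_bpm = recording$truth_rr_bpm,
      subject_id = recording$subject_id,
      condition = recording$condition,
      window_start_s = wins$start_s[k],
      clip_id = sprintf("%s_%s_%03d", recording$subject_id,
                        recording$condition, as.integer(wins$start_s[k])),
      patch_box = pb
    ), class = "clip_sample")
  }
  clips
}

#' @export
print.clip_sample <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<clip_sample> %s: %dx%dx%d, target %d samples @ %g Hz, true RR %.1f BPM\n",
              x$clip_id, d[1], d[2], d[3], length(x$target$samples),
              x$target$fs, x$truth_rr_bpm))
  invisible(x)
}
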