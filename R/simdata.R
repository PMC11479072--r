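## Synthetic thermal recordings -------------------------------------------
##
## The real dataset behind this method (facial thermal video + respiratory
## effort belt) is ethics-restricted, so the package ships a generator that
## reproduces the statistical structure the pipeline relies on: a warm
## face-shaped region whose nostril (or mask) patch oscillates at the
## breathing frequency, a belt waveform that is the same respiratory process
## with a phase lag, slow body sway, and additive sensor noise.

SIM_CONDITIONS <- c("sit_mask", "sit_nomask", "stand_mask", "stand_nomask")

#' Configuration for one synthetic thermal recording
#'
#' Defines the acquisition protocol emulated by [simulate_recording()]:
#' 90 s of grayscale thermal-like video at 30 fps and 640x480 resolution,
#' with a respiratory effort belt sampled at 2048 Hz. The facial heat signal
#' leads or lags the belt by `belt_lag_s` seconds (chest circumference and
#' nostril temperature are not phase aligned); body sway is stronger for
#' standing conditions; breathing is non-sinusoidal (decaying harmonics).
#'
#' @param subject_id Subject identifier (character).
#' @param condition One of `"sit_mask"`, `"sit_nomask"`, `"stand_mask"`,
#'   `"stand_nomask"`.
#' @param duration_s Recording length in seconds (default 90).
#' @param video_fps Video frame rate in Hz (default 30). `duration_s *
#'   video_fps` must be an integer.
#' @param frame_size Frame dimensions `c(height, width)` in pixels
#'   (default `c(480, 640)`).
#' @param rr_bpm True respiration rate in breaths/min; must lie in the
#'   physiological band \[3, 42\].
#' @param belt_fs Belt sampling rate in Hz (default 2048).
#' @param belt_lag_s Phase lag (s) of the facial heat signal relative to the
#'   belt. `NULL` (default) draws once from U(0.2, 1.5).
#' @param sway_amp_px Standard deviation of the body-sway displacement in
#'   pixels. `NULL` (default) uses 3 px sitting, 6 px standing, scaled by
#'   frame height relative to the nominal 480 px.
#' @param noise_sd Per-pixel Gaussian sensor noise standard deviation, in
#'   intensity units (default 1).
#' @param waveform_harmonics Number of harmonics in the respiratory
#'   waveform (default 2; amplitudes decay as 1/k so the waveform is
#'   non-sinusoidal, as real effort-belt traces are).
#' @param intensity_max Upper intensity bound (arbitrary linear scale,
#'   default 255); frames are clipped to \[0, intensity_max\].
#' @param rng_seed Integer seed; identical configurations (including the
#'   seed) reproduce bit-identical recordings.
#' @return An object of class `sim_config`.
#' @seealso [simulate_recording()], [simulate_cohort()]
#' @export
sim_config <- function(subject_id = "S01",
                       condition = "sit_nomask",
                       duration_s = 90,
                       video_fps = 30,
                       frame_size = c(480, 640),
                       rr_bpm = 15,
                       belt_fs = 2048,
                       belt_lag_s = NULL,
                       sway_amp_px = NULL,
                       noise_sd = 1,
                       waveform_harmonics = 2,
                       intensity_max = 255,
                       rng_seed = 1) {
  condition <- match.arg(condition, SIM_CONDITIONS)
  if (!is.numeric(rr_bpm) || rr_bpm < 3 || rr_bpm > 42)
    stopf("rr_bpm must lie in [3, 42] BPM; got %g", rr_bpm)
  if (!is.numeric(duration_s) || duration_s <= 0) stopf("duration_s must be positive")
  if (!is.numeric(video_fps) || video_fps <= 0) stopf("video_fps must be positive")
  n_frames <- duration_s * video_fps
  if (abs(n_frames - round(n_frames)) > 1e-9)
    stopf("duration_s * video_fps must be an integer frame count (got %g)", n_frames)
  if (length(frame_size) != 2 || any(frame_size < 16))
    stopf("frame_size must be c(height, width), each >= 16 px")
  if (!is.null(belt_lag_s) && (belt_lag_s < 0 || belt_lag_s >= duration_s))
    stopf("belt_lag_s must lie in [0, duration_s)")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (!is_count(waveform_harmonics)) stopf("waveform_harmonics must be a positive count")
  structure(list(
    subject_id = as.character(subject_id), condition = condition,
    duration_s = duration_s, video_fps = video_fps,
    frame_size = as.integer(frame_size), rr_bpm = rr_bpm,
    belt_fs = belt_fs, belt_lag_s = belt_lag_s,
    sway_amp_px = sway_amp_px, noise_sd = noise_sd,
    waveform_harmonics = as.integer(waveform_harmonics),
    intensity_max = intensity_max, rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

standing <- function(condition) condition %in% c("stand_mask", "stand_nomask")
masked <- function(condition) condition %in% c("sit_mask", "stand_mask")

## Respiratory waveform: fundamental plus decaying harmonics (a_k = 1/k),
## with a random global phase. Unit peak-normalized.
resp_waveform <- function(t, rr_bpm, harmonics, phase) {
  f <- bpm_to_hz(rr_bpm)
  w <- 0
  for (k in seq_len(harmonics)) {
    w <- w + (1 / k) * sin(2 * pi * k * f * t + k * phase)
  }
  w / sum(1 / seq_len(harmonics))
}

## Ornstein-Uhlenbeck displacement path with stationary sd `amp` (pixels)
## and relaxation time tau (s); smooth low-frequency sway.
ou_path <- function(n, dt, amp, tau = 2) {
  x <- numeric(n)
  if (amp <= 0 || n == 1) return(x)
  rho <- exp(-dt / tau)
  innov_sd <- amp * sqrt(1 - rho^2)
  x[1] <- stats::rnorm(1, 0, amp)
  eps <- stats::rnorm(n - 1, 0, innov_sd)
  for (i in 2:n) x[i] <- rho * x[i - 1] + eps[i - 1]
  x
}

## filled-ellipse mask and its tight bounding window (1-based, inclusive)
ellipse_patch <- function(cy, cx, ry, rx, H, W) {
  y0 <- max(1L, floor(cy - ry)); y1 <- min(H, ceiling(cy + ry))
  x0 <- max(1L, floor(cx - rx)); x1 <- min(W, ceiling(cx + rx))
  if (y0 > y1 || x0 > x1) return(NULL)
  yy <- y0:y1; xx <- x0:x1
  m <- outer(((yy - cy) / ry)^2, ((xx - cx) / rx)^2, "+") <= 1
  list(y0 = y0, y1 = y1, x0 = x0, x1 = x1, mask = m * 1)
}

#' Simulate one synthetic thermal recording
#'
#' Generates a `thermal_recording`: a face-shaped warm ellipse whose
#' nostril sub-region (or, in mask conditions, a larger lower-contrast mask
#' region) oscillates in intensity at the respiration frequency (exhalation
#' warms, inhalation cools), superimposed on a smooth Ornstein-Uhlenbeck
#' body-sway translation and i.i.d. Gaussian sensor noise. The belt
#' reference is the same respiratory waveform delayed by `belt_lag_s` and
#' sampled at `belt_fs`. Ground-truth per-frame face and breathing-patch
#' bounding boxes are recorded for downstream validation.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `thermal_recording` with elements `frames`
#'   (H x W x T array, intensities in \[0, intensity_max\]), `fps`, `belt`
#'   (a [resp_signal()]), `truth_rr_bpm`, `truth_boxes` and `truth_patch`
#'   (per-frame boxes, columns `frame,x0,y0,x1,y1`; 0-based half-open pixel
#'   coordinates), `belt_lag_s`, `condition` and `subject_id`.
#' @examples
#' rec <- simulate_recording(sim_config(duration_s = 12, frame_size = c(60, 80),
#'                                      rng_seed = 7))
#' dim(rec$frames)
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  H <- cfg$frame_size[1]; W <- cfg$frame_size[2]
  T_ <- as.integer(round(cfg$duration_s * cfg$video_fps))
  with_seed(cfg$rng_seed, {
    lag <- if (is.null(cfg$belt_lag_s)) stats::runif(1, 0.2, 1.5) else cfg$belt_lag_s
    sway_amp <- cfg$sway_amp_px
    if (is.null(sway_amp))
      sway_amp <- (if (standing(cfg$condition)) 6 else 3) * H / 480
    phase <- stats::runif(1, 0, 2 * pi)

    t_frame <- (seq_len(T_) - 1) / cfg$video_fps
    w_face <- resp_waveform(t_frame, cfg$rr_bpm, cfg$waveform_harmonics, phase)

    dy <- ou_path(T_, 1 / cfg$video_fps, sway_amp)
    dx <- ou_path(T_, 1 / cfg$video_fps, sway_amp)

    ## face geometry (fractions of frame size; face roughly centered)
    cy0 <- 0.45 * H; cx0 <- 0.5 * W
    ry <- 0.28 * H; rx <- 0.20 * W
    bg_level <- 0.15 * cfg$intensity_max      # cool background
    face_level <- 0.35 * cfg$intensity_max    # warm face elevation
    breath_amp <- 5 * cfg$intensity_max / 255 # nostril modulation depth

    ## breathing patch, relative to face center: nostril (small, crisp) or
    ## mask (larger area, lower contrast -- heat spread over mask surface)
    if (masked(cfg$condition)) {
      p_dy <- 0.45 * ry; p_ry <- 0.45 * ry; p_rx <- 0.60 * rx
      p_amp <- breath_amp * 0.6
    } else {
      p_dy <- 0.35 * ry; p_ry <- 0.18 * ry; p_rx <- 0.30 * rx
      p_amp <- breath_amp
    }

    frames <- array(0, dim = c(H, W, T_))
    tb <- matrix(0L, nrow = T_, ncol = 4)
    tp <- matrix(0L, nrow = T_, ncol = 4)
    for (i in seq_len(T_)) {
      cy <- cy0 + dy[i]; cx <- cx0 + dx[i]
      fr <- matrix(bg_level, H, W)
      fe <- ellipse_patch(cy, cx, ry, rx, H, W)
      if (!is.null(fe))
        fr[fe$y0:fe$y1, fe$x0:fe$x1] <-
          fr[fe$y0:fe$y1, fe$x0:fe$x1] + face_level * fe$mask
      pe <- ellipse_patch(cy + p_dy, cx, p_ry, p_rx, H, W)
      if (!is.null(pe))
        fr[pe$y0:pe$y1, pe$x0:pe$x1] <-
          fr[pe$y0:pe$y1, pe$x0:pe$x1] + p_amp * w_face[i] * pe$mask
      if (cfg$noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(H * W, 0, cfg$noise_sd), H, W)
      frames[, , i] <- fr
      ## 0-based half-open truth boxes, clipped to frame
      tb[i, ] <- c(max(0, floor(cx - rx)), max(0, floor(cy - ry)),
                   min(W, ceiling(cx + rx)), min(H, ceiling(cy + ry)))
      tp[i, ] <- c(max(0, floor(cx - p_rx)), max(0, floor(cy + p_dy - p_ry)),
                   min(W, ceiling(cx + p_rx)), min(H, ceiling(cy + p_dy + p_ry)))
    }
    frames[frames < 0] <- 0
    frames[frames > cfg$intensity_max] <- cfg$intensity_max

    nb <- as.integer(round(cfg$duration_s * cfg$belt_fs))
    t_belt <- (seq_len(nb) - 1) / cfg$belt_fs
    ## facial heat leads the belt by `lag`: belt(t) = w_face(t - lag)
    belt <- resp_waveform(t_belt - lag, cfg$rr_bpm, cfg$waveform_harmonics, phase)

    structure(list(
      frames = frames, fps = cfg$video_fps,
      belt = resp_signal(belt, cfg$belt_fs),
      truth_rr_bpm = cfg$rr_bpm,
      truth_boxes = data.frame(frame = seq_len(T_) - 1L, x0 = tb[, 1],
                               y0 = tb[, 2], x1 = tb[, 3], y1 = tb[, 4]),
      truth_patch = data.frame(frame = seq_len(T_) - 1L, x0 = tp[, 1],
                               y0 = tp[, 2], x1 = tp[, 3], y1 = tp[, 4]),
      belt_lag_s = lag, condition = cfg$condition,
      subject_id = cfg$subject_id, intensity_max = cfg$intensity_max,
      config = cfg
    ), class = "thermal_recording")
  })
}

#' @export
print.thermal_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<thermal_recording> subject %s, %s: %d frames of %dx%d @ %g fps (%.1f s)\n",
    x$subject_id, x$condition, d[3], d[1], d[2], x$fps, d[3] / x$fps))
  cat(sprintf("  true RR %.1f BPM; belt %d samples @ %g Hz, lag %.2f s\n",
              x$truth_rr_bpm, length(x$belt$samples), x$belt$fs, x$belt_lag_s))
  invisible(x)
}

#' Simulate a cohort of recordings
#'
#' One recording per subject x condition. Each subject's respiration rate is
#' drawn once (U(8, 22) BPM, a typical resting adult range) and shared
#' across that subject's conditions, so that subject identity is a genuine
#' nuisance factor for subject-wise train/test splits. Every recording gets
#' its own derived seed and its own belt lag.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param conditions Character vector of conditions (default all four).
#' @param base_seed Integer seed; the same seed reproduces the same cohort.
#' @param ... Further arguments passed to [sim_config()] (e.g. `duration_s`,
#'   `frame_size`, `noise_sd`) to size recordings.
#' @return A list of `thermal_recording` objects, length
#'   `n_subjects * length(conditions)`.
#' @examples
#' cohort <- simulate_cohort(2, conditions = "sit_nomask", base_seed = 1,
#'                           duration_s = 12, frame_size = c(60, 80))
#' length(cohort)
#' @export
simulate_cohort <- function(n_subjects, conditions = SIM_CONDITIONS,
                            base_seed = 1, ...) {
  lapply(cohort_configs(n_subjects, conditions, base_seed, ...),
         simulate_recording)
}

#' Per-recording configurations of a cohort
#'
#' The deterministic expansion used by [simulate_cohort()]: subject RRs
#' are drawn once from the base seed, every subject x condition cell gets
#' its own derived recording seed. Useful to (re)generate single
#' recordings of a cohort without materializing all of it.
#'
#' @inheritParams simulate_cohort
#' @return A list of [sim_config()] objects, one per subject x condition.
#' @export
cohort_configs <- function(n_subjects, conditions = SIM_CONDITIONS,
                           base_seed = 1, ...) {
  if (!is_count(n_subjects)) stopf("n_subjects must be a positive count")
  conditions <- match.arg(conditions, SIM_CONDITIONS, several.ok = TRUE)
  rr <- with_seed(derive_seed(base_seed, 0), stats::runif(n_subjects, 8, 22))
  out <- vector("list", n_subjects * length(conditions))
  k <- 0
  for (s in seq_len(n_subjects)) {
    for (ci in seq_along(conditions)) {
      k <- k + 1
      out[[k]] <- sim_config(subject_id = sprintf("S%02d", s),
                             condition = conditions[ci],
                             rr_bpm = rr[s],
                             rng_seed = derive_seed(base_seed, s, ci), ...)
    }
  }
  out
}
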