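## Recording serialization -------------------------------------------------
##
## Recordings are written as a directory of 16-bit grayscale PNG frames
## plus a CSV belt trace and a JSON metadata sidecar; everything needed to
## round-trip a `thermal_recording` through plain files.

#' Write / read a thermal recording
#'
#' `write_recording` stores `rec$frames` as 16-bit PNG files
#' (`frame_000001.png`, ...; intensities scaled by `intensity_max`), the
#' belt as `belt.csv`, truth boxes as `truth_boxes.csv` /
#' `truth_patch.csv`, and scalar metadata as `meta.json`.
#' `read_recording` reconstructs the `thermal_recording` (frame
#' intensities are quantized to 16 bits by the round trip). Requires the
#' `png` package.
#'
#' @param rec A `thermal_recording`.
#' @param dir Directory to create/read.
#' @return `write_recording` returns `dir` invisibly; `read_recording`
#'   returns a `thermal_recording`.
#' @export
write_recording <- function(rec, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("the `png` package is required for recording serialization")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  T_ <- dim(rec$frames)[3]
  for (i in seq_len(T_)) {
    png::writePNG(rec$frames[, , i] / rec$intensity_max,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  utils::write.csv(data.frame(value = rec$belt$samples),
                   file.path(dir, "belt.csv"), row.names = FALSE)
  utils::write.csv(rec$truth_boxes, file.path(dir, "truth_boxes.csv"),
                   row.names = FALSE)
  if (!is.null(rec$truth_patch))
    utils::write.csv(rec$truth_patch, file.path(dir, "truth_patch.csv"),
                     row.names = FALSE)
  meta <- list(fps = rec$fps, belt_fs = rec$belt$fs,
               truth_rr_bpm = rec$truth_rr_bpm, belt_lag_s = rec$belt_lag_s,
               condition = rec$condition, subject_id = rec$subject_id,
               intensity_max = rec$intensity_max, n_frames = T_)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("the `png` package is required for recording serialization")
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  stopifnot(length(files) == meta$n_frames)
  f1 <- png::readPNG(files[1])
  frames <- array(0, dim = c(nrow(f1), ncol(f1), length(files)))
  for (i in seq_along(files))
    frames[, , i] <- png::readPNG(files[i]) * meta$intensity_max
  belt <- utils::read.csv(file.path(dir, "belt.csv"))$value
  tp_path <- file.path(dir, "truth_patch.csv")
  structure(list(
    frames = frames, fps = meta$fps,
    belt = resp_signal(belt, meta$belt_fs),
    truth_rr_bpm = meta$truth_rr_bpm,
    truth_boxes = utils::read.csv(file.path(dir, "truth_boxes.csv")),
    truth_patch = if (file.exists(tp_path)) utils::read.csv(tp_path) else NULL,
    belt_lag_s = meta$belt_lag_s, condition = meta$condition,
    subject_id = meta$subject_id, intensity_max = meta$intensity_max,
    config = NULL
  ), class = "thermal_recording")
}
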