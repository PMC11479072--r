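## Facial ROI detection and dynamic cropping ------------------------------
##
## Track-by-detection: a detector is run on every frame and the per-frame
## crops are stacked into a stabilized face video. The detector is a
## pluggable function `function(frame) -> bounding box (or NULL)`; the
## package ships a deterministic intensity detector suited to synthetic
## thermal frames. A transformer-based face detector trained on thermal
## imagery can be slotted into the same interface (see
## `vignette("thermoresp-methods")`); only the intensity detector is
## exercised by the test suite.
##
## All pixel boxes are 0-based and half-open: [x0, x1) x [y0, y1).

#' Construct a bounding box
#'
#' Boxes use a single convention everywhere in the package: 0-based,
#' half-open pixel intervals `[x0, x1) x [y0, y1)`.
#'
#' @param x0,y0,x1,y1 Box edges in pixels; `x0 < x1`, `y0 < y1`.
#' @param frame_index 0-based frame index (optional).
#' @param confidence Detection confidence in \[0, 1\].
#' @return A one-row data frame with class `bounding_box`.
#' @export
bounding_box <- function(x0, y0, x1, y1, frame_index = NA_integer_,
                         confidence = 1) {
  if (!(x0 < x1 && y0 < y1)) stopf("invalid box: need x0 < x1 and y0 < y1")
  if (confidence < 0 || confidence > 1) stopf("confidence must be in [0, 1]")
  structure(data.frame(frame = frame_index, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                       confidence = confidence),
            class = c("bounding_box", "data.frame"))
}

box_area <- function(b) (b$x1 - b$x0) * (b$y1 - b$y0)

#' Intersection over union of two boxes
#' @param a,b Boxes (one-row data frames with x0, y0, x1, y1).
#' @return IoU in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  iy <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- ix * iy
  inter / (box_area(a) + box_area(b) - inter)
}

## tie-break rule for multiple candidates: highest confidence, then larger
## area, then top-left (smaller y0, then smaller x0)
pick_box <- function(candidates) {
  if (nrow(candidates) == 1) return(candidates)
  o <- order(-candidates$confidence, -(candidates$x1 - candidates$x0) *
               (candidates$y1 - candidates$y0),
             candidates$y0, candidates$x0)
  candidates[o[1], , drop = FALSE]
}

## O(HW) box blur via cumulative sums; light spatial smoothing so that
## sensor noise does not fragment the thresholded foreground
box_blur <- function(x, k = 5) {
  if (k <= 1) return(x)
  h <- (k - 1) %/% 2
  blur1 <- function(m) {           # running mean down the columns
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    lo <- pmax(0, seq_len(n) - h - 1); hi <- pmin(n, seq_len(n) + h)
    (cs[hi + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]) / (hi - lo)
  }
  t(blur1(t(blur1(x))))
}

## Otsu's threshold (maximum between-class variance) on a 256-bin
## histogram; deterministic and robust to the warm region's own noise
otsu_threshold <- function(x, nbins = 256) {
  rng <- range(x)
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / (rng[2] - rng[1]) * nbins)),
                nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) * (rng[2] - rng[1]) / nbins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_tot <- mu0[nbins]
  between <- (mu_tot * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Intensity-based face detector for thermal frames
#'
#' A deterministic detector for thermal-like imagery in which the face is
#' the dominant warm region. The frame is lightly box-blurred (so sensor
#' noise cannot fragment the foreground), thresholded at the lower of a
#' high intensity percentile and Otsu's background/foreground cut (pixels
#' at or above the threshold are foreground, keeping constant warm
#' plateaus intact), the largest 4-connected foreground component is
#' taken, and its tight bounding box is expanded by a relative margin and
#' clipped to the frame. Confidence is the fill ratio (component area /
#' box area).
#'
#' @param frame Numeric H x W matrix of intensities.
#' @param quantile Threshold percentile (default 0.95); the effective
#'   threshold is `min(percentile, Otsu)` so that warm regions larger than
#'   `1 - quantile` of the frame are still segmented whole.
#' @param margin Relative box expansion (default 0.10).
#' @param blur Box-blur window in pixels (default 5; 1 disables).
#' @return A [bounding_box()], or `NULL` when there is no usable
#'   foreground (e.g. a uniform frame, where nothing stands out).
#' @export
intensity_detector <- function(frame, quantile = 0.95, margin = 0.10, blur = 5) {
  if (!is.matrix(frame) || length(frame) == 0) stopf("frame must be a non-empty matrix")
  H <- nrow(frame); W <- ncol(frame)
  sm <- box_blur(frame, blur)
  rng <- range(sm)
  if (rng[2] - rng[1] <= 1e-12 * max(abs(rng), 1)) return(NULL)  # uniform frame
  thr <- min(stats::quantile(sm, quantile, names = FALSE), otsu_threshold(sm))
  fg <- sm >= thr
  if (mean(fg) > 0.9) return(NULL)   # nothing stands out
  if (!any(fg)) return(NULL)
  lab <- cpp_label_components(fg)
  tab <- tabulate(lab[lab > 0])
  best <- which.max(tab)   # ties: lowest label = first in column-major scan
  idx <- which(lab == best, arr.ind = TRUE)
  y0 <- min(idx[, 1]) - 1; y1 <- max(idx[, 1])
  x0 <- min(idx[, 2]) - 1; x1 <- max(idx[, 2])
  my <- margin * (y1 - y0); mx <- margin * (x1 - x0)
  b <- c(max(0, floor(x0 - mx)), max(0, floor(y0 - my)),
         min(W, ceiling(x1 + mx)), min(H, ceiling(y1 + my)))
  conf <- min(1, tab[best] / ((b[3] - b[1]) * (b[4] - b[2])))
  bounding_box(b[1], b[2], b[3], b[4], confidence = conf)
}

#' Detect the facial ROI on every frame of a recording
#'
#' Runs `detector` on each frame (track-by-detection). Frames where
#' detection fails inherit the nearest previous valid box (leading failures
#' inherit the first valid one); if no frame yields a detection the call
#' fails. If a detector returns several candidate boxes, the highest
#' confidence wins, ties broken by larger area then top-left position.
#'
#' @param recording A `thermal_recording`, or an H x W x T array.
#' @param detector A function `frame -> bounding_box` (possibly multi-row,
#'   or `NULL` on failure). Default [intensity_detector()].
#' @param ... Passed on to `detector`.
#' @return A data frame of per-frame boxes (`frame, x0, y0, x1, y1,
#'   confidence`), one row per frame.
#' @export
detect_faces <- function(recording, detector = intensity_detector, ...) {
  frames <- if (inherits(recording, "thermal_recording")) recording$frames else recording
  stopifnot(length(dim(frames)) == 3)
  T_ <- dim(frames)[3]
  rows <- vector("list", T_)
  for (i in seq_len(T_)) {
    b <- detector(frames[, , i], ...)
    if (!is.null(b) && nrow(b) > 1) b <- pick_box(b)
    if (!is.null(b)) b$frame <- i - 1L
    rows[[i]] <- b
  }
  valid <- !vapply(rows, is.null, logical(1))
  if (!any(valid)) stopf("face detection failed on every frame")
  ## carry the last valid box forward; leading failures take the first valid
  first_valid <- which(valid)[1]
  for (i in seq_len(T_)) {
    if (!valid[i]) {
      src <- if (i < first_valid) first_valid else max(which(valid[seq_len(i)]))
      rows[[i]] <- rows[[src]]
      rows[[i]]$frame <- i - 1L
      rows[[i]]$confidence <- 0
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Temporally smooth a track of bounding boxes
#'
#' Per-coordinate centered moving median over `window` frames, suppressing
#' frame-to-frame detector jitter that would otherwise shake the cropped
#' video. Edges use the available part of the window. Output coordinates
#' are rounded to integer pixels; boxes never leave the original frame
#' bounds (the median of in-bounds values is in bounds, and rounding is
#' clipped).
#'
#' @param boxes Data frame of per-frame boxes as from [detect_faces()].
#' @param window Odd window length in frames (>= 1); `window = 1` returns
#'   the input unchanged.
#' @param frame_size Optional `c(height, width)` to clip against.
#' @return Data frame of smoothed boxes.
#' @export
smooth_boxes <- function(boxes, window = 5, frame_size = NULL) {
  if (!is_count(window) || window %% 2 == 0) stopf("window must be odd and >= 1")
  if (window == 1) return(boxes)
  n <- nrow(boxes)
  half <- (window - 1) / 2
  out <- boxes
  for (col in c("x0", "y0", "x1", "y1")) {
    v <- boxes[[col]]
    sm <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      sm[i] <- stats::median(v[lo:hi])
    }
    out[[col]] <- round(sm)
  }
  if (!is.null(frame_size)) {
    out$x0 <- pmax(0, out$x0); out$y0 <- pmax(0, out$y0)
    out$x1 <- pmin(frame_size[2], out$x1); out$y1 <- pmin(frame_size[1], out$y1)
  }
  bad <- out$x1 <= out$x0 | out$y1 <= out$y0
  if (any(bad)) stopf("smoothing produced a degenerate box at frame %d",
                      which(bad)[1] - 1)
  out
}

#' Crop every frame to its box and resize
#'
#' Each frame is cropped to its bounding box and resampled to `out_size`
#' with bilinear interpolation; the crops are stacked in time order into a
#' dynamically cropped face video. A full-frame box at native output size
#' is an exact identity, and spatially constant frames stay exactly
#' constant.
#'
#' @param recording A `thermal_recording` or an H x W x T array.
#' @param boxes Data frame with one box per frame (`x0, y0, x1, y1`).
#' @param out_size Output `c(height, width)` (default `c(128, 128)`).
#' @return An `out_h x out_w x T` array.
#' @export
crop_and_resize <- function(recording, boxes, out_size = c(128, 128)) {
  frames <- if (inherits(recording, "thermal_recording")) recording$frames else recording
  stopifnot(length(dim(frames)) == 3)
  if (nrow(boxes) != dim(frames)[3]) stopf("need one box per frame")
  bm <- as.matrix(boxes[, c("x0", "y0", "x1", "y1")])
  storage.mode(bm) <- "double"
  cpp_crop_resize(frames, bm, as.integer(out_size[1]), as.integer(out_size[2]))
}

#' Write / read a box track as CSV
#' @param boxes Data frame of boxes.
#' @param path File path.
#' @return `read_boxes_csv` returns the data frame; `write_boxes_csv` its
#'   path, invisibly.
#' @export
write_boxes_csv <- function(boxes, path) {
  utils::write.csv(boxes[, c("frame", "x0", "y0", "x1", "y1", "confidence")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boxes_csv
#' @export
read_boxes_csv <- function(path) utils::read.csv(path)
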