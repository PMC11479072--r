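## Training / evaluation orchestration ------------------------------------

#' Training configuration
#'
#' Defaults follow the published protocol for this estimator family:
#' 15 epochs, batch size 2, Adam with learning rate 0.001, five repeats of
#' subject-wise 18/2/2 train/validation/test splits.
#'
#' @param epochs Training epochs (default 15).
#' @param batch_size Clips per optimizer step (default 2).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param n_repeats Number of repeated subject-wise splits (default 5).
#' @param split `c(train, val, test)` subject counts (default
#'   `c(18, 2, 2)`).
#' @param loss `"nmcc_afd"` (the phase-tolerant objective) or `"rmse"` (a
#'   baseline toggle; pointwise and phase-sensitive).
#' @param loss_cfg A [loss_config()].
#' @param model_cfg A [model_config()].
#' @param rng_seed Seed for splits and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 15, batch_size = 2, learning_rate = 0.001,
                         n_repeats = 5, split = c(18, 2, 2),
                         loss = c("nmcc_afd", "rmse"),
                         loss_cfg = loss_config(), model_cfg = model_config(),
                         rng_seed = 1) {
  loss <- match.arg(loss)
  if (!is_count(epochs) || !is_count(batch_size)) stopf("epochs/batch_size must be counts")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (length(split) != 3 || any(split < 1)) stopf("split must be c(train, val, test), each >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, n_repeats = as.integer(n_repeats),
                 split = as.integer(split), loss = loss, loss_cfg = loss_cfg,
                 model_cfg = model_cfg, rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Subject-wise train/validation/test splits
#'
#' `n_repeats` seeded random partitions of the subjects. All clips of a
#' subject (all conditions) stay in one fold, so no information leaks from
#' training to test subjects. Test sets are disjoint across repeats as far
#' as the cohort size permits (subjects are cycled in a shuffled order).
#'
#' @param subject_ids Character vector of distinct subject ids.
#' @param split `c(train, val, test)` counts.
#' @param n_repeats Number of partitions.
#' @param seed RNG seed.
#' @return A list of `n_repeats` lists with elements `train`, `val`,
#'   `test` (character vectors partitioning `subject_ids`).
#' @export
make_splits <- function(subject_ids, split = c(18, 2, 2), n_repeats = 5, seed = 1) {
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  if (n < sum(split))
    stopf("%d subjects cannot be split into %d/%d/%d", n, split[1], split[2], split[3])
  with_seed(seed, {
    shuffled <- sample(subject_ids)
    lapply(seq_len(n_repeats), function(r) {
      ## cycle test sets through the shuffled order for cross-repeat disjointness
      idx <- ((r - 1) * split[3] + seq_len(split[3]) - 1) %% n + 1
      test <- shuffled[idx]
      rest <- setdiff(shuffled, test)
      val <- sample(rest, split[2])
      train <- sample(setdiff(rest, val), split[1])
      list(train = train, val = val, test = test)
    })
  })
}

clip_subjects <- function(clips) vapply(clips, function(cl) cl$subject_id, character(1))

## per-clip loss and gradient at the model output
clip_loss_grad <- function(y, target, cfg) {
  if (cfg$loss == "rmse") {
    t_s <- as_samples(target)
    d <- y - t_s
    rmse <- sqrt(mean(d^2))
    g <- if (rmse > 0) d / (length(d) * rmse) else d * 0
    list(loss = rmse, grad = g)
  } else {
    list(loss = combined_loss(y, target, cfg$loss_cfg),
         grad = combined_loss_grad(y, target, cfg$loss_cfg))
  }
}

batch_mean_loss <- function(model, clips, cfg) {
  mean(vapply(clips, function(cl) {
    y <- forward_one(model, clip_frames(cl))$y
    clip_loss_grad(y, cl$target, cfg)$loss
  }, numeric(1)))
}

#' Fit the respiratory signal estimator
#'
#' Trains the 3D CNN + bi-LSTM estimator on a set of clips by stochastic
#' gradient descent (Adam), minimizing the phase-tolerant NMCC+AFD
#' objective (or RMSE when `cfg$loss = "rmse"`). Validation loss is
#' tracked per epoch and the returned weights are those of the best
#' validation epoch. With the hard-argmax AFD, gradients flow only through
#' the NMCC term; `alpha = 0` with `soft_afd = FALSE` therefore has an
#' identically zero gradient and training refuses to start.
#'
#' @param clips List of `clip_sample` objects (training set).
#' @param cfg A [train_config()].
#' @param val_clips Optional validation clips; without them the best epoch
#'   is the last.
#' @param quiet Suppress per-epoch messages.
#' @return An object of class `rr_estimator`: the fitted `rr_model`, the
#'   loss history, the configuration, and a validation evaluation report.
#' @export
fit_rr_estimator <- function(clips, cfg = train_config(), val_clips = NULL,
                             quiet = FALSE) {
  stopifnot(inherits(cfg, "train_config"), length(clips) >= 1)
  if (cfg$loss == "nmcc_afd" && cfg$loss_cfg$alpha == 0 && !cfg$loss_cfg$soft_afd)
    stopf(paste("alpha = 0 with the hard-argmax AFD has identically zero",
                "gradients (no term of the loss is differentiable);",
                "use alpha > 0 or soft_afd = TRUE"))

  model <- build_model(cfg$model_cfg, quiet = quiet)
  opt <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(val = Inf, params = model$params, epoch = 0L)
  n <- length(clips)

  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$rng_seed, ep), sample(n))
    ep_losses <- numeric(0)
    for (bstart in seq(1, n, by = cfg$batch_size)) {
      bidx <- ord[bstart:min(bstart + cfg$batch_size - 1, n)]
      gsum <- NULL
      blosses <- numeric(length(bidx))
      for (j in seq_along(bidx)) {
        cl <- clips[[bidx[j]]]
        fwd <- forward_one(model, clip_frames(cl), keep_cache = TRUE)
        lg <- tryCatch(clip_loss_grad(fwd$y, cl$target, cfg),
                       error = function(e) NULL)
        if (is.null(lg)) { blosses[j] <- NA; next }   # e.g. no in-band energy
        blosses[j] <- lg$loss
        bw <- backward_one(model, fwd, lg$grad / length(bidx))
        gsum <- if (is.null(gsum)) bw$grads
                else mapply(`+`, gsum, bw$grads, SIMPLIFY = FALSE)
      }
      if (is.null(gsum)) next
      if (any(!is.finite(unlist(lapply(gsum, range)))))
        stopf("non-finite gradient at epoch %d; aborting (try a lower learning rate)", ep)
      st <- adam_step(model$params, gsum, opt, lr = cfg$learning_rate)
      model$params <- st$params
      opt <- st$state
      ep_losses <- c(ep_losses, blosses)
    }
    train_loss <- mean(ep_losses, na.rm = TRUE)
    if (!is.finite(train_loss)) stopf("loss became non-finite at epoch %d", ep)
    val_loss <- if (!is.null(val_clips)) batch_mean_loss(model, val_clips, cfg) else NA_real_
    history <- rbind(history, data.frame(epoch = ep, train_loss = train_loss,
                                         val_loss = val_loss))
    if (!quiet)
      message(sprintf("epoch %2d/%d: train %.4f%s", ep, cfg$epochs, train_loss,
                      if (is.na(val_loss)) "" else sprintf(", val %.4f", val_loss)))
    if (!is.na(val_loss) && val_loss < best$val)
      best <- list(val = val_loss, params = model$params, epoch = ep)
  }
  if (is.finite(best$val)) model$params <- best$params
  else best$epoch <- cfg$epochs

  est <- structure(list(model = model, history = history, config = cfg,
                        best_epoch = best$epoch, n_train_clips = n),
                   class = "rr_estimator")
  if (!is.null(val_clips)) est$val_report <- evaluate(model, val_clips, cfg$loss_cfg)
  est
}

#' @export
print.rr_estimator <- function(x, ...) {
  cat(sprintf("<rr_estimator> trained %d epochs on %d clips (loss: %s); best epoch %d\n",
              nrow(x$history), x$n_train_clips, x$config$loss, x$best_epoch))
  cat(sprintf("  final train loss %.4f", utils::tail(x$history$train_loss, 1)))
  if (!all(is.na(x$history$val_loss)))
    cat(sprintf(", best val loss %.4f", min(x$history$val_loss, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @export
summary.rr_estimator <- function(object, ...) {
  print(object)
  print(object$model)
  if (!is.null(object$val_report)) {
    cat("validation performance:\n")
    print(object$val_report)
  }
  invisible(object)
}

#' @export
coef.rr_estimator <- function(object, ...) object$model$params

#' @export
plot.rr_estimator <- function(x, ...) {
  h <- x$history
  ylim <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "b", pch = 16, ylim = ylim,
                 xlab = "epoch", ylab = "loss", main = "training history", ...)
  if (!all(is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, type = "b", pch = 1, lty = 2)
    graphics::legend("topright", c("train", "validation"), pch = c(16, 1),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' @export
predict.rr_estimator <- function(object, newdata, ...) forward(object$model, newdata)

#' @export
residuals.rr_estimator <- function(object, ...) {
  if (is.null(object$val_report))
    stopf("no validation clips were supplied at fit time; evaluate() explicitly")
  r <- object$val_report$per_clip
  stats::setNames(r$est_bpm - r$true_bpm, r$clip_id)
}

#' Run a full simulate / preprocess / train / evaluate experiment
#'
#' Simulates (or takes) a cohort, extracts clips, and for each repeat of a
#' subject-wise split trains the estimator on the training subjects and
#' evaluates it on the held-out test subjects. Aggregates are means and
#' standard deviations across repeats. Full provenance (configurations and
#' seeds) is embedded in the result.
#'
#' @param cohort A list of `thermal_recording`s, or `NULL` to simulate one.
#' @param train_cfg A [train_config()].
#' @param n_subjects,conditions,base_seed,... Cohort simulation arguments
#'   (passed to [simulate_cohort()]) when `cohort` is `NULL`.
#' @param out_size,analysis_fps Preprocessing arguments (see
#'   [make_clips()]).
#' @param clips Optionally precomputed clips (bypasses simulation and
#'   preprocessing entirely, e.g. from [reference_clips()]).
#' @param keep_models Keep the fitted estimator of each repeat (default
#'   `TRUE`).
#' @param quiet Suppress progress messages.
#' @return An object of class `rr_experiment`: per-repeat evaluation
#'   reports and fitted models, aggregate metrics (mean and sd across
#'   repeats of mean error, max x-corr and % of clips under 2 BPM), and
#'   provenance.
#' @export
run_experiment <- function(cohort = NULL, train_cfg = train_config(),
                           n_subjects = 22, conditions = SIM_CONDITIONS,
                           base_seed = 1, out_size = NULL, analysis_fps = 5,
                           clips = NULL, keep_models = TRUE, quiet = FALSE, ...) {
  if (is.null(out_size)) out_size <- train_cfg$model_cfg$spatial_in
  if (is.null(clips)) {
    if (is.null(cohort))
      cohort <- simulate_cohort(n_subjects, conditions, base_seed, ...)
    if (!quiet) message(sprintf("preprocessing %d recordings ...", length(cohort)))
    clips <- list()
    for (rec in cohort)
      clips <- c(clips, make_clips(rec, out_size = out_size,
                                   analysis_fps = analysis_fps))
  }
  subj <- clip_subjects(clips)
  splits <- make_splits(unique(subj), train_cfg$split, train_cfg$n_repeats,
                        seed = train_cfg$rng_seed)

  repeats <- vector("list", length(splits))
  for (r in seq_along(splits)) {
    sp <- splits[[r]]
    ## programmatic leakage check: folds partition the subjects
    stopifnot(length(intersect(sp$train, sp$test)) == 0,
              length(intersect(sp$train, sp$val)) == 0,
              length(intersect(sp$val, sp$test)) == 0)
    if (!quiet)
      message(sprintf("repeat %d/%d: train %s | val %s | test %s",
                      r, length(splits), paste(sp$train, collapse = ","),
                      paste(sp$val, collapse = ","), paste(sp$test, collapse = ",")))
    cfg_r <- train_cfg
    cfg_r$rng_seed <- as.integer(derive_seed(train_cfg$rng_seed, r))
    cfg_r$model_cfg$rng_seed <- as.integer(derive_seed(train_cfg$rng_seed, r, 1))
    fit <- fit_rr_estimator(clips[subj %in% sp$train], cfg_r,
                            val_clips = clips[subj %in% sp$val], quiet = quiet)
    report <- evaluate(fit, clips[subj %in% sp$test], train_cfg$loss_cfg)
    repeats[[r]] <- list(split = sp, report = report,
                         fit = if (keep_models) fit else NULL)
  }

  per_repeat <- do.call(rbind, lapply(seq_along(repeats), function(r) {
    a <- repeats[[r]]$report$aggregates
    data.frame(repeat_ = r, mean_abs_error_bpm = a$mean_abs_error_bpm,
               mean_max_xcorr = a$mean_max_xcorr,
               pct_under_2bpm = a$pct_under_2bpm, n_test_clips = a$n_evaluated)
  }))
  aggregates <- list(
    n_repeats = nrow(per_repeat),
    mean_abs_error_bpm = mean(per_repeat$mean_abs_error_bpm),
    sd_abs_error_bpm = stats::sd(per_repeat$mean_abs_error_bpm),
    mean_max_xcorr = mean(per_repeat$mean_max_xcorr),
    sd_max_xcorr = stats::sd(per_repeat$mean_max_xcorr),
    pct_under_2bpm = mean(per_repeat$pct_under_2bpm),
    n_clips_total = length(clips)
  )
  structure(list(repeats = repeats, per_repeat = per_repeat,
                 aggregates = aggregates,
                 provenance = list(train_cfg = train_cfg, base_seed = base_seed,
                                   n_recordings = length(cohort),
                                   out_size = out_size,
                                   analysis_fps = analysis_fps,
                                   package_version = as.character(
                                     utils::packageVersion("thermoresp")))),
            class = "rr_experiment")
}

#' The package's scaled-down reference experiment
#'
#' A complete simulate / preprocess / train / evaluate run sized for a
#' desktop CPU: 8 subjects under two conditions (seated without a mask,
#' standing with a mask), 40 s recordings at 120x160 px, 64x64 clips, a
#' compact model variant (~50 k parameters), 5 training epochs and one
#' subject-wise 6/1/1 split. All protocol constants that matter to the
#' method (10 s / 5 s sliding windows, 5 Hz analysis rate, 50-frame clips,
#' the 0.05-0.7 Hz band, batch size 2, Adam at 0.001) are the full-protocol
#' values; only cohort size, recording length, frame geometry, network
#' width and epoch count are reduced.
#'
#' @param seed Master seed for the cohort, splits and weight init.
#' @param loss `"nmcc_afd"` or `"rmse"` (the baseline toggle).
#' @param clips Optionally precomputed clips from [reference_clips()]
#'   (lets the two loss modes share one preprocessed cohort).
#' @param epochs,n_repeats Override the run size.
#' @param quiet Suppress progress output.
#' @return An `rr_experiment` (with `$cohort_args` describing the cohort so
#'   individual recordings can be regenerated).
#' @export
run_reference_experiment <- function(seed = 1, loss = c("nmcc_afd", "rmse"),
                                     clips = NULL, epochs = 5, n_repeats = 1,
                                     quiet = TRUE) {
  loss <- match.arg(loss)
  if (is.null(clips)) clips <- reference_clips(seed, quiet = quiet)
  mcfg <- model_config(vanilla_pre = c(6, 12), encoder_channels = 24,
                       decoder_channels = 24, vanilla_post = c(24),
                       lstm_hidden = 24, spatial_in = c(64, 64),
                       rng_seed = seed)
  tcfg <- train_config(epochs = epochs, n_repeats = n_repeats,
                       split = c(6, 1, 1), loss = loss, model_cfg = mcfg,
                       rng_seed = seed)
  ex <- run_experiment(clips = clips, train_cfg = tcfg, quiet = quiet)
  ex$cohort_args <- reference_cohort_args(seed)
  ex
}

#' @rdname run_reference_experiment
#' @export
reference_cohort_args <- function(seed = 1) {
  list(n_subjects = 8, conditions = c("sit_nomask", "stand_mask"),
       base_seed = seed, duration_s = 40, frame_size = c(120, 160))
}

#' Preprocessed clips of the reference cohort
#'
#' Simulates the reference cohort one recording at a time (so full-frame
#' video never accumulates in memory) and runs the standard preprocessing
#' chain into 64x64 clips.
#'
#' @param seed Cohort seed.
#' @param out_size Clip spatial size (default `c(64, 64)`).
#' @param quiet Suppress progress output.
#' @return A list of `clip_sample` objects.
#' @export
reference_clips <- function(seed = 1, out_size = c(64, 64), quiet = TRUE) {
  cfgs <- do.call(cohort_configs, reference_cohort_args(seed))
  clips <- list()
  for (cfg in cfgs) {
    rec <- simulate_recording(cfg)
    if (!quiet) message("preprocessing ", rec$subject_id, " ", rec$condition)
    clips <- c(clips, make_clips(rec, out_size = out_size))
    rm(rec)
  }
  clips
}

#' @export
print.rr_experiment <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("<rr_experiment> %d repeats, %d clips total\n", a$n_repeats, a$n_clips_total))
  cat(sprintf("  RR error: %.2f +/- %.2f BPM (mean +/- sd across repeats)\n",
              a$mean_abs_error_bpm, a$sd_abs_error_bpm))
  cat(sprintf("  max x-corr: %.2f +/- %.2f\n", a$mean_max_xcorr, a$sd_max_xcorr))
  cat(sprintf("  clips with < 2 BPM error: %.1f%%\n", a$pct_under_2bpm))
  invisible(x)
}
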