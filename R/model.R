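## Spatio-temporal respiratory signal estimator ---------------------------
##
## Architecture: a stack of "vanilla" 3D conv blocks (3x3x3 conv + ReLU +
## spatial-only average pooling, sequence length unchanged), exactly one
## encoder block (conv + ReLU + average pooling with temporal stride 2,
## halving the sequence), exactly one decoder block (transposed 3D conv
## with temporal stride 2, restoring the sequence length), further vanilla
## blocks, global spatial average pooling per time step, a bi-directional
## LSTM over the 50-step sequence, and a per-step fully connected map to
## the 1-D respiratory signal. With one temporal pooling at the 5 Hz
## analysis rate the internal sequence runs at 2.5 Hz, whose 1.25 Hz
## Nyquist still covers the 0.7 Hz respiration band; a second temporal
## pooling would not, which is why the config enforces exactly one.

#' Model configuration
#'
#' Channel widths, block counts and the nonlinearity are tunable; the
#' defaults give a compact network (~0.58 M parameters) in the size class
#' of published video vital-sign estimators. The hard architectural
#' constraint is the single temporal-stride-2 encoder/decoder pair (see
#' the Nyquist argument above); violating it is a build error.
#'
#' @param in_channels Input channels (1 for thermal video).
#' @param vanilla_pre Channel widths of vanilla blocks before the encoder
#'   (default `c(16, 32)`).
#' @param encoder_channels Channels of the single temporal encoder block
#'   (default 64).
#' @param decoder_channels Channels of the single temporal decoder block
#'   (default 64).
#' @param vanilla_post Channel widths of vanilla blocks after the decoder
#'   (default `c(64, 64, 64)`; the last value is the channel count of the
#'   final 3D feature volume).
#' @param n_encoder,n_decoder Number of temporal encoder / decoder blocks;
#'   must both be 1 (exposed so the constraint is explicit and testable).
#' @param lstm_hidden LSTM hidden units per direction (default 64).
#' @param lstm_bidirectional Process the sequence in both directions
#'   (default `TRUE`).
#' @param seq_len Clip length in frames at the analysis rate (default 50).
#' @param spatial_in Input spatial size `c(height, width)` (default
#'   `c(128, 128)`).
#' @param analysis_fps Analysis frame rate in Hz (default 5); used for the
#'   internal-Nyquist check.
#' @param band Respiration band (Hz) the internal rate must cover.
#' @param rng_seed Seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(in_channels = 1, vanilla_pre = c(16, 32),
                         encoder_channels = 64, decoder_channels = 64,
                         vanilla_post = c(64, 64, 64),
                         n_encoder = 1, n_decoder = 1,
                         lstm_hidden = 64, lstm_bidirectional = TRUE,
                         seq_len = 50, spatial_in = c(128, 128),
                         analysis_fps = 5, band = c(0.05, 0.7),
                         rng_seed = 1) {
  structure(list(in_channels = in_channels, vanilla_pre = vanilla_pre,
                 encoder_channels = encoder_channels,
                 decoder_channels = decoder_channels,
                 vanilla_post = vanilla_post,
                 n_encoder = n_encoder, n_decoder = n_decoder,
                 lstm_hidden = lstm_hidden,
                 lstm_bidirectional = isTRUE(lstm_bidirectional),
                 seq_len = seq_len, spatial_in = as.integer(spatial_in),
                 analysis_fps = analysis_fps, band = band,
                 rng_seed = as.integer(rng_seed)),
            class = "model_config")
}

#' Build the respiratory signal estimator
#'
#' Instantiates the layer plan and seeded initial weights described by a
#' [model_config()]. The parameter count is logged at build time.
#'
#' @param cfg A [model_config()].
#' @param quiet Suppress the build message.
#' @return An object of class `rr_model`.
#' @export
build_model <- function(cfg = model_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "model_config"))
  if (cfg$n_encoder != 1 || cfg$n_decoder != 1)
    stopf(paste("exactly one temporal encoder and one decoder block are required:",
                "the internal rate after k temporal-stride-2 poolings is fps/2^k,",
                "and only k = 1 keeps the internal Nyquist above the %g Hz band edge"),
          cfg$band[2])
  internal_nyquist <- cfg$analysis_fps / 2^cfg$n_encoder / 2
  if (internal_nyquist <= cfg$band[2])
    stopf("internal Nyquist %.3g Hz does not cover the band edge %.3g Hz",
          internal_nyquist, cfg$band[2])

  ## layer plan; pooling factors adapt to the spatial size reached
  plan <- list()
  H <- cfg$spatial_in[1]; W <- cfg$spatial_in[2]
  cin <- cfg$in_channels
  spool <- function(H, W) c(if (H >= 2) 2 else 1, if (W >= 2) 2 else 1)
  for (ch in cfg$vanilla_pre) {
    sp <- spool(H, W)
    plan[[length(plan) + 1]] <- list(type = "conv", cin = cin, cout = ch,
                                     pool = c(sp, 1))
    H <- H %/% sp[1]; W <- W %/% sp[2]; cin <- ch
  }
  sp <- spool(H, W)
  plan[[length(plan) + 1]] <- list(type = "conv", cin = cin,
                                   cout = cfg$encoder_channels,
                                   pool = c(sp, 2), role = "encoder")
  H <- H %/% sp[1]; W <- W %/% sp[2]; cin <- cfg$encoder_channels
  plan[[length(plan) + 1]] <- list(type = "tconv", cin = cin,
                                   cout = cfg$decoder_channels, pool = NULL,
                                   role = "decoder")
  cin <- cfg$decoder_channels
  for (ch in cfg$vanilla_post) {
    sp <- spool(H, W)
    plan[[length(plan) + 1]] <- list(type = "conv", cin = cin, cout = ch,
                                     pool = c(sp, 1))
    H <- H %/% sp[1]; W <- W %/% sp[2]; cin <- ch
  }

  params <- with_seed(cfg$rng_seed, {
    p <- list()
    for (i in seq_along(plan)) {
      ly <- plan[[i]]
      fan_in <- 27 * ly$cin
      p[[sprintf("conv%d_K", i)]] <-
        matrix(stats::rnorm(fan_in * ly$cout, 0, sqrt(2 / fan_in)), fan_in, ly$cout)
      p[[sprintf("conv%d_b", i)]] <- numeric(ly$cout)
    }
    Hh <- cfg$lstm_hidden
    lim <- 1 / sqrt(Hh)
    init_lstm <- function(prefix) {
      out <- list()
      out[[paste0(prefix, "_Wx")]] <- matrix(stats::runif(cin * 4 * Hh, -lim, lim), cin, 4 * Hh)
      out[[paste0(prefix, "_Wh")]] <- matrix(stats::runif(Hh * 4 * Hh, -lim, lim), Hh, 4 * Hh)
      b <- numeric(4 * Hh); b[Hh + 1:Hh] <- 1   # forget-gate bias 1
      out[[paste0(prefix, "_b")]] <- b
      out
    }
    p <- c(p, init_lstm("lstm_f"))
    if (cfg$lstm_bidirectional) p <- c(p, init_lstm("lstm_b"))
    nfc <- if (cfg$lstm_bidirectional) 2 * Hh else Hh
    p$fc_w <- stats::rnorm(nfc, 0, sqrt(1 / nfc))
    p$fc_b <- 0
    p
  })

  model <- structure(list(config = cfg, plan = plan, params = params),
                     class = "rr_model")
  if (!quiet)
    message(sprintf("built rr_model: %d conv blocks, %s LSTM (%d/direction), %s parameters",
                    length(plan), if (cfg$lstm_bidirectional) "bi" else "uni",
                    cfg$lstm_hidden, format(n_params(model), big.mark = ",")))
  model
}

#' Number of trainable parameters
#' @param model An `rr_model` or `rr_estimator`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  if (inherits(model, "rr_estimator")) model <- model$model
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.rr_model <- function(x, ...) {
  cfg <- x$config
  cat("<rr_model> temporal encoder-decoder 3D CNN + ",
      if (cfg$lstm_bidirectional) "bi-" else "", "LSTM\n", sep = "")
  for (i in seq_along(x$plan)) {
    ly <- x$plan[[i]]
    role <- if (!is.null(ly$role)) ly$role else "vanilla"
    pool <- if (is.null(ly$pool)) "temporal x2 (transposed)" else
      sprintf("pool %dx%dx%d", ly$pool[1], ly$pool[2], ly$pool[3])
    cat(sprintf("  [%d] %-7s conv3d %3d -> %3d, %s\n", i, role, ly$cin, ly$cout, pool))
  }
  cat(sprintf("  LSTM %d/direction%s; per-step FC -> 1\n", cfg$lstm_hidden,
              if (cfg$lstm_bidirectional) " (bidirectional)" else ""))
  cat(sprintf("  input %dx%dx%d @ %g Hz; parameters: %s\n", cfg$spatial_in[1],
              cfg$spatial_in[2], cfg$seq_len, cfg$analysis_fps,
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

## insert zeros between time steps (temporal stride-2 transposed conv)
stuff_time <- function(a) {
  d <- dim(a)
  out <- array(0, dim = c(d[1], d[2], 2 * d[3], d[4]))
  out[, , seq(1, 2 * d[3], by = 2), ] <- a
  out
}

unstuff_time <- function(da) {
  d <- dim(da)
  da[, , seq(1, d[3], by = 2), , drop = FALSE]
}

## forward pass for ONE clip (H x W x T array); returns y and, optionally,
## the caches needed for backprop
forward_one <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config
  d <- dim(x)
  if (length(d) != 3) stopf("clip must be an H x W x T array")
  if (d[1] != cfg$spatial_in[1] || d[2] != cfg$spatial_in[2])
    stopf("clip spatial size %dx%d does not match model input %dx%d",
          d[1], d[2], cfg$spatial_in[1], cfg$spatial_in[2])
  if (d[3] < 4 || d[3] %% 2 != 0)
    stopf("clip length must be even and >= 4 (temporal encoder/decoder pair)")
  if (anyNA(x) || any(!is.finite(x))) stopf("non-finite values in input clip")

  a <- array(x, dim = c(d, 1))
  cache <- if (keep_cache) vector("list", length(model$plan)) else NULL
  for (i in seq_along(model$plan)) {
    ly <- model$plan[[i]]
    K <- model$params[[sprintf("conv%d_K", i)]]
    b <- model$params[[sprintf("conv%d_b", i)]]
    conv_in <- if (ly$type == "tconv") stuff_time(a) else a
    z <- cpp_conv3d_fwd(conv_in, K, b)
    r <- z * (z > 0)
    if (keep_cache)
      cache[[i]] <- list(conv_in = conv_in, relu_mask = (z > 0),
                         relu_out = r, in_dims = dim(conv_in))
    a <- if (!is.null(ly$pool) && any(ly$pool > 1))
      cpp_avgpool3d_fwd(r, ly$pool[1], ly$pool[2], ly$pool[3]) else r
  }
  dfeat <- dim(a)
  S <- matrix(colMeans(matrix(a, dfeat[1] * dfeat[2])), dfeat[3], dfeat[4])

  lp <- list(f_Wx = model$params$lstm_f_Wx, f_Wh = model$params$lstm_f_Wh,
             f_b = model$params$lstm_f_b, b_Wx = model$params$lstm_b_Wx,
             b_Wh = model$params$lstm_b_Wh, b_b = model$params$lstm_b_b)
  lf <- bilstm_forward(S, lp, cfg$lstm_bidirectional)
  y <- drop(lf$H %*% model$params$fc_w) + model$params$fc_b
  list(y = y, cache = cache, feat_dims = dfeat, S = S, lstm = lf, lp = lp)
}

## backward pass for one clip given dLoss/dy; returns parameter gradients
## and (optionally) the gradient at the ReLU output of conv layer
## `cam_layer` (for Grad-CAM)
backward_one <- function(model, fwd, dy, cam_layer = NULL) {
  cfg <- model$config
  grads <- list()
  dH <- dy %o% model$params$fc_w
  grads$fc_w <- drop(dy %*% fwd$lstm$H)
  grads$fc_b <- sum(dy)
  lb <- bilstm_backward(fwd$lstm, fwd$lp, dH, cfg$lstm_bidirectional)
  for (nm in names(lb$grads)) grads[[paste0("lstm_", nm)]] <- lb$grads[[nm]]

  dfeat <- fwd$feat_dims
  nspat <- dfeat[1] * dfeat[2]
  ## undo global spatial average pooling: spread dS over space
  da <- array(rep(as.vector(lb$dX), each = nspat) / nspat, dim = dfeat)

  cam_grad <- NULL
  for (i in rev(seq_along(model$plan))) {
    ly <- model$plan[[i]]
    cc <- fwd$cache[[i]]
    if (!is.null(ly$pool) && any(ly$pool > 1)) {
      din <- dim(cc$relu_mask)
      da <- cpp_avgpool3d_bwd(da, din[1], din[2], din[3],
                              ly$pool[1], ly$pool[2], ly$pool[3])
    }
    if (!is.null(cam_layer) && i == cam_layer)
      cam_grad <- da   # gradient w.r.t. the ReLU output of this conv layer
    dz <- da * cc$relu_mask
    K <- model$params[[sprintf("conv%d_K", i)]]
    bw <- cpp_conv3d_bwd(cc$conv_in, K, dz, want_dx = (i > 1))
    grads[[sprintf("conv%d_K", i)]] <- bw$dK
    grads[[sprintf("conv%d_b", i)]] <- drop(bw$db)
    da <- if (i == 1) NULL
          else if (ly$type == "tconv") unstuff_time(bw$dx) else bw$dx
  }
  list(grads = grads, d_input = da, cam_grad = cam_grad)
}

#' Run the estimator on clips
#'
#' @param model An `rr_model`.
#' @param clips A single H x W x T array, a `clip_sample`, or a list of
#'   either.
#' @return A B x T matrix of estimated respiratory signals (one row per
#'   clip). Deterministic for fixed weights and input.
#' @export
forward <- function(model, clips) {
  stopifnot(inherits(model, "rr_model"))
  clips <- as_clip_list(clips)
  ys <- lapply(clips, function(x) forward_one(model, clip_frames(x))$y)
  do.call(rbind, ys)
}

clip_frames <- function(x) if (inherits(x, "clip_sample")) x$frames else x

as_clip_list <- function(clips) {
  if (inherits(clips, "clip_sample") || (is.array(clips) && length(dim(clips)) == 3))
    list(clips)
  else if (is.list(clips)) clips
  else stopf("clips must be an array, a clip_sample, or a list of them")
}

#' @export
predict.rr_model <- function(object, newdata, ...) forward(object, newdata)
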