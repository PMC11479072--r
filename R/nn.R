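## Recurrent / dense layer primitives -------------------------------------
##
## The 3D convolution and pooling kernels live in src/; the sequence stages
## (LSTM, per-step linear head) are small dense operations handled here.
## All layers provide explicit forward caches and backward passes; gradient
## correctness is pinned by finite-difference tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

## X: T x C input sequence; Wx: C x 4H; Wh: H x 4H; b: 4H
## gate order within the 4H axis: input, forget, cell, output
lstm_forward <- function(X, Wx, Wh, b) {
  T_ <- nrow(X); Hh <- ncol(Wh) / 4
  XW <- X %*% Wx
  Hmat <- matrix(0, T_, Hh)
  cache <- vector("list", T_)
  h <- numeric(Hh); cc <- numeric(Hh)
  idx_i <- 1:Hh; idx_f <- Hh + 1:Hh; idx_g <- 2 * Hh + 1:Hh; idx_o <- 3 * Hh + 1:Hh
  for (t in seq_len(T_)) {
    gates <- XW[t, ] + drop(h %*% Wh) + b
    gi <- sigmoid(gates[idx_i]); gf <- sigmoid(gates[idx_f])
    gg <- tanh(gates[idx_g]);    go <- sigmoid(gates[idx_o])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h_prev <- if (t == 1) numeric(Hh) else Hmat[t - 1, ]
    h <- go * tc
    Hmat[t, ] <- h
    cache[[t]] <- list(gi = gi, gf = gf, gg = gg, go = go, c = cc, tc = tc,
                       c_prev = c_prev, h_prev = h_prev)
  }
  list(H = Hmat, cache = cache, X = X)
}

## dH: T x H upstream gradient; returns dX, dWx, dWh, db
lstm_backward <- function(fwd, Wx, Wh, dH) {
  X <- fwd$X; cache <- fwd$cache
  T_ <- nrow(X); Hh <- ncol(dH)
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4 * Hh)
  dX <- matrix(0, T_, nrow(Wx))
  dh_next <- numeric(Hh); dc_next <- numeric(Hh)
  for (t in rev(seq_len(T_))) {
    cc <- cache[[t]]
    dh <- dH[t, ] + dh_next
    dc <- dc_next + dh * cc$go * (1 - cc$tc^2)
    dgo <- dh * cc$tc * cc$go * (1 - cc$go)
    dgi <- dc * cc$gg * cc$gi * (1 - cc$gi)
    dgf <- dc * cc$c_prev * cc$gf * (1 - cc$gf)
    dgg <- dc * cc$gi * (1 - cc$gg^2)
    dgates <- c(dgi, dgf, dgg, dgo)
    dWx <- dWx + X[t, ] %o% dgates
    dWh <- dWh + cc$h_prev %o% dgates
    db <- db + dgates
    dX[t, ] <- drop(Wx %*% dgates)
    dh_next <- drop(Wh %*% dgates)
    dc_next <- dc * cc$gf
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

## bidirectional wrapper: concatenate forward-direction and (time-aligned)
## reverse-direction hidden states per step
bilstm_forward <- function(X, params, bidirectional = TRUE) {
  fw <- lstm_forward(X, params$f_Wx, params$f_Wh, params$f_b)
  if (!bidirectional) return(list(H = fw$H, fw = fw, bw = NULL))
  Xr <- X[rev(seq_len(nrow(X))), , drop = FALSE]
  bw <- lstm_forward(Xr, params$b_Wx, params$b_Wh, params$b_b)
  Hb <- bw$H[rev(seq_len(nrow(X))), , drop = FALSE]
  list(H = cbind(fw$H, Hb), fw = fw, bw = bw)
}

bilstm_backward <- function(fwd, params, dH, bidirectional = TRUE) {
  Hh <- ncol(fwd$fw$H)
  bf <- lstm_backward(fwd$fw, params$f_Wx, params$f_Wh,
                      dH[, seq_len(Hh), drop = FALSE])
  g <- list(f_Wx = bf$dWx, f_Wh = bf$dWh, f_b = bf$db)
  dX <- bf$dX
  if (bidirectional) {
    T_ <- nrow(dH)
    dHb <- dH[rev(seq_len(T_)), Hh + seq_len(Hh), drop = FALSE]
    bb <- lstm_backward(fwd$bw, params$b_Wx, params$b_Wh, dHb)
    g$b_Wx <- bb$dWx; g$b_Wh <- bb$dWh; g$b_b <- bb$db
    dX <- dX + bb$dX[rev(seq_len(T_)), , drop = FALSE]
  }
  list(grads = g, dX = dX)
}

## Adam optimizer state and update over a flat named list of arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
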