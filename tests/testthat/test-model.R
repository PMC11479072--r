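test_that("the default architecture lands in the published size class", {
  expect_message(m <- build_model(model_config()), "parameters")
  expect_gte(n_params(m), 5e5)
  expect_lte(n_params(m), 2e6)
  ## final 3D feature volume has 64 channels
  expect_equal(m$plan[[length(m$plan)]]$cout, 64)
  expect_output(print(m), "encoder")
})

test_that("the temporal encoder/decoder pair preserves sequence length", {
  for (T_ in c(4, 10, 50)) {
    m <- build_model(tiny_model_config(), quiet = TRUE)
    x <- array(rnorm(16 * 16 * T_), c(16, 16, T_))
    y <- forward(m, x)
    expect_equal(dim(y), c(1, T_))
    expect_true(all(is.finite(y)))
  }
  m <- tiny_model()
  expect_error(forward(m, array(1, c(16, 16, 7))), "even")
  expect_error(forward(m, array(1, c(16, 16, 2))), "even")
})

test_that("more than one temporal pooling stage is rejected", {
  expect_error(build_model(tiny_model_config(n_encoder = 2), quiet = TRUE),
               "exactly one")
  ## one pooling at 2 Hz analysis rate puts the internal Nyquist below the band
  expect_error(build_model(tiny_model_config(analysis_fps = 2), quiet = TRUE),
               "Nyquist")
})

test_that("evaluation is deterministic and rejects non-finite input", {
  m <- tiny_model()
  x <- array(rnorm(16 * 16 * 10), c(16, 16, 10))
  expect_identical(forward(m, x), forward(m, x))
  xbad <- x; xbad[3, 3, 3] <- NaN
  expect_error(forward(m, xbad), "non-finite")
  xinf <- x; xinf[1, 1, 1] <- Inf
  expect_error(forward(m, xinf), "non-finite")
})

test_that("a zeroed head produces an all-zero signal; batches stack rows", {
  m <- tiny_model()
  m$params$fc_w[] <- 0; m$params$fc_b <- 0
  x1 <- array(rnorm(16 * 16 * 10), c(16, 16, 10))
  x2 <- array(rnorm(16 * 16 * 10), c(16, 16, 10))
  y <- forward(m, list(x1, x2))
  expect_equal(dim(y), c(2, 10))
  expect_true(all(y == 0))
})

test_that("temporal reversal changes the output", {
  set.seed(8)
  m <- tiny_model()
  x <- array(rnorm(16 * 16 * 10), c(16, 16, 10))
  xr <- x[, , 10:1]
  y <- forward(m, x); yr <- forward(m, xr)
  expect_false(isTRUE(all.equal(as.numeric(y), rev(as.numeric(yr)))))
  expect_false(isTRUE(all.equal(as.numeric(y), as.numeric(yr))))

  ## the unidirectional variant also distinguishes the two orderings
  mu <- build_model(tiny_model_config(lstm_bidirectional = FALSE), quiet = TRUE)
  expect_false(isTRUE(all.equal(as.numeric(forward(mu, x)),
                                as.numeric(forward(mu, xr)))))
})

test_that("loss gradients reach every trainable tensor", {
  ns <- asNamespace("thermoresp")
  set.seed(12)
  m <- tiny_model()
  x <- array(rnorm(16 * 16 * 10), c(16, 16, 10))
  tgt <- resp_signal(sin(2 * pi * 0.25 * (0:9) / 5) + 0.1 * rnorm(10), 5)
  fwd <- ns$forward_one(m, x, keep_cache = TRUE)
  g <- ns$backward_one(m, fwd, ns$combined_loss_grad(fwd$y, tgt, loss_config()))$grads
  expect_setequal(names(g), names(m$params))
  for (nm in names(g))
    expect_gt(max(abs(g[[nm]])), 0)
})

test_that("backpropagation matches finite differences on every layer type", {
  ns <- asNamespace("thermoresp")
  set.seed(42)
  cfg <- loss_config()
  m <- build_model(tiny_model_config(seed = 3, spatial = 8), quiet = TRUE)
  x <- array(rnorm(8 * 8 * 10), c(8, 8, 10))
  tgt <- resp_signal(sin(2 * pi * 0.25 * (0:9) / 5) + 0.3 * rnorm(10), 5)
  fwd <- ns$forward_one(m, x, keep_cache = TRUE)
  g <- ns$backward_one(m, fwd, ns$combined_loss_grad(fwd$y, tgt, cfg))$grads
  lossfun <- function(mm) combined_loss(ns$forward_one(mm, x)$y, tgt, cfg)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      e <- 1e-5
      mp <- m; mp$params[[nm]][i] <- p[i] + e
      mm2 <- m; mm2$params[[nm]][i] <- p[i] - e
      num <- (lossfun(mp) - lossfun(mm2)) / (2 * e)
      expect_lt(abs(num - g[[nm]][i]) / max(1e-6, abs(num), abs(g[[nm]][i])),
                1e-3)
    }
  }
})

test_that("the internal temporal rate still covers the respiration band", {
  cfg <- model_config()
  internal_rate <- cfg$analysis_fps / 2^cfg$n_encoder
  expect_equal(internal_rate, 2.5)
  expect_gt(internal_rate / 2, cfg$band[2])   # 1.25 Hz Nyquist > 0.7 Hz
})
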