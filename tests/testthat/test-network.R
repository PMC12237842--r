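tiny_cfg <- function(input_dim = 30) {
  network_config(input_dim, hidden_dims = c(16, 8), latent_dim = 4,
                 dropout_rate = 0.1)
}

tiny_weights <- function(input_dim = 30, seed = 1) {
  set.seed(seed)
  init_weights(tiny_cfg(input_dim))
}

test_that("network_config enforces a decreasing funnel", {
  expect_error(network_config(10, c(512, 128), 10), "decrease strictly")
  expect_error(network_config(100, c(50, 60), 10), "decrease strictly")
  cfg <- network_config(100, c(50, 20), 10)
  expect_equal(cfg$latent_dim, 10)
})

test_that("encoding is deterministic in eval mode with the right shapes", {
  w <- tiny_weights()
  X <- matrix(rnorm(5 * 30), 5, 30)
  out1 <- encode_cells(X, w)
  out2 <- encode_cells(X, w)
  expect_identical(out1, out2)
  expect_equal(dim(out1$mu), c(5, 4))
  expect_equal(dim(out1$log_var), c(5, 4))
  # degenerate all-zero input still yields finite outputs
  z0 <- encode_cells(matrix(0, 1, 30), w)
  expect_true(all(is.finite(z0$mu)) && all(is.finite(z0$log_var)))
  expect_error(encode_cells(matrix(0, 2, 7), w), "expects")
})

test_that("default latent dimension is 10", {
  expect_equal(network_config(2000)$latent_dim, 10)
})

test_that("reparameterization follows z = mu + sigma * eps", {
  # eps = 0 returns the mean exactly
  out <- list(mu = matrix(c(1, 2), 1), log_var = matrix(0, 1, 2))
  expect_equal(reparameterize(out, epsilon = matrix(0, 1, 2)),
               matrix(c(1, 2), 1))
  # log_var = 2 ln 2 means sigma = 2
  out2 <- list(mu = matrix(0), log_var = matrix(2 * log(2)))
  expect_equal(reparameterize(out2, epsilon = matrix(1)), matrix(2))
  # Monte-Carlo moments: mean within 4 SE, variance within 5%
  mu <- 1.5; lv <- log(0.49)
  out3 <- list(mu = matrix(mu, 1e5, 1), log_var = matrix(lv, 1e5, 1))
  set.seed(11)
  z <- reparameterize(out3)
  se <- sqrt(exp(lv) / 1e5)
  expect_lt(abs(mean(z) - mu), 4 * se)
  expect_lt(abs(stats::var(as.vector(z)) - exp(lv)) / exp(lv), 0.05)
  # seeded draws reproduce
  expect_identical(reparameterize(out, seed = 5), reparameterize(out, seed = 5))
})

test_that("decoding maps latent codes back to input dimension", {
  w <- tiny_weights()
  H <- matrix(rnorm(6 * 4), 6, 4)
  xh <- decode_latent(H, w)
  expect_equal(dim(xh), c(6, 30))
  expect_true(all(is.finite(xh)))
  expect_error(decode_latent(matrix(0, 2, 3), w), "latent_dim")
  # encode -> mean -> decode is deterministic end to end
  X <- matrix(rnorm(4 * 30), 4, 30)
  r1 <- decode_latent(encode_cells(X, w)$mu, w)
  r2 <- decode_latent(encode_cells(X, w)$mu, w)
  expect_identical(r1, r2)
})

test_that("reconstruction loss equals the elementwise MSE oracle", {
  x <- matrix(c(0, 0), 1)
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(x, matrix(c(1, 1), 1)), 1)
  set.seed(2)
  a <- matrix(rnorm(30), 5, 6); b <- matrix(rnorm(30), 5, 6)
  loop <- 0
  for (i in 1:5) for (j in 1:6) loop <- loop + (a[i, j] - b[i, j])^2
  expect_equal(reconstruction_loss(a, b), loop / 30, tolerance = 1e-12)
})

test_that("standard-normal KL matches the closed form and quadrature", {
  z <- list(mu = matrix(0, 1, 3), log_var = matrix(0, 1, 3))
  expect_equal(kl_standard_normal(z), 0)
  one <- list(mu = matrix(1), log_var = matrix(0))
  expect_equal(kl_standard_normal(one), 0.5)
  # non-negativity on random inputs
  set.seed(4)
  for (i in 1:20) {
    e <- list(mu = matrix(rnorm(4), 2), log_var = matrix(rnorm(4), 2))
    expect_gte(kl_standard_normal(e), 0)
  }
  # 1-D cases against numerical integration
  for (case in list(c(0.7, log(2)), c(-1.2, log(0.3)), c(2, 0))) {
    e <- list(mu = matrix(case[1]), log_var = matrix(case[2]))
    expect_equal(kl_standard_normal(e),
                 kl_quadrature_1d(case[1], exp(case[2])), tolerance = 1e-6)
  }
})

test_that("pretraining reduces the loss and reproduces bit-identically", {
  set.seed(21)
  # rank-1 structure: easy to compress through the bottleneck
  u <- rnorm(60); v <- rnorm(30)
  X <- outer(u, v) + matrix(rnorm(1800, sd = 0.05), 60, 30)
  res <- pretrain_vae(X, tiny_cfg(),
                      train_config(epochs = 100, learning_rate = 3e-3,
                                   beta = 0), seed = 3)
  expect_lt(tail(res$loss_trace$loss, 1), res$loss_trace$loss[1])
  # trained reconstruction beats an untrained network by a wide margin
  untrained <- pretrain_vae(X, tiny_cfg(),
                            train_config(epochs = 0, beta = 0), seed = 3)
  rec_tr <- reconstruction_loss(
    X, decode_latent(encode_cells(X, res$weights)$mu, res$weights))
  rec_un <- reconstruction_loss(
    X, decode_latent(encode_cells(X, untrained$weights)$mu,
                     untrained$weights))
  expect_lt(rec_tr, rec_un / 3)
  # epochs = 0 returns the seeded initialization unchanged
  set.seed(3)
  w0 <- init_weights(tiny_cfg())
  expect_equal(untrained$weights, w0)
  expect_equal(nrow(untrained$loss_trace), 0)
  # reproducibility: identical traces on identical seeds
  res2 <- pretrain_vae(X, tiny_cfg(),
                       train_config(epochs = 100, learning_rate = 3e-3,
                                    beta = 0), seed = 3)
  expect_identical(res$loss_trace, res2$loss_trace)
  # the KL-regularized variant also trains
  resb <- pretrain_vae(X, tiny_cfg(), train_config(epochs = 20, beta = 1),
                       seed = 3)
  expect_lt(tail(resb$loss_trace$loss, 1), resb$loss_trace$loss[1])
})

test_that("leaky activation keeps negative-side gradients alive", {
  set.seed(31)
  cfg <- network_config(12, c(8, 6), 3, dropout_rate = 0,
                        activation = "leaky_relu")
  w <- init_weights(cfg)
  X <- matrix(rnorm(4 * 12), 4, 12)
  enc <- encode_cells(X, w)
  expect_true(all(is.finite(enc$mu)))
  # training still reduces the loss under the leaky variant
  res <- pretrain_vae(X, cfg, train_config(epochs = 30, beta = 0), seed = 2)
  expect_lt(tail(res$loss_trace$loss, 1), res$loss_trace$loss[1])
})

test_that("the decoder intercept stays frozen when disabled", {
  set.seed(32)
  cfg <- network_config(10, c(6, 4), 2, dropout_rate = 0,
                        decoder_bias = FALSE)
  X <- matrix(rnorm(20 * 10), 20, 10)
  res <- pretrain_vae(X, cfg, train_config(epochs = 5, beta = 0), seed = 2)
  expect_true(all(res$weights$dec_bout == 0))
  # and it trains when enabled
  cfg2 <- network_config(10, c(6, 4), 2, dropout_rate = 0)
  res2 <- pretrain_vae(X, cfg2, train_config(epochs = 5, beta = 0), seed = 2)
  expect_false(all(res2$weights$dec_bout == 0))
})

test_that("analytic gradients match finite differences", {
  # spot-check the hand-written backprop on a tiny instance
  set.seed(9)
  cfg <- network_config(6, c(5, 4), 2, dropout_rate = 0)
  w <- init_weights(cfg)
  X <- matrix(rnorm(3 * 6), 3, 6)
  eps_noise <- matrix(rnorm(3 * 2), 3, 2)
  loss_fn <- function(w) {
    enc <- vadeclust:::encoder_forward(w, X)
    z <- enc$mu + exp(enc$log_var / 2) * eps_noise
    dec <- vadeclust:::decoder_forward(w, z)
    mean((X - dec$xhat)^2) +
      mean(rowSums(-0.5 * (1 + enc$log_var - enc$mu^2 - exp(enc$log_var))))
  }
  enc <- vadeclust:::encoder_forward(w, X)
  z <- enc$mu + exp(enc$log_var / 2) * eps_noise
  dec <- vadeclust:::decoder_forward(w, z)
  n <- nrow(X)
  grads <- vadeclust:::vae_backward(
    w, enc, dec, eps_noise,
    d_xhat = 2 * (dec$xhat - X) / (n * ncol(X)),
    d_mu_extra = enc$mu / n,
    d_lv_extra = 0.5 * (exp(enc$log_var) - 1) / n)
  h <- 1e-6
  for (nm in c("enc_W1", "enc_b2", "W_mu", "W_lv", "dec_W1", "dec_bout")) {
    idx <- seq_len(min(5, length(w[[nm]])))
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
      fd <- (loss_fn(wp) - loss_fn(wm)) / (2 * h)
      expect_equal(grads[[nm]][i], fd, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("weight serialization round-trips bit-identically", {
  w <- tiny_weights(seed = 7)
  path <- tempfile(fileext = ".rds")
  save_weights(w, path)
  w2 <- load_weights(path)
  expect_identical(w, w2)
  X <- matrix(rnorm(3 * 30), 3, 30)
  expect_identical(encode_cells(X, w), encode_cells(X, w2))
  expect_identical(decode_latent(encode_cells(X, w)$mu, w),
                   decode_latent(encode_cells(X, w2)$mu, w2))
})
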