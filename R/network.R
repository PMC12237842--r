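#' Encoder/decoder architecture configuration
#'
#' The encoder is a stack of fully connected ReLU layers of sizes
#' `hidden_dims` (strictly decreasing from the input toward the latent
#' layer) followed by two linear heads producing the posterior mean and
#' log-variance of the `latent_dim`-dimensional latent code. The decoder
#' mirrors the encoder (`rev(hidden_dims)`) with a linear output layer.
#' Inverted dropout is applied to the encoder hidden activations during
#' training only.
#'
#' @param input_dim Number of input features (genes).
#' @param hidden_dims Encoder hidden layer widths, strictly decreasing.
#' @param latent_dim Latent embedding size (10 by default).
#' @param dropout_rate Encoder dropout probability in `[0, 1)`.
#' @param activation `"relu"` (default) or `"leaky_relu"` (slope 0.01 on
#'   the negative side; immune to permanently dead hidden units, which
#'   plain ReLU stacks can suffer on heavily corrupted inputs).
#' @param decoder_bias Keep the output-layer intercept trainable (the
#'   default). With the intercept frozen at zero the decoder cannot
#'   represent "predict the per-gene mean" without using the latent
#'   code, which prevents the latent from collapsing on hard (e.g.
#'   heavily corrupted) inputs; [vade_fit] falls back to this variant
#'   automatically when it detects a collapsed pretrain.
#' @return A `network_config` list.
#' @export
network_config <- function(input_dim, hidden_dims = c(512, 128),
                           latent_dim = 10, dropout_rate = 0.1,
                           activation = c("relu", "leaky_relu"),
                           decoder_bias = TRUE) {
  activation <- match.arg(activation)
  stopifnot(input_dim >= 1, latent_dim >= 1,
            all(hidden_dims >= 1),
            dropout_rate >= 0, dropout_rate < 1)
  dims <- c(input_dim, hidden_dims, latent_dim)
  if (any(diff(dims) >= 0))
    stop("hidden_dims must decrease strictly from input_dim (", input_dim,
         ") toward latent_dim (", latent_dim, "); got [",
         paste(hidden_dims, collapse = ", "), "]")
  structure(list(input_dim = input_dim, hidden_dims = hidden_dims,
                 latent_dim = latent_dim, dropout_rate = dropout_rate,
                 activation = activation,
                 decoder_bias = isTRUE(decoder_bias)),
            class = "network_config")
}

#' Optimization configuration
#'
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param beta Weight on the KL term during autoencoder pretraining
#'   (`beta = 0` gives a plain deterministic autoencoder; the latent code
#'   is then the posterior mean rather than a sample).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100, batch_size = 128,
                         learning_rate = 1e-3, beta = 1.0) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0, beta >= 0)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, beta = beta),
            class = "train_config")
}

# log-variance is clamped to this window in the encoder forward pass;
# gradients are zeroed where the clamp is active
LOGVAR_CLAMP <- 10

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

#' Initialize network weights
#'
#' He-initialized ReLU stacks for encoder and decoder; linear heads use
#' `sqrt(1/fan_in)` scaling. Draws from the current RNG state, so wrap in
#' `set.seed()` (or use [pretrain_vae]/[vade_fit], which seed for you) for
#' reproducibility.
#'
#' @param cfg A [network_config].
#' @return A `vade_weights` list of parameter matrices with the config
#'   attached as attribute `config`.
#' @export
init_weights <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  p <- list()
  dims <- c(cfg$input_dim, cfg$hidden_dims)
  for (l in seq_along(cfg$hidden_dims)) {
    p[[paste0("enc_W", l)]] <- he_init(dims[l], dims[l + 1])
    p[[paste0("enc_b", l)]] <- numeric(dims[l + 1])
  }
  last <- utils::tail(cfg$hidden_dims, 1)
  p$W_mu <- matrix(stats::rnorm(last * cfg$latent_dim, sd = sqrt(1 / last)),
                   last, cfg$latent_dim)
  p$b_mu <- numeric(cfg$latent_dim)
  # near-zero init keeps the initial posterior variance ~1 even when
  # pretraining never touches this head (plain-autoencoder phase)
  p$W_lv <- matrix(stats::rnorm(last * cfg$latent_dim, sd = 1e-4),
                   last, cfg$latent_dim)
  p$b_lv <- numeric(cfg$latent_dim)
  ddims <- c(cfg$latent_dim, rev(cfg$hidden_dims))
  for (l in seq_along(cfg$hidden_dims)) {
    p[[paste0("dec_W", l)]] <- he_init(ddims[l], ddims[l + 1])
    p[[paste0("dec_b", l)]] <- numeric(ddims[l + 1])
  }
  p$dec_Wout <- matrix(
    stats::rnorm(utils::tail(ddims, 1) * cfg$input_dim,
                 sd = sqrt(1 / utils::tail(ddims, 1))),
    utils::tail(ddims, 1), cfg$input_dim)
  p$dec_bout <- numeric(cfg$input_dim)
  structure(p, config = cfg, class = "vade_weights")
}

# column-major broadcast: one allocation, no sweep overhead
add_bias <- function(A, b) A + rep(b, each = nrow(A))

LEAKY_SLOPE <- 0.01

act_forward <- function(a, activation) {
  if (activation == "relu") pmax(a, 0)
  else ifelse(a > 0, a, LEAKY_SLOPE * a)
}

# derivative mask evaluated at the activation output (positive part is
# identity in both variants, negative part is 0 or the leak slope)
act_grad <- function(h, activation) {
  if (activation == "relu") (h > 0)
  else ifelse(h > 0, 1, LEAKY_SLOPE)
}

# Forward pass through the encoder; keeps activations for backprop.
# Dropout masks are drawn from the current RNG state when train_mode.
encoder_forward <- function(weights, X, train_mode = FALSE) {
  cfg <- attr(weights, "config")
  if (ncol(X) != cfg$input_dim)
    stop("input has ", ncol(X), " features but the network expects ",
         cfg$input_dim)
  h <- X
  acts <- list(); masks <- list()
  for (l in seq_along(cfg$hidden_dims)) {
    a <- add_bias(h %*% weights[[paste0("enc_W", l)]],
                  weights[[paste0("enc_b", l)]])
    h <- act_forward(a, cfg$activation)
    if (train_mode && cfg$dropout_rate > 0) {
      m <- matrix(stats::runif(length(h)) >= cfg$dropout_rate,
                  nrow(h), ncol(h)) / (1 - cfg$dropout_rate)
      h <- h * m
      masks[l] <- list(m)
    } else masks[l] <- list(NULL)
    acts[[l]] <- h
  }
  mu <- add_bias(h %*% weights$W_mu, weights$b_mu)
  lv_raw <- add_bias(h %*% weights$W_lv, weights$b_lv)
  lv <- pmin(pmax(lv_raw, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  list(mu = mu, log_var = lv,
       cache = list(X = X, acts = acts, masks = masks,
                    clamp_ok = abs(lv_raw) < LOGVAR_CLAMP))
}

decoder_forward <- function(weights, Z) {
  cfg <- attr(weights, "config")
  if (ncol(Z) != cfg$latent_dim)
    stop("latent input has ", ncol(Z), " columns but latent_dim is ",
         cfg$latent_dim)
  h <- Z
  acts <- list()
  for (l in seq_along(cfg$hidden_dims)) {
    a <- add_bias(h %*% weights[[paste0("dec_W", l)]],
                  weights[[paste0("dec_b", l)]])
    h <- act_forward(a, cfg$activation)
    acts[[l]] <- h
  }
  xhat <- add_bias(h %*% weights$dec_Wout, weights$dec_bout)
  list(xhat = xhat, cache = list(Z = Z, acts = acts))
}

#' Encode cells into posterior parameters
#'
#' Maps each row of a normalized expression matrix to the mean and
#' log-variance of its approximate Gaussian posterior over the latent
#' space. Deterministic when `train_mode` is off (dropout disabled).
#'
#' @param X Numeric matrix (cells x genes), e.g. a
#'   [normalize_counts] output.
#' @param weights A `vade_weights` object.
#' @param train_mode Enable dropout (training only).
#' @return List with `mu` and `log_var`, each cells x latent_dim.
#' @export
encode_cells <- function(X, weights, train_mode = FALSE) {
  out <- encoder_forward(weights, as.matrix(X), train_mode)
  list(mu = out$mu, log_var = out$log_var)
}

#' Sample latent codes with the reparameterization trick
#'
#' Computes `z = mu + exp(log_var / 2) * eps` with `eps ~ N(0, I)`, so the
#' sample is a deterministic function of the posterior parameters and the
#' noise, and gradients can flow through it.
#'
#' @param enc_out List with `mu` and `log_var` (see [encode_cells]).
#' @param epsilon Optional noise matrix of the same shape as `mu`; if
#'   missing, drawn standard-normal (seeded by `seed` when given).
#' @param seed Optional integer seed for the standard-normal draw.
#' @return Matrix of latent samples, same shape as `mu`.
#' @export
reparameterize <- function(enc_out, epsilon = NULL, seed = NULL) {
  mu <- enc_out$mu; lv <- enc_out$log_var
  stopifnot(all(dim(mu) == dim(lv)))
  if (is.null(epsilon)) {
    if (!is.null(seed)) set.seed(seed)
    epsilon <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  }
  stopifnot(all(dim(epsilon) == dim(mu)))
  mu + exp(lv / 2) * epsilon
}

#' Decode latent codes into reconstructed expression
#'
#' @param Z Matrix of latent codes (cells x latent_dim).
#' @param weights A `vade_weights` object.
#' @return Reconstruction matrix (cells x input_dim).
#' @export
decode_latent <- function(Z, weights) {
  decoder_forward(weights, as.matrix(Z))$xhat
}

#' Mean squared reconstruction error
#'
#' Averaged over all cells and genes; zero iff the reconstruction is exact.
#'
#' @param x Input matrix.
#' @param x_hat Reconstruction of the same shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(x, x_hat) {
  stopifnot(all(dim(x) == dim(x_hat)))
  mean((x - x_hat)^2)
}

#' KL divergence of the encoder posterior from a standard normal
#'
#' Closed form per cell, `-0.5 * sum_d(1 + log_var - mu^2 - exp(log_var))`,
#' averaged over cells; used as the regularizer during pretraining.
#'
#' @param enc_out List with `mu` and `log_var`.
#' @return Non-negative scalar.
#' @export
kl_standard_normal <- function(enc_out) {
  mu <- enc_out$mu; lv <- enc_out$log_var
  mean(rowSums(-0.5 * (1 + lv - mu^2 - exp(lv))))
}

# ---- Adam optimizer ---------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# The update runs in compiled code and mutates params and the moment
# estimates in place (they are owned exclusively by the training loop);
# bias corrections are folded into the step size.
adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  alpha <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  eps_t <- eps * sqrt(1 - beta2^state$t)
  adam_update_inplace(params, grads, state$m, state$v, alpha, eps_t,
                      beta1, beta2)
  list(params = params, state = state)
}

# ---- Backpropagation --------------------------------------------------

# Gradients of a scalar loss wrt all parameters, given upstream gradients
# d_xhat (through the decoder and the sampling path) and direct gradients
# d_mu_extra / d_lv_extra on the posterior parameters (KL terms).
vae_backward <- function(weights, enc, dec, eps_noise,
                         d_xhat, d_mu_extra = NULL, d_lv_extra = NULL,
                         sample_z = TRUE) {
  cfg <- attr(weights, "config")
  L <- length(cfg$hidden_dims)
  g <- list()

  if (!is.null(d_xhat)) {
    h_prev <- if (L >= 1) dec$cache$acts[[L]] else dec$cache$Z
    g$dec_Wout <- crossprod(h_prev, d_xhat)
    g$dec_bout <- colSums(d_xhat)
    dh <- tcrossprod(d_xhat, weights$dec_Wout)
    for (l in rev(seq_len(L))) {
      dh <- dh * act_grad(dec$cache$acts[[l]], cfg$activation)
      h_prev <- if (l > 1) dec$cache$acts[[l - 1]] else dec$cache$Z
      g[[paste0("dec_W", l)]] <- crossprod(h_prev, dh)
      g[[paste0("dec_b", l)]] <- colSums(dh)
      dh <- tcrossprod(dh, weights[[paste0("dec_W", l)]])
    }
    dz <- dh
  } else {
    dz <- NULL
  }

  d_mu <- if (is.null(d_mu_extra)) 0 else d_mu_extra
  d_lv <- if (is.null(d_lv_extra)) 0 else d_lv_extra
  if (!is.null(dz)) {
    d_mu <- d_mu + dz
    if (sample_z)
      d_lv <- d_lv + dz * eps_noise * 0.5 * exp(enc$log_var / 2)
  }
  if (is.matrix(d_lv)) d_lv <- d_lv * enc$cache$clamp_ok
  if (!is.matrix(d_mu)) d_mu <- matrix(0, nrow(enc$mu), ncol(enc$mu))
  if (!is.matrix(d_lv)) d_lv <- matrix(0, nrow(enc$mu), ncol(enc$mu))

  h_last <- if (L >= 1) enc$cache$acts[[L]] else enc$cache$X
  g$W_mu <- crossprod(h_last, d_mu)
  g$b_mu <- colSums(d_mu)
  g$W_lv <- crossprod(h_last, d_lv)
  g$b_lv <- colSums(d_lv)
  dh <- tcrossprod(d_mu, weights$W_mu) + tcrossprod(d_lv, weights$W_lv)
  for (l in rev(seq_len(L))) {
    if (!is.null(enc$cache$masks[[l]])) dh <- dh * enc$cache$masks[[l]]
    dh <- dh * act_grad(enc$cache$acts[[l]], cfg$activation)
    h_prev <- if (l > 1) enc$cache$acts[[l - 1]] else enc$cache$X
    g[[paste0("enc_W", l)]] <- crossprod(h_prev, dh)
    g[[paste0("enc_b", l)]] <- colSums(dh)
    dh <- tcrossprod(dh, weights[[paste0("enc_W", l)]])
  }
  g
}

#' Pretrain the autoencoder
#'
#' Minimizes `reconstruction_loss + beta * kl_standard_normal` by
#' minibatch Adam for `train_cfg$epochs` passes, starting from
#' seed-determined He initialization. With `beta = 0` the latent code is
#' the posterior mean (plain autoencoder); otherwise the latent code is
#' sampled via [reparameterize]. Fully reproducible given `seed`.
#'
#' @param X Numeric matrix (cells x genes) of normalized expression.
#' @param cfg A [network_config]; if `NULL`, built from `ncol(X)` with
#'   defaults.
#' @param train_cfg A [train_config].
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and sampling noise.
#' @param verbose Print per-epoch losses.
#' @return List with `weights` (a `vade_weights`) and `loss_trace`
#'   (data.frame epoch/loss/reconstruction/kl).
#' @export
pretrain_vae <- function(X, cfg = NULL, train_cfg = train_config(),
                         seed = 1L, verbose = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("X is empty")
  if (is.null(cfg)) cfg <- network_config(input_dim = ncol(X))
  set.seed(seed)
  weights <- init_weights(cfg)
  opt <- adam_state(weights)
  n <- nrow(X)
  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      reconstruction = numeric(0), kl = numeric(0))
  beta <- train_cfg$beta
  for (epoch in seq_len(train_cfg$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = train_cfg$batch_size)
    ep_loss <- ep_rec <- ep_kl <- 0
    for (s in starts) {
      rows <- idx[s:min(s + train_cfg$batch_size - 1, n)]
      xb <- X[rows, , drop = FALSE]
      nb <- length(rows)
      enc <- encoder_forward(weights, xb, train_mode = TRUE)
      if (beta > 0) {
        eps_noise <- matrix(stats::rnorm(nb * cfg$latent_dim), nb)
        z <- enc$mu + exp(enc$log_var / 2) * eps_noise
      } else {
        eps_noise <- NULL
        z <- enc$mu
      }
      dec <- decoder_forward(weights, z)
      rec <- mean((xb - dec$xhat)^2)
      kl <- mean(rowSums(-0.5 * (1 + enc$log_var - enc$mu^2 -
                                   exp(enc$log_var))))
      loss <- rec + beta * kl
      if (!is.finite(loss))
        stop("non-finite pretraining loss at epoch ", epoch,
             "; try a smaller learning rate or rescale the input")
      d_xhat <- 2 * (dec$xhat - xb) / (nb * ncol(X))
      d_mu_extra <- if (beta > 0) beta * enc$mu / nb else NULL
      d_lv_extra <- if (beta > 0) beta * 0.5 * (exp(enc$log_var) - 1) / nb
                    else NULL
      grads <- vae_backward(weights, enc, dec, eps_noise, d_xhat,
                            d_mu_extra, d_lv_extra, sample_z = beta > 0)
      if (!cfg$decoder_bias) grads$dec_bout <- NULL
      upd <- adam_update(weights, grads, opt, train_cfg$learning_rate)
      attrs <- attributes(weights)
      weights <- upd$params
      attributes(weights) <- attrs
      opt <- upd$state
      w <- nb / n
      ep_loss <- ep_loss + loss * w
      ep_rec <- ep_rec + rec * w
      ep_kl <- ep_kl + kl * w
    }
    trace <- rbind(trace, data.frame(epoch = epoch, loss = ep_loss,
                                     reconstruction = ep_rec, kl = ep_kl))
    if (verbose)
      message(sprintf("pretrain epoch %d: loss %.5f (rec %.5f, kl %.5f)",
                      epoch, ep_loss, ep_rec, ep_kl))
  }
  list(weights = weights, loss_trace = trace)
}

#' Save or load model weights
#'
#' Round-trips are bit-identical, including the attached
#' [network_config].
#'
#' @param weights A `vade_weights` object.
#' @param path Checkpoint file path.
#' @return `save_weights` returns `path` invisibly; `load_weights` returns
#'   the `vade_weights`.
#' @export
save_weights <- function(weights, path) {
  stopifnot(inherits(weights, "vade_weights"))
  saveRDS(weights, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  w <- readRDS(path)
  stopifnot(inherits(w, "vade_weights"))
  w
}
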