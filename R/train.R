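# Per-cell, per-component Gaussian KL between the encoder posterior
# N(mu_i, diag exp(lv_i)) and component k's N(m_k, diag s2_k):
# 0.5 * sum_d [log s2 - lv + (exp(lv) + (mu - m)^2) / s2 - 1]
gauss_kl_matrix <- function(mu, lv, params) {
  n <- nrow(mu)
  out <- matrix(0, n, params$K)
  ev <- exp(lv)
  for (k in seq_len(params$K)) {
    m <- params$means[k, ]; s2 <- params$vars[k, ]
    dd <- sweep(mu, 2, m, `-`)^2
    out[, k] <- 0.5 * rowSums(
      sweep(-lv, 2, log(s2), `+`) +
        sweep(ev + dd, 2, s2, `/`) - 1)
  }
  out
}

#' Joint clustering loss (negative mixture ELBO)
#'
#' Decomposes the negative evidence lower bound of the Gaussian-mixture
#' latent model into three reported parts: the reconstruction error of the
#' provided decode, the responsibility-weighted Gaussian KL between the
#' encoder posterior and the mixture components, and the categorical KL
#' between the responsibilities and the mixture weights. Responsibilities
#' `q(k | x)` are evaluated at the posterior mean for stability. With a
#' single standard-normal component the value reduces exactly to
#' `reconstruction_loss + kl_standard_normal`.
#'
#' @param x Input batch (cells x genes).
#' @param enc_out List with `mu`, `log_var` from [encode_cells].
#' @param z Latent sample used for the decode (unused by the closed-form
#'   KL terms; accepted for bookkeeping).
#' @param x_hat Reconstruction of `x`.
#' @param params A [gmm_params].
#' @return List of class `loss_breakdown`: `total`, `reconstruction`,
#'   `kl_gmm`, `entropy_q`, plus the responsibilities `gamma`.
#' @export
clustering_loss <- function(x, enc_out, z, x_hat, params) {
  mu <- enc_out$mu; lv <- enc_out$log_var
  stopifnot(all(dim(x) == dim(x_hat)), all(dim(mu) == dim(lv)))
  gamma <- cluster_posterior(mu, params)
  rec <- reconstruction_loss(x, x_hat)
  klmat <- gauss_kl_matrix(mu, lv, params)
  kl_gmm <- mean(rowSums(gamma * klmat))
  lg <- ifelse(gamma > 0, log(gamma), 0)
  ent <- mean(rowSums(gamma * sweep(lg, 2, log(params$pi), `-`)))
  total <- rec + kl_gmm + ent
  if (!is.finite(total)) stop("non-finite clustering loss")
  structure(list(total = total, reconstruction = rec, kl_gmm = kl_gmm,
                 entropy_q = ent, gamma = gamma),
            class = "loss_breakdown")
}

#' Fit the deep mixture clustering model
#'
#' Full pipeline: (1) plain-autoencoder pretraining of the encoder/decoder
#' (reconstruction only); (2) k-means initialization of the mixture on the
#' pretrained posterior means (or BIC selection of K when `K = "auto"`);
#' (3) joint optimization of the negative mixture ELBO by minibatch Adam
#' on the network — and on the mixture parameters in `gmm_mode =
#' "gradient"` — with a periodic full-data EM refresh of the mixture.
#' During optimization the reconstruction error is weighted by the number
#' of genes, i.e. the Gaussian log-likelihood is summed over genes per
#' cell, keeping it commensurate with the per-cell KL terms.
#'
#' @param X Normalized expression matrix (cells x genes).
#' @param K Number of clusters, or `"auto"` for BIC selection over
#'   `k_range`.
#' @param cfg A [network_config] (default built from `ncol(X)`).
#' @param train_cfg A [train_config] for the clustering phase.
#' @param pretrain_cfg A [train_config] for pretraining (its `beta` is
#'   ignored; pretraining is a plain autoencoder).
#' @param k_range Candidate K values when `K = "auto"`.
#' @param gmm_mode `"gradient"`: mixture parameters get Adam updates each
#'   batch plus an EM refresh every `em_refresh_every` epochs;
#'   `"em"`: mixture parameters are only updated by the EM refresh.
#' @param em_refresh_every Epoch period of the full-data EM refresh.
#' @param sample_latent Sample `z` via [reparameterize] for the decoder
#'   (default); if `FALSE` the posterior mean is decoded.
#' @param early_stop_tol Stop when the fraction of cells changing hard
#'   assignment between epochs falls below this; `NULL` disables.
#' @param max_restarts Pretraining retries (bias-free decoder, shifted
#'   seed) when the latent collapses to a constant; 0 disables.
#' @param seed Integer seed; every stochastic step derives from it.
#' @param verbose Print progress.
#' @return A `vade_fit` list: `weights`, `gmm` ([gmm_params]),
#'   `posterior` (n x K), `labels` (hard assignments), `latent` (posterior
#'   means), `K`, `loss_trace` (clustering phase), `pretrain_trace`,
#'   `seed`.
#' @export
vade_fit <- function(X, K, cfg = NULL,
                     train_cfg = train_config(epochs = 100),
                     pretrain_cfg = train_config(epochs = 100),
                     k_range = 2:10,
                     gmm_mode = c("gradient", "em"),
                     em_refresh_every = 5,
                     sample_latent = TRUE,
                     early_stop_tol = 0.001,
                     max_restarts = 2L,
                     seed = 1L, verbose = FALSE) {
  gmm_mode <- match.arg(gmm_mode)
  X <- as.matrix(X)
  n <- nrow(X); D <- ncol(X)
  if (n == 0) stop("X is empty")
  if (is.null(cfg)) cfg <- network_config(input_dim = D)

  pre_cfg <- train_config(epochs = pretrain_cfg$epochs,
                          batch_size = pretrain_cfg$batch_size,
                          learning_rate = pretrain_cfg$learning_rate,
                          beta = 0)
  pre <- pretrain_vae(X, cfg, pre_cfg, seed = seed, verbose = verbose)
  weights <- pre$weights
  mu_full <- encoder_forward(weights, X, train_mode = FALSE)$mu

  # a collapsed pretrain leaves the latent means (near-)constant across
  # cells; retry with the decoder intercept frozen at zero, which makes
  # the all-dead solution unrepresentable
  attempt <- 0L
  while (mean(apply(mu_full, 2, stats::sd)) < 0.01 &&
         attempt < max_restarts) {
    attempt <- attempt + 1L
    if (verbose || attempt == 1L)
      message("vade_fit: latent collapsed during pretraining; ",
              "retrying with bias-free decoder (attempt ", attempt, ")")
    cfg <- network_config(cfg$input_dim, cfg$hidden_dims, cfg$latent_dim,
                          cfg$dropout_rate, cfg$activation,
                          decoder_bias = FALSE)
    pre <- pretrain_vae(X, cfg, pre_cfg, seed = seed + 101L * attempt,
                        verbose = verbose)
    weights <- pre$weights
    mu_full <- encoder_forward(weights, X, train_mode = FALSE)$mu
  }
  # start the posterior spread at ~10% of the embedding spread so the
  # Gaussian KL terms see structure rather than one overlapping blob
  spread <- mean(apply(mu_full, 2, stats::sd))
  if (is.finite(spread) && spread > 0)
    weights$b_lv <- rep(2 * log(0.1 * spread), cfg$latent_dim)

  if (identical(K, "auto")) {
    sel <- select_k(mu_full, k_range, seed = seed + 1L)
    K <- sel$K
    if (verbose) message("select_k chose K = ", K)
  }
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  params <- kmeans_init(mu_full, K, seed = seed + 2L)

  opt <- adam_state(weights)
  gpar <- list(u = log(params$pi), m = params$means,
               t = log(params$vars))
  gopt <- adam_state(gpar)

  set.seed(seed + 3L)
  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      reconstruction = numeric(0), kl_gmm = numeric(0),
                      entropy_q = numeric(0))
  prev_labels <- NULL
  for (epoch in seq_len(train_cfg$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = train_cfg$batch_size)
    ep <- c(loss = 0, rec = 0, kl = 0, ent = 0)
    for (s in starts) {
      rows <- idx[s:min(s + train_cfg$batch_size - 1, n)]
      xb <- X[rows, , drop = FALSE]
      nb <- length(rows)
      enc <- encoder_forward(weights, xb, train_mode = TRUE)
      if (sample_latent) {
        eps_noise <- matrix(stats::rnorm(nb * cfg$latent_dim), nb)
        z <- enc$mu + exp(enc$log_var / 2) * eps_noise
      } else {
        eps_noise <- NULL
        z <- enc$mu
      }
      dec <- decoder_forward(weights, z)

      gamma <- cluster_posterior(enc$mu, params)   # treated as constant
      ev <- exp(enc$log_var)
      inv_s2 <- 1 / params$vars                    # K x p
      A <- gamma %*% inv_s2                        # n x p
      B <- gamma %*% (params$means * inv_s2)

      rec <- mean((xb - dec$xhat)^2)
      klmat <- gauss_kl_matrix(enc$mu, enc$log_var, params)
      kl_gmm <- mean(rowSums(gamma * klmat))
      lg <- ifelse(gamma > 0, log(gamma), 0)
      ent <- mean(rowSums(gamma * sweep(lg, 2, log(params$pi), `-`)))
      loss <- D * rec + kl_gmm + ent
      if (!is.finite(loss))
        stop("non-finite clustering loss at epoch ", epoch)

      # gene-summed Gaussian likelihood: d/dxhat of D * rec
      d_xhat <- 2 * (dec$xhat - xb) / nb
      d_mu_extra <- (enc$mu * A - B) / nb
      d_lv_extra <- 0.5 * (ev * A - 1) / nb
      grads <- vae_backward(weights, enc, dec, eps_noise, d_xhat,
                            d_mu_extra, d_lv_extra,
                            sample_z = sample_latent)
      if (!cfg$decoder_bias) grads$dec_bout <- NULL
      upd <- adam_update(weights, grads, opt, train_cfg$learning_rate)
      attrs <- attributes(weights)
      weights <- upd$params
      attributes(weights) <- attrs
      opt <- upd$state

      if (gmm_mode == "gradient") {
        gbar <- colMeans(gamma)
        dd_m <- matrix(0, K, cfg$latent_dim)
        dd_t <- matrix(0, K, cfg$latent_dim)
        for (k in seq_len(K)) {
          gk <- gamma[, k]
          diff <- sweep(enc$mu, 2, params$means[k, ], `-`)
          dd_m[k, ] <- -colSums(gk * diff) / (nb * params$vars[k, ])
          dd_t[k, ] <- 0.5 * colSums(
            gk * (1 - sweep(ev + diff^2, 2, params$vars[k, ], `/`))) / nb
        }
        gg <- list(u = params$pi - gbar, m = dd_m, t = dd_t)
        gupd <- adam_update(gpar, gg, gopt, train_cfg$learning_rate)
        gpar <- gupd$params
        gopt <- gupd$state
        gpar$t <- pmax(gpar$t, log(VAR_FLOOR))
        params <- gmm_params(exp(gpar$u - max(gpar$u)) /
                               sum(exp(gpar$u - max(gpar$u))),
                             gpar$m, exp(gpar$t))
      }

      w <- nb / n
      ep <- ep + w * c(loss, rec, kl_gmm, ent)
    }
    trace <- rbind(trace, data.frame(epoch = epoch, loss = ep[["loss"]],
                                     reconstruction = ep[["rec"]],
                                     kl_gmm = ep[["kl"]],
                                     entropy_q = ep[["ent"]]))
    if (verbose)
      message(sprintf("cluster epoch %d: loss %.4f", epoch, ep[["loss"]]))

    refresh <- epoch %% em_refresh_every == 0
    need_labels <- !is.null(early_stop_tol) || refresh
    if (need_labels) {
      mu_full <- encoder_forward(weights, X, train_mode = FALSE)$mu
      if (refresh) {
        params <- fit_gmm_em(mu_full, params, max_iter = 10)$params
        gpar <- list(u = log(params$pi), m = params$means,
                     t = log(params$vars))
        gopt <- adam_state(gpar)
      }
      if (!is.null(early_stop_tol)) {
        labels <- max.col(cluster_posterior(mu_full, params), ties.method = "first")
        if (!is.null(prev_labels) &&
            mean(labels != prev_labels) < early_stop_tol) {
          if (verbose) message("early stop at epoch ", epoch)
          prev_labels <- labels
          break
        }
        prev_labels <- labels
      }
    }
  }

  mu_full <- encoder_forward(weights, X, train_mode = FALSE)$mu
  posterior <- cluster_posterior(mu_full, params)
  labels <- max.col(posterior, ties.method = "first")
  rownames(mu_full) <- rownames(X)
  structure(list(weights = weights, gmm = params, posterior = posterior,
                 labels = labels, latent = mu_full, K = K,
                 loss_trace = trace, pretrain_trace = pre$loss_trace,
                 seed = seed),
            class = "vade_fit")
}

#' @export
print.vade_fit <- function(x, ...) {
  cat("vade_fit:", nrow(x$latent), "cells,", x$K, "clusters;",
      "cluster sizes:", paste(tabulate(x$labels, x$K), collapse = " "), "\n")
  invisible(x)
}
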