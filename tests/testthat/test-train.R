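test_that("clustering loss degenerates to VAE loss with one standard
           normal component", {
  set.seed(16)
  cfg <- network_config(20, c(12, 6), 3, dropout_rate = 0)
  w <- init_weights(cfg)
  p1 <- gmm_params(1, matrix(0, 1, 3), matrix(1, 1, 3))
  for (i in 1:50) {
    x <- matrix(rnorm(4 * 20), 4, 20)
    enc <- encode_cells(x, w)
    z <- reparameterize(enc, seed = i)
    xh <- decode_latent(z, w)
    lb <- clustering_loss(x, enc, z, xh, p1)
    expect_equal(lb$total,
                 reconstruction_loss(x, xh) + kl_standard_normal(enc),
                 tolerance = 1e-9)
    expect_equal(lb$entropy_q, 0, tolerance = 1e-12)
    # bookkeeping identity
    expect_equal(lb$total, lb$reconstruction + lb$kl_gmm + lb$entropy_q,
                 tolerance = 1e-9)
  }
})

test_that("clustering loss KL terms match numerical quadrature", {
  # one cell, one latent dimension, two components
  pk <- gmm_params(c(0.35, 0.65), matrix(c(-1, 2), 2, 1),
                   matrix(c(0.8, 1.7), 2, 1))
  mu <- 0.4; lv <- log(0.6)
  enc <- list(mu = matrix(mu), log_var = matrix(lv))
  x <- matrix(c(1, 2), 1)
  xh <- matrix(c(0.5, 1.5), 1)
  lb <- clustering_loss(x, enc, matrix(mu), xh, pk)
  gamma <- as.vector(cluster_posterior(matrix(mu), pk))
  # E_q[log q(h)] via the Gaussian entropy, E_q[log N(h; m_k, s2_k)] by
  # quadrature; their gamma-weighted difference is the Gaussian KL part
  neg_entropy <- -0.5 * (1 + log(2 * pi) + lv)
  kl_quad <- sum(vapply(1:2, function(k) {
    gamma[k] * (neg_entropy -
                  expect_log_gauss_quad(mu, exp(lv), pk$means[k, 1],
                                        pk$vars[k, 1]))
  }, numeric(1)))
  cat_kl <- sum(gamma * log(gamma / pk$pi))
  expect_equal(lb$kl_gmm, kl_quad, tolerance = 1e-4)
  expect_equal(lb$entropy_q, cat_kl, tolerance = 1e-9)
  expect_equal(lb$total, reconstruction_loss(x, xh) + kl_quad + cat_kl,
               tolerance = 1e-4)
})

test_that("the full fit recovers clusters on a small simulated dataset", {
  sim <- fixture_small()
  f <- filter_cells_genes(sim$counts, filter_config(10, 3))
  X <- normalize_counts(f$counts)
  keep <- !(rownames(sim$counts) %in% f$report$removed_cells)
  cfg <- network_config(ncol(X), c(64, 24), 8)
  fit <- vade_fit(X, K = 3, cfg = cfg,
                  train_cfg = train_config(epochs = 15),
                  pretrain_cfg = train_config(epochs = 200,
                                              learning_rate = 3e-3),
                  seed = 2)
  expect_equal(fit$K, 3)
  expect_equal(dim(fit$posterior), c(nrow(X), 3))
  expect_equal(rowSums(fit$posterior), rep(1, nrow(X)), tolerance = 1e-9)
  expect_gt(ari(sim$labels[keep], fit$labels), 0.8)
  # relabeling the predicted clusters cannot change agreement scores
  perm <- c(3, 1, 2)
  expect_equal(ari(sim$labels[keep], perm[fit$labels]),
               ari(sim$labels[keep], fit$labels), tolerance = 1e-12)
  expect_equal(nmi(sim$labels[keep], perm[fit$labels]),
               nmi(sim$labels[keep], fit$labels), tolerance = 1e-12)
  # the traced loss decreases after smoothing (early stop may shorten
  # the trace below the window; any non-trivial trace must not rise)
  w <- min(5, nrow(fit$loss_trace))
  sm <- stats::filter(fit$loss_trace$loss, rep(1 / w, w), sides = 1)
  sm <- sm[!is.na(sm)]
  if (length(sm) > 1) expect_lt(tail(sm, 1), sm[1] + 1e-6)
})

test_that("K = 1 assigns every cell to a single cluster", {
  sim <- fixture_small()
  X <- normalize_counts(sim$counts)
  cfg <- network_config(ncol(X), c(32, 16), 4)
  fit <- vade_fit(X, K = 1, cfg = cfg,
                  train_cfg = train_config(epochs = 2),
                  pretrain_cfg = train_config(epochs = 2), seed = 1)
  expect_true(all(fit$labels == 1))
  expect_true(all(fit$posterior == 1))
})

test_that("identical seeds give identical fits", {
  sim <- fixture_small()
  X <- normalize_counts(sim$counts)
  cfg <- network_config(ncol(X), c(32, 16), 4)
  args <- list(X = X, K = 3, cfg = cfg,
               train_cfg = train_config(epochs = 3),
               pretrain_cfg = train_config(epochs = 3), seed = 9)
  f1 <- do.call(vade_fit, args)
  f2 <- do.call(vade_fit, args)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$latent, f2$latent)
})

test_that("latent mixture means recovered by EM align with a planted
           mixture decoded linearly", {
  # GMM structure in a 2-D latent pushed through a random linear map to
  # 40 observed dims; EM on the true latent coordinates recovers the
  # mixture, and the end-to-end fit recovers the partition itself
  set.seed(18)
  truth_means <- matrix(c(-4, 0, 4, 0, 0, 6), 3, 2, byrow = TRUE)
  z <- rep(1:3, each = 100)
  H <- truth_means[z, ] + matrix(rnorm(600, sd = 0.4), 300, 2)
  em <- fit_gmm_em(H, kmeans_init(H, 3, seed = 1))
  align <- best_mean_alignment(em$params$means, truth_means)
  expect_lt(max(abs(em$params$means[align, ] - truth_means)), 0.15)

  A <- matrix(rnorm(2 * 40, sd = 0.5), 2, 40)
  X <- H %*% A + matrix(rnorm(300 * 40, sd = 0.1), 300, 40)
  cfg <- network_config(40, c(24, 12), 2, dropout_rate = 0)
  fit <- vade_fit(X, K = 3, cfg = cfg,
                  train_cfg = train_config(epochs = 10),
                  pretrain_cfg = train_config(epochs = 40,
                                              learning_rate = 3e-3),
                  seed = 4)
  expect_gt(ari(z, fit$labels), 0.95)
})
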