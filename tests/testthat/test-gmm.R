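test_that("mixture density matches direct per-component evaluation", {
  # single standard normal at the origin
  p1 <- gmm_params(1, matrix(0, 1, 1), matrix(1, 1, 1))
  expect_equal(gmm_density(0, p1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  # two identical components collapse to one
  p2 <- gmm_params(c(0.5, 0.5), matrix(0, 2, 1), matrix(1, 2, 1))
  expect_equal(gmm_density(0.3, p2), gmm_density(0.3, p1), tolerance = 1e-12)
  # 2-D, distinct parameters vs hand loop
  set.seed(6)
  pi_k <- c(0.3, 0.7)
  means <- matrix(rnorm(4), 2, 2)
  vars <- matrix(rexp(4) + 0.2, 2, 2)
  pk <- gmm_params(pi_k, means, vars)
  for (i in 1:10) {
    h <- rnorm(2)
    expect_equal(gmm_density(h, pk),
                 gmm_density_loop_oracle(h, pi_k, means, vars),
                 tolerance = 1e-12)
  }
  expect_error(gmm_density(c(NA, 1), pk), "non-finite")
})

test_that("mixture density integrates to one on a 1-D grid", {
  pk <- gmm_params(c(0.4, 0.6), matrix(c(-2, 3), 2, 1),
                   matrix(c(0.5, 2), 2, 1))
  grid <- seq(-15, 20, by = 0.001)
  expect_equal(sum(gmm_density(matrix(grid), pk)) * 0.001, 1,
               tolerance = 1e-4)
})

test_that("k-means initialization recovers separated structure", {
  set.seed(5)
  H <- matrix(c(rnorm(50, 0, 1e-4), rnorm(50, 10, 1e-4)), ncol = 1)
  init <- kmeans_init(H, 2, seed = 1)
  expect_equal(unname(sort(init$means[, 1])), c(0, 10), tolerance = 1e-3)
  expect_equal(init$pi, c(0.5, 0.5), tolerance = 1e-6)
  # K = 1: mean of the data, occupancy 1
  i1 <- kmeans_init(H, 1, seed = 1)
  expect_equal(i1$means[1, 1], mean(H))
  expect_equal(i1$pi, 1)
  expect_equal(sum(kmeans_init(H, 3, seed = 1)$pi), 1, tolerance = 1e-12)
  expect_error(kmeans_init(H, 200, seed = 1), "exceeds")
})

test_that("EM is a fixed point at the truth and monotone in likelihood", {
  # data exactly at the means with tight variances: parameters stay put
  H <- matrix(rep(c(0, 10), each = 40), ncol = 1)
  pk <- gmm_params(c(0.5, 0.5), matrix(c(0, 10), 2, 1),
                   matrix(1e-4, 2, 1))
  stepped <- em_step(H, pk)$params
  expect_equal(stepped$means, pk$means, tolerance = 1e-9)
  expect_equal(stepped$pi, pk$pi, tolerance = 1e-9)

  # monotone log-likelihood on 50 random small instances
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(20:120, 1); p <- sample(1:3, 1); K <- sample(1:3, 1)
    H <- matrix(rnorm(n * p, sd = 2), n, p)
    params <- kmeans_init(H, K, seed = rep)
    prev <- -Inf
    for (it in 1:15) {
      s <- em_step(H, params)
      expect_gte(s$loglik, prev - 1e-8)
      prev <- s$loglik
      params <- s$params
    }
  }
})

test_that("EM recovers parameters of a separated 3-component mixture", {
  set.seed(31)
  n <- 3000
  truth_means <- matrix(c(0, 0, 5, 5, -5, 5), 3, 2, byrow = TRUE)
  z <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  H <- truth_means[z, ] + matrix(rnorm(2 * n), n, 2)
  params <- kmeans_init(H, 3, seed = 1)
  for (i in 1:50) params <- em_step(H, params)$params
  align <- best_mean_alignment(params$means, truth_means)
  expect_lt(max(abs(params$means[align, ] - truth_means)), 0.1)
  expect_lt(max(abs(params$pi[align] - c(0.3, 0.4, 0.3))), 0.05)
  hard <- max.col(cluster_posterior(H, params))
  expect_gt(ari(z, hard), 0.99)
})

test_that("cluster posterior implements the Bayes ratio", {
  # symmetric components about the query point: equal responsibility
  pk <- gmm_params(c(0.5, 0.5), matrix(c(-1, 1), 2, 1), matrix(1, 2, 1))
  expect_equal(as.vector(cluster_posterior(0, pk)), c(0.5, 0.5))
  # K = 1: all ones
  p1 <- gmm_params(1, matrix(2, 1, 1), matrix(3, 1, 1))
  expect_equal(as.vector(cluster_posterior(rnorm(5), p1)), rep(1, 5))
  # hand-computed two-component Bayes ratio
  pk2 <- gmm_params(c(0.2, 0.8), matrix(c(0, 2), 2, 1),
                    matrix(c(1, 0.25), 2, 1))
  h <- 1.1
  w1 <- 0.2 * stats::dnorm(h, 0, 1)
  w2 <- 0.8 * stats::dnorm(h, 2, 0.5)
  expect_equal(as.vector(cluster_posterior(h, pk2)),
               c(w1, w2) / (w1 + w2), tolerance = 1e-9)
  # rows always sum to one, even far in the tails
  far <- matrix(seq(-50, 50, length.out = 7))
  expect_equal(rowSums(cluster_posterior(far, pk2)), rep(1, 7),
               tolerance = 1e-9)
})

test_that("BIC selects the generating component count on separable blobs", {
  set.seed(14)
  centers <- matrix(c(0, 0, 8, 0, 0, 8), 3, 2, byrow = TRUE)
  z <- rep(1:3, each = 80)
  H <- centers[z, ] + matrix(rnorm(480, sd = 0.7), 240, 2)
  sel <- select_k(H, 1:8, seed = 2)
  expect_equal(sel$K, 3)
  expect_equal(nrow(sel$table), 8)
  # singleton range returns its element
  expect_equal(select_k(H, 1, seed = 2)$K, 1)
  expect_error(select_k(H, integer(0)), "empty")
})

test_that("independent mixture fitter agrees on the easy case", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(15)
  H <- rbind(matrix(rnorm(200, 0, 0.5), 100, 2),
             matrix(rnorm(200, 6, 0.5), 100, 2))
  ours <- fit_gmm_em(H, kmeans_init(H, 2, seed = 1))
  mc <- mclust::Mclust(H, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(ours$loglik, mc$loglik, tolerance = 0.01)
})
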