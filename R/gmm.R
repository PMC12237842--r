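# floor applied to every diagonal variance to prevent component collapse
VAR_FLOOR <- 1e-6

#' Diagonal-covariance Gaussian mixture parameters
#'
#' @param pi Mixture weights, positive, summing to 1.
#' @param means K x p matrix of component means.
#' @param vars K x p matrix of positive diagonal variances (floored at
#'   1e-6).
#' @return A `gmm_params` list.
#' @export
gmm_params <- function(pi, means, vars) {
  means <- as.matrix(means); vars <- as.matrix(vars)
  K <- length(pi)
  stopifnot(K >= 1, nrow(means) == K, all(dim(vars) == dim(means)),
            all(pi > 0), abs(sum(pi) - 1) < 1e-8)
  vars <- pmax(vars, VAR_FLOOR)
  structure(list(K = K, pi = as.numeric(pi / sum(pi)),
                 means = means, vars = vars),
            class = "gmm_params")
}

#' @export
print.gmm_params <- function(x, ...) {
  cat("gmm_params:", x$K, "components in", ncol(x$means), "dimensions;",
      "weights", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

# coerce vector input to a latent matrix: a length-p vector is one
# point; with 1-D components any vector is a column of points
as_latent_matrix <- function(H, params) {
  if (is.null(dim(H))) {
    p <- ncol(params$means)
    H <- if (length(H) == p) matrix(H, nrow = 1) else matrix(H, ncol = 1)
  }
  H
}

# n x K matrix of log(pi_k) + log N(h_i; mu_k, diag(vars_k))
gmm_log_weighted_dens <- function(H, params) {
  H <- as.matrix(H)
  if (ncol(H) != ncol(params$means))
    stop("latent matrix has ", ncol(H), " columns but the mixture has ",
         ncol(params$means), " dimensions")
  p <- ncol(H)
  out <- matrix(0, nrow(H), params$K)
  for (k in seq_len(params$K)) {
    d2 <- sweep(H, 2, params$means[k, ], `-`)^2
    out[, k] <- log(params$pi[k]) -
      0.5 * (p * log(2 * pi) + sum(log(params$vars[k, ]))) -
      0.5 * rowSums(sweep(d2, 2, params$vars[k, ], `/`))
  }
  out
}

row_logsumexp <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Gaussian mixture density
#'
#' Evaluates `sum_k pi_k * N(h; mu_k, diag(Sigma_k))` for each row of `H`,
#' computed in log space for numerical stability.
#'
#' @param H Matrix (or vector, taken as one point) of latent coordinates.
#' @param params A [gmm_params].
#' @param log Return the log-density.
#' @return Numeric vector of (log-)densities, one per row of `H`.
#' @export
gmm_density <- function(H, params, log = FALSE) {
  H <- as_latent_matrix(H, params)
  if (anyNA(H) || any(!is.finite(H))) stop("H contains non-finite values")
  ld <- row_logsumexp(gmm_log_weighted_dens(H, params))
  if (log) ld else exp(ld)
}

#' Initialize mixture parameters by k-means
#'
#' Component means are k-means centroids (k-means++-style multi-start via
#' `nstart`), weights are cluster occupancy fractions, and variances are
#' within-cluster per-dimension variances, floored.
#'
#' @param H Latent matrix (cells x p).
#' @param K Number of components.
#' @param seed Integer seed.
#' @param nstart Number of k-means restarts.
#' @return A [gmm_params].
#' @export
kmeans_init <- function(H, K, seed = 1L, nstart = 50) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (K > n) stop("K (", K, ") exceeds the number of cells (", n, ")")
  set.seed(seed)
  if (K == 1) {
    cl <- list(cluster = rep(1L, n), centers = matrix(colMeans(H), 1))
  } else {
    cl <- stats::kmeans(H, centers = K, nstart = nstart, iter.max = 100)
  }
  pi <- tabulate(cl$cluster, K) / n
  if (any(pi == 0)) stop("k-means produced an empty cluster; lower K")
  vars <- matrix(VAR_FLOOR, K, ncol(H))
  for (k in seq_len(K)) {
    rows <- H[cl$cluster == k, , drop = FALSE]
    if (nrow(rows) > 1)
      vars[k, ] <- pmax(apply(rows, 2, stats::var) * (nrow(rows) - 1) /
                          nrow(rows), VAR_FLOOR)
  }
  gmm_params(pi, cl$centers, vars)
}

#' One EM step for the diagonal GMM
#'
#' E-step computes responsibilities (the cluster posterior); M-step
#' re-estimates weights, means, and floored diagonal variances. The data
#' log-likelihood is non-decreasing across steps (up to variance
#' flooring). A component whose total responsibility falls below 1e-8 is
#' re-seeded at the lowest-density point.
#'
#' @param H Latent matrix.
#' @param params Current [gmm_params].
#' @return List with `params` (updated) and `loglik` (log-likelihood of
#'   `H` under the incoming parameters).
#' @export
em_step <- function(H, params) {
  H <- as.matrix(H)
  n <- nrow(H)
  lwd <- gmm_log_weighted_dens(H, params)
  lse <- row_logsumexp(lwd)
  loglik <- sum(lse)
  gamma <- exp(lwd - lse)
  Nk <- colSums(gamma)
  dead <- which(Nk < 1e-8)
  if (length(dead)) {
    worst <- order(lse)[seq_along(dead)]
    for (j in seq_along(dead)) {
      k <- dead[j]
      gamma[, k] <- 0
      gamma[worst[j], ] <- 0
      gamma[worst[j], k] <- 1
    }
    gamma <- gamma / rowSums(gamma)
    Nk <- colSums(gamma)
    message("em_step: re-initialized ", length(dead),
            " collapsed component(s) from low-density points")
  }
  pi <- Nk / n
  means <- crossprod(gamma, H) / Nk
  ex2 <- crossprod(gamma, H^2) / Nk
  vars <- pmax(ex2 - means^2, VAR_FLOOR)
  list(params = gmm_params(pi, means, vars), loglik = loglik)
}

#' Run EM to convergence
#'
#' @param H Latent matrix.
#' @param params Initial [gmm_params] (e.g. from [kmeans_init]).
#' @param max_iter Maximum EM iterations.
#' @param tol Stop when the log-likelihood gain drops below `tol`.
#' @return List with `params`, `loglik` (final), and `loglik_trace`.
#' @export
fit_gmm_em <- function(H, params, max_iter = 100, tol = 1e-6) {
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    step <- em_step(H, params)
    params <- step$params
    trace <- c(trace, step$loglik)
    if (it > 1 && trace[it] - trace[it - 1] < tol) break
  }
  final <- sum(row_logsumexp(gmm_log_weighted_dens(H, params)))
  list(params = params, loglik = final, loglik_trace = trace)
}

#' Cluster membership posterior
#'
#' Bayes responsibilities `p(k | h) = pi_k N(h; mu_k, Sigma_k) / sum_k'
#' ...`, computed as a row softmax of log-weighted densities so rows sum
#' to one even for extreme values.
#'
#' @param H Latent matrix.
#' @param params A [gmm_params].
#' @return n x K row-stochastic matrix.
#' @export
cluster_posterior <- function(H, params) {
  H <- as_latent_matrix(H, params)
  lwd <- gmm_log_weighted_dens(H, params)
  exp(lwd - row_logsumexp(lwd))
}

#' Select the number of components by BIC
#'
#' Fits a diagonal GMM by k-means-initialized EM for every K in `k_range`
#' and returns the BIC-minimizing K. When true labels are available the
#' number of distinct labels should be used instead.
#'
#' @param H Latent matrix.
#' @param k_range Integer vector of candidate K.
#' @param seed Integer seed.
#' @param max_iter EM iteration cap per candidate.
#' @return List with `K` (selected) and `table` (data.frame K, loglik,
#'   n_params, bic).
#' @export
select_k <- function(H, k_range = 1:10, seed = 1L, max_iter = 100) {
  H <- as.matrix(H)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop("k_range is empty")
  if (any(k_range < 1) || any(k_range > nrow(H)))
    stop("k_range must lie within [1, n_cells]")
  n <- nrow(H); p <- ncol(H)
  rows <- lapply(k_range, function(K) {
    fit <- fit_gmm_em(H, kmeans_init(H, K, seed = seed + K),
                      max_iter = max_iter)
    npar <- (K - 1) + 2 * K * p
    data.frame(K = K, loglik = fit$loglik, n_params = npar,
               bic = -2 * fit$loglik + npar * log(n))
  })
  tab <- do.call(rbind, rows)
  list(K = tab$K[which.min(tab$bic)], table = tab)
}
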