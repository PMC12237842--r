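# Independent oracles used to cross-check the package's metric and model
# code. These deliberately use different routes than the implementation:
# explicit pair enumeration, first-principles entropy sums, and numerical
# quadrature.

# Adjusted Rand index by explicit enumeration of all C(n,2) item pairs,
# using the pair-confusion formulation (never touches the contingency
# formula the package implements).
ari_pair_oracle <- function(true, pred) {
  n <- length(true)
  ut <- upper.tri(matrix(0L, n, n))
  st <- outer(true, true, `==`)[ut]
  sp <- outer(pred, pred, `==`)[ut]
  n11 <- sum(st & sp)
  n10 <- sum(st & !sp)
  n01 <- sum(!st & sp)
  n00 <- sum(!st & !sp)
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  num / den
}

# NMI from first principles in base-2 logs (the package uses natural
# logs; the ratio is base-invariant).
nmi_entropy_oracle <- function(true, pred) {
  n <- length(true)
  pt <- table(true) / n
  pp <- table(pred) / n
  h <- function(p) -sum(ifelse(p > 0, p * log2(p), 0))
  joint <- table(true, pred) / n
  mi <- 0
  for (a in rownames(joint)) for (b in colnames(joint)) {
    pab <- joint[a, b]
    if (pab > 0) mi <- mi + pab * log2(pab / (pt[[a]] * pp[[b]]))
  }
  if (h(pt) + h(pp) == 0) return(1)
  2 * mi / (h(pt) + h(pp))
}

# All set partitions of n items as restricted-growth label vectors.
all_partitions <- function(n) {
  grow <- function(prefix, m) {
    if (length(prefix) == n) return(list(prefix))
    out <- list()
    for (v in seq_len(m + 1))
      out <- c(out, grow(c(prefix, v), max(m, v)))
    out
  }
  do.call(rbind, grow(integer(0), 0L))
}

# KL(N(mu, sigma2) || N(0, 1)) in one dimension by numerical integration.
kl_quadrature_1d <- function(mu, sigma2) {
  f <- function(x) {
    q <- stats::dnorm(x, mu, sqrt(sigma2))
    ifelse(q > 0, q * (stats::dnorm(x, mu, sqrt(sigma2), log = TRUE) -
                         stats::dnorm(x, log = TRUE)), 0)
  }
  stats::integrate(f, mu - 12 * sqrt(sigma2), mu + 12 * sqrt(sigma2),
                   rel.tol = 1e-10)$value
}

# E_{h ~ N(mu, sigma2)}[log N(h; m, s2)] by quadrature (for the mixture
# ELBO check).
expect_log_gauss_quad <- function(mu, sigma2, m, s2) {
  f <- function(x) stats::dnorm(x, mu, sqrt(sigma2)) *
    stats::dnorm(x, m, sqrt(s2), log = TRUE)
  stats::integrate(f, mu - 12 * sqrt(sigma2), mu + 12 * sqrt(sigma2),
                   rel.tol = 1e-10)$value
}

# brute-force mixture density: plain loop over components, no log-space
gmm_density_loop_oracle <- function(h, pi, means, vars) {
  total <- 0
  for (k in seq_along(pi)) {
    dens <- 1
    for (d in seq_along(h))
      dens <- dens * stats::dnorm(h[d], means[k, d], sqrt(vars[k, d]))
    total <- total + pi[k] * dens
  }
  total
}

# align estimated component means to true means over all permutations
# (small K), returning the permutation minimizing total distance
best_mean_alignment <- function(est, truth) {
  K <- nrow(truth)
  perms <- if (K == 1) matrix(1) else {
    p <- expand.grid(rep(list(seq_len(K)), K))
    p <- p[apply(p, 1, function(r) length(unique(r)) == K), , drop = FALSE]
    as.matrix(p)
  }
  best <- NULL; best_d <- Inf
  for (i in seq_len(nrow(perms))) {
    d <- sum(sqrt(rowSums((est[perms[i, ], , drop = FALSE] - truth)^2)))
    if (d < best_d) { best_d <- d; best <- perms[i, ] }
  }
  best
}
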