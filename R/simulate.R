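#' Specification for the group-structured count simulator
#'
#' Parameterizes a gamma-Poisson (negative binomial) generative hierarchy
#' in the style of established scRNA-seq simulators: gene base means are
#' gamma, a fraction of genes per group receives multiplicative log-normal
#' differential-expression factors, cell library sizes are log-normal, and
#' counts are negative binomial with a shared dispersion, optionally
#' zero-inflated with a logistic-in-log-mean dropout probability.
#'
#' Defaults emulate plant protoplast droplet data, which are denser than
#' typical mammalian sets: with the default library size the expected zero
#' fraction is roughly 0.6-0.8.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param n_groups Number of cell groups (clusters).
#' @param group_probs Group membership probabilities (defaults to uniform).
#' @param mean_shape,mean_rate Gamma parameters of gene base means.
#' @param libsize_mu,libsize_sigma Meanlog/sdlog of the log-normal cell
#'   library sizes.
#' @param de_prob Fraction of genes differentially expressed in each group.
#' @param de_facloc,de_facscale Meanlog/sdlog of the log-normal DE factors
#'   (`de_facloc = log(4)` makes DE genes ~4x their base mean).
#' @param dispersion Negative-binomial dispersion (NB size = 1/dispersion).
#' @param dropout_mid,dropout_shape Logistic zero-inflation parameters, or
#'   `NULL` (default) for none: an entry with cell x gene mean m is forced
#'   to zero with probability `plogis(dropout_shape * (dropout_mid -
#'   log(m)))`, so low-mean entries drop out more often.
#' @param seed Integer RNG seed; the full draw is reproducible from it.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_cells = 2000, n_genes = 2000, n_groups = 5,
                            group_probs = NULL,
                            mean_shape = 0.6, mean_rate = 0.3,
                            libsize_mu = log(1500), libsize_sigma = 0.25,
                            de_prob = 0.3, de_facloc = log(4),
                            de_facscale = 0.2,
                            dispersion = 0.5,
                            dropout_mid = NULL, dropout_shape = 1,
                            seed = 1L) {
  if (is.null(group_probs)) group_probs <- rep(1 / n_groups, n_groups)
  stopifnot(n_cells >= 1, n_genes >= 1, n_groups >= 1,
            length(group_probs) == n_groups,
            abs(sum(group_probs) - 1) < 1e-8,
            mean_shape > 0, mean_rate > 0, libsize_sigma >= 0,
            de_prob >= 0, de_prob <= 1, de_facscale >= 0, dispersion > 0)
  structure(list(n_cells = n_cells, n_genes = n_genes, n_groups = n_groups,
                 group_probs = group_probs, mean_shape = mean_shape,
                 mean_rate = mean_rate, libsize_mu = libsize_mu,
                 libsize_sigma = libsize_sigma, de_prob = de_prob,
                 de_facloc = de_facloc, de_facscale = de_facscale,
                 dispersion = dispersion, dropout_mid = dropout_mid,
                 dropout_shape = dropout_shape, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate group-structured scRNA-seq counts
#'
#' Draws a cells x genes count matrix and per-cell group labels from the
#' hierarchy described in [simulation_spec]. The per-cell expected counts
#' are the group's gene-mean profile rescaled to the cell's library size,
#' so library-size variation is independent of group identity.
#'
#' @param spec A [simulation_spec].
#' @return List with `counts` (a [count_matrix]), `labels` (integer group
#'   per cell), and `spec`.
#' @export
simulate_counts <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes; n <- spec$n_cells; K <- spec$n_groups

  base_mean <- stats::rgamma(G, shape = spec$mean_shape, rate = spec$mean_rate)
  # group profiles: multiplicative log-normal factors on a de_prob subset
  group_mean <- matrix(rep(base_mean, K), nrow = K, byrow = TRUE)
  for (k in seq_len(K)) {
    de <- stats::runif(G) < spec$de_prob
    fac <- stats::rlnorm(sum(de), meanlog = spec$de_facloc,
                         sdlog = spec$de_facscale)
    group_mean[k, de] <- group_mean[k, de] * fac
  }
  labels <- sample.int(K, n, replace = TRUE, prob = spec$group_probs)
  libsize <- stats::rlnorm(n, meanlog = spec$libsize_mu,
                           sdlog = spec$libsize_sigma)

  profile <- group_mean / rowSums(group_mean)   # K x G, rows sum to 1
  mu <- profile[labels, , drop = FALSE] * libsize   # n x G expected counts
  counts <- matrix(stats::rnbinom(n * G, mu = mu, size = 1 / spec$dispersion),
                   nrow = n)
  if (!is.null(spec$dropout_mid)) {
    p_drop <- stats::plogis(spec$dropout_shape * (spec$dropout_mid - log(mu)))
    keep <- matrix(stats::runif(n * G) >= p_drop, nrow = n)
    counts <- counts * keep
  }
  rownames(counts) <- sprintf("cell%04d", seq_len(n))
  colnames(counts) <- sprintf("gene%04d", seq_len(G))
  list(counts = count_matrix(counts), labels = labels, spec = spec)
}

#' Additive-noise specification
#'
#' @param distribution One of `"uniform"`, `"gaussian"`, `"gamma"`,
#'   `"negative_binomial"`.
#' @param params Named list of distribution parameters: uniform `low`/`high`
#'   (default 0/2); gaussian `mean`/`sd` (0/1); gamma `shape`/`scale` (2/1);
#'   negative_binomial `r`/`p` (2/0.5).
#' @param seed Integer RNG seed.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(distribution = c("uniform", "gaussian", "gamma",
                                        "negative_binomial"),
                       params = list(), seed = 1L) {
  distribution <- match.arg(distribution)
  defaults <- switch(distribution,
    uniform = list(low = 0, high = 2),
    gaussian = list(mean = 0, sd = 1),
    gamma = list(shape = 2, scale = 1),
    negative_binomial = list(r = 2, p = 0.5))
  params <- utils::modifyList(defaults, params)
  ok <- switch(distribution,
    uniform = params$low <= params$high,
    gaussian = params$sd >= 0,
    gamma = params$shape > 0 && params$scale > 0,
    negative_binomial = params$r > 0 && params$p > 0 && params$p <= 1)
  if (!ok) stop("invalid parameters for ", distribution, " noise")
  structure(list(distribution = distribution, params = params,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add elementwise random noise to a count matrix
#'
#' Draws i.i.d. noise from the named distribution, adds it to every entry,
#' rounds to the nearest integer (half to even), and clamps negative
#' results to zero, so the output is again a valid count matrix.
#'
#' @param X A [count_matrix].
#' @param spec A [noise_spec].
#' @return A [count_matrix] of the same shape and ids.
#' @export
add_noise <- function(X, spec) {
  stopifnot(inherits(X, "count_matrix"), inherits(spec, "noise_spec"))
  V <- unclass_matrix(X)
  n <- length(V)
  set.seed(spec$seed)
  p <- spec$params
  eps <- switch(spec$distribution,
    uniform = stats::runif(n, p$low, p$high),
    gaussian = stats::rnorm(n, p$mean, p$sd),
    gamma = stats::rgamma(n, shape = p$shape, scale = p$scale),
    negative_binomial = stats::rnbinom(n, size = p$r, prob = p$p))
  out <- round(V + eps)
  out[out < 0] <- 0
  count_matrix(out, rownames(V), colnames(V))
}

#' Dropout-corruption specification
#'
#' @param rate Fraction of entries to zero out, in `[0, 1]`.
#' @param scope `"nonzero_entries"` (default; only detected genes can be
#'   masked) or `"all_entries"` (Bernoulli mask over the whole matrix).
#' @param per_cell With the default scope, mask exactly
#'   `floor(rate * detected genes)` entries per cell rather than a global
#'   draw.
#' @param seed Integer RNG seed.
#' @return A `corruption_spec` list.
#' @export
corruption_spec <- function(rate, scope = c("nonzero_entries", "all_entries"),
                            per_cell = TRUE, seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(rate >= 0, rate <= 1)
  structure(list(rate = rate, scope = scope, per_cell = per_cell,
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Corrupt a count matrix by masking entries to zero
#'
#' Emulates aggravated technical dropout. Under the default per-cell
#' nonzero scope, each cell has exactly `floor(rate * detected)` of its
#' nonzero entries set to zero, chosen uniformly at random; a zero entry is
#' never altered. The returned mask marks zeroed positions.
#'
#' @param X A [count_matrix].
#' @param spec A [corruption_spec].
#' @return List with `counts` (corrupted [count_matrix]) and `mask`
#'   (logical matrix, `TRUE` where an entry was zeroed).
#' @export
corrupt_dropout <- function(X, spec) {
  stopifnot(inherits(X, "count_matrix"), inherits(spec, "corruption_spec"))
  V <- unclass_matrix(X)
  set.seed(spec$seed)
  mask <- matrix(FALSE, nrow(V), ncol(V), dimnames = dimnames(V))
  if (spec$scope == "nonzero_entries" && spec$per_cell) {
    for (i in seq_len(nrow(V))) {
      nz <- which(V[i, ] > 0)
      m <- floor(spec$rate * length(nz))
      if (m > 0) mask[i, nz[sample.int(length(nz), m)]] <- TRUE
    }
  } else if (spec$scope == "nonzero_entries") {
    nz <- which(V > 0)
    m <- floor(spec$rate * length(nz))
    if (m > 0) mask[nz[sample.int(length(nz), m)]] <- TRUE
  } else {
    mask[] <- stats::runif(length(V)) < spec$rate
  }
  V[mask] <- 0
  list(counts = count_matrix(V), mask = mask)
}
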