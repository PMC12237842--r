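# Shared fixtures for the heavier end-to-end tests. Built lazily and
# cached for the test session so the simulation and the deep fit are run
# once and reused by the clustering, robustness and feature-benchmark
# tests (which are defined on the same dataset).

.fixture_cache <- new.env(parent = emptyenv())

fixture_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- simulate_counts(simulation_spec(
      n_cells = 2000, n_genes = 2000, n_groups = 5,
      de_prob = 0.3, de_facloc = log(4), seed = 101L))
  }
  .fixture_cache$sim
}

# filtered + normalized view of the simulated data, with labels aligned
fixture_norm <- function() {
  if (is.null(.fixture_cache$norm)) {
    sim <- fixture_sim()
    f <- filter_cells_genes(sim$counts, filter_config())
    keep <- !(rownames(sim$counts) %in% f$report$removed_cells)
    .fixture_cache$norm <- list(X = normalize_counts(f$counts),
                                labels = sim$labels[keep])
  }
  .fixture_cache$norm
}

# the full-pipeline fit at the study scale (pretrain 30 / cluster 30)
fixture_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    d <- fixture_norm()
    .fixture_cache$fit <- vade_fit(
      d$X, K = 5,
      train_cfg = train_config(epochs = 30),
      pretrain_cfg = train_config(epochs = 30),
      seed = 7L)
  }
  .fixture_cache$fit
}

# a small, fast dataset for unit-scale pipeline tests
fixture_small <- function() {
  if (is.null(.fixture_cache$small)) {
    sim <- simulate_counts(simulation_spec(
      n_cells = 300, n_genes = 200, n_groups = 3,
      de_prob = 0.4, de_facloc = log(5), seed = 42L))
    .fixture_cache$small <- sim
  }
  .fixture_cache$small
}
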