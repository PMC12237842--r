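#' K-means clustering of an embedding
#'
#' Multi-start Lloyd's k-means (via `stats::kmeans`) on the rows of a
#' feature matrix; the usual baseline clusterer for latent or PCA
#' embeddings.
#'
#' @param H Feature matrix (cells x features).
#' @param K Number of clusters, `1 <= K <= n_cells`.
#' @param seed Integer seed.
#' @param nstart Restarts.
#' @return Integer vector of hard labels.
#' @export
kmeans_cluster <- function(H, K, seed = 1L, nstart = 50) {
  H <- as.matrix(H)
  if (K < 1 || K > nrow(H))
    stop("K must be between 1 and the number of cells")
  set.seed(seed)
  if (K == 1) return(rep(1L, nrow(H)))
  stats::kmeans(H, centers = K, nstart = nstart, iter.max = 100)$cluster
}

#' PCA embedding baseline
#'
#' Top principal-component scores of the centered matrix. Deterministic:
#' each component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param X Numeric matrix (cells x genes), typically normalized.
#' @param n_components Number of components (default 10, matching the
#'   latent dimension).
#' @return Scores matrix (cells x n_components).
#' @export
pca_baseline <- function(X, n_components = 10) {
  X <- as.matrix(X)
  if (n_components < 1 || n_components > min(dim(X)))
    stop("n_components must be in [1, min(n_cells, n_genes)]")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  sweep(pc$x, 2, flip, `*`)
}

#' Exact t-SNE embedding (export/QC)
#'
#' Small from-scratch implementation of exact (non-Barnes-Hut) t-SNE for
#' two-dimensional visualization export: Gaussian input affinities
#' calibrated per point to the target perplexity, Student-t output
#' affinities, gradient descent with momentum and early exaggeration.
#' Intended for modest cell counts (thousands); quadratic in n.
#'
#' @param M Feature matrix (cells x features); raw or embedded data.
#' @param perplexity Effective neighbor count; requires
#'   `n_cells > 3 * perplexity`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Gradient-descent iterations.
#' @return n_cells x 2 coordinate matrix.
#' @export
tsne_embed <- function(M, perplexity = 30, seed = 1L, max_iter = 300) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (n <= 3 * perplexity)
    stop("need n_cells > 3 * perplexity (n = ", n, ", perplexity = ",
         perplexity, ")")
  sq <- rowSums(M^2)
  D2 <- pmax(outer(sq, sq, `+`) - 2 * tcrossprod(M), 0)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        pj <- w / sw
        h <- -sum(ifelse(pj > 0, pj * log(pj), 0))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / max(sum(w), .Machine$double.xmin)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  warm <- ceiling(max_iter / 3)
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= warm) 4 else 1       # early exaggeration
    sqy <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(sqy, sqy, `+`) - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter <= warm) 0.5 else 0.8
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- mom * inc - 100 * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Configuration of the feature classification benchmark
#'
#' @param models Subset of `c("svm", "rfc", "xgboost", "glmnet")`.
#' @param cv_folds Cross-validation folds for the grid search (>= 2).
#' @param test_fraction Held-out fraction for the final metrics.
#' @param grid Named list of per-model hyperparameter data.frames; any
#'   entry overrides the built-in small default grid.
#' @param seed Integer seed (split, folds, model seeds).
#' @return An `mlbench_config` list.
#' @export
mlbench_config <- function(models = c("svm", "rfc", "xgboost", "glmnet"),
                           cv_folds = 5, test_fraction = 0.2,
                           grid = list(), seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(cv_folds >= 2, test_fraction > 0, test_fraction < 1)
  defaults <- list(
    svm = data.frame(cost = c(1, 10)),
    rfc = data.frame(nodesize = c(1, 5)),
    xgboost = data.frame(max_depth = c(3, 6)),
    glmnet = data.frame(lambda = c(1e-2, 1e-3)))
  grid <- utils::modifyList(defaults, grid)
  structure(list(models = models, cv_folds = cv_folds,
                 test_fraction = test_fraction, grid = grid,
                 seed = as.integer(seed)),
            class = "mlbench_config")
}

stratified_split <- function(y, fraction, seed) {
  set.seed(seed)
  test <- integer(0)
  for (c in unique(y)) {
    idx <- which(y == c)
    m <- max(1L, round(fraction * length(idx)))
    test <- c(test, idx[sample.int(length(idx), m)])
  }
  sort(test)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (c in unique(y)) {
    idx <- sample(which(y == c))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_predict_model <- function(model, hp, x_train, y_train, x_test, seed) {
  y_train <- factor(y_train)
  set.seed(seed)
  if (model == "svm") {
    fit <- e1071::svm(x_train, y_train, kernel = "radial", cost = hp$cost,
                      scale = FALSE)
    as.character(stats::predict(fit, x_test))
  } else if (model == "rfc") {
    fit <- randomForest::randomForest(x_train, y_train, ntree = 200,
                                      nodesize = hp$nodesize)
    as.character(stats::predict(fit, x_test))
  } else if (model == "xgboost") {
    fit <- xgboost::xgboost(x_train, y_train, max_depth = hp$max_depth,
                            learning_rate = 0.3, nrounds = 50,
                            nthreads = 1, verbosity = 0)
    prob <- stats::predict(fit, x_test)
    if (is.matrix(prob))
      colnames(prob)[max.col(prob, ties.method = "first")]
    else  # binary: probability of the second level
      levels(y_train)[(prob > 0.5) + 1L]
  } else if (model == "glmnet") {
    fit <- glmnet::glmnet(x_train, y_train, family = "multinomial",
                          alpha = 0, lambda = hp$lambda)
    as.character(stats::predict(fit, x_test, type = "class",
                                s = hp$lambda))
  } else stop("unknown model: ", model)
}

#' Benchmark classifiers on a feature representation
#'
#' Makes one stratified train/test split; per model, selects
#' hyperparameters from a small grid by stratified cross-validated
#' accuracy on the training portion; refits on the full training portion;
#' and reports macro-averaged accuracy/precision/recall/F1 (plus micro
#' accuracy) on the identical held-out test set for every model. Used to
#' compare the 10-dimensional latent representation against the raw
#' normalized features.
#'
#' @param features Feature matrix (cells x features).
#' @param labels Class label per cell (>= 2 classes; every class needs at
#'   least `cv_folds` members).
#' @param cfg An [mlbench_config].
#' @return List with `table` (data.frame model, cv_accuracy, accuracy,
#'   precision, recall, f1, overall_accuracy), `test_idx`, and
#'   `predictions` (named list of per-model test-set predictions).
#' @export
ml_feature_benchmark <- function(features, labels, cfg = mlbench_config()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  if (min(table(labels)) < cfg$cv_folds)
    stop("a class has fewer members than cv_folds; merge classes or ",
         "add data")
  test_idx <- stratified_split(labels, cfg$test_fraction, cfg$seed)
  train_idx <- setdiff(seq_along(labels), test_idx)
  x_tr <- features[train_idx, , drop = FALSE]
  y_tr <- labels[train_idx]
  x_te <- features[test_idx, , drop = FALSE]
  y_te <- labels[test_idx]
  fold <- stratified_folds(y_tr, cfg$cv_folds, cfg$seed + 1L)

  rows <- list(); preds <- list()
  for (model in cfg$models) {
    grid <- cfg$grid[[model]]
    cv_acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      accs <- numeric(cfg$cv_folds)
      for (f in seq_len(cfg$cv_folds)) {
        tr <- fold != f
        p <- fit_predict_model(model, grid[g, , drop = FALSE],
                               x_tr[tr, , drop = FALSE], y_tr[tr],
                               x_tr[!tr, , drop = FALSE],
                               seed = cfg$seed + 10L * g + f)
        accs[f] <- mean(p == y_tr[!tr])
      }
      cv_acc[g] <- mean(accs)
    }
    best <- which.max(cv_acc)
    p <- fit_predict_model(model, grid[best, , drop = FALSE],
                           x_tr, y_tr, x_te, seed = cfg$seed + 99L)
    m <- evaluate_predictions(y_te, p)
    preds[[model]] <- p
    rows[[model]] <- data.frame(
      model = model, cv_accuracy = cv_acc[best], accuracy = m$accuracy,
      precision = m$precision, recall = m$recall, f1 = m$f1,
      overall_accuracy = m$overall_accuracy)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       test_idx = test_idx, predictions = preds)
}

#' Clustering robustness under dropout corruption
#'
#' For each corruption rate and each of `n_replicates` corruption seeds:
#' zero out the prescribed fraction of detected entries per cell
#' ([corrupt_dropout]), drop genes left with no counts, renormalize, embed
#' and cluster with each method, and score ARI and NMI against the true
#' labels. Methods: `"vade"` (the deep mixture fit, its own assignments)
#' and `"pca"` (PCA scores + k-means).
#'
#' @param X Raw [count_matrix].
#' @param labels True group label per cell.
#' @param rates Corruption rates in `[0, 1]` (default 0.1-0.9).
#' @param methods Character subset of `c("vade", "pca")`.
#' @param K Number of clusters.
#' @param seed Integer seed; per-replicate corruption and fit seeds derive
#'   from it.
#' @param n_replicates Corruption masks averaged per rate.
#' @param vade_args List of extra arguments passed to [vade_fit]
#'   (e.g. reduced `train_cfg`/`pretrain_cfg`). Optional elements
#'   `hidden_dims`, `latent_dim` and `dropout_rate` configure the network,
#'   which is rebuilt per rate because corruption changes the number of
#'   retained genes.
#' @param pca_dims Components for the PCA baseline.
#' @return List of class `robustness_result`: `summary` (data.frame
#'   method, rate, ari, nmi averaged over replicates) and `replicates`
#'   (per-seed rows).
#' @export
robustness_curve <- function(X, labels, rates = seq(0.1, 0.9, by = 0.1),
                             methods = c("vade", "pca"), K,
                             seed = 1L, n_replicates = 3,
                             vade_args = list(), pca_dims = 10) {
  stopifnot(all(rates >= 0), all(rates <= 1))
  methods <- match.arg(methods, several.ok = TRUE)
  net <- vade_args[c("hidden_dims", "latent_dim", "dropout_rate")]
  net <- net[!vapply(net, is.null, logical(1))]
  vade_args <- vade_args[setdiff(names(vade_args),
                                 c("hidden_dims", "latent_dim",
                                   "dropout_rate"))]
  rows <- list()
  for (r in seq_along(rates)) {
    for (rep in seq_len(n_replicates)) {
      sub_seed <- seed + 1000L * rep + r
      cor <- corrupt_dropout(X, corruption_spec(rates[r], seed = sub_seed))
      V <- unclass_matrix(cor$counts)
      V <- V[, colSums(V) > 0, drop = FALSE]
      Xn <- normalize_counts(count_matrix(V))
      for (method in methods) {
        pred <- if (method == "vade") {
          cfg <- do.call(network_config,
                         c(list(input_dim = ncol(Xn)), net))
          args <- c(list(X = Xn, K = K, cfg = cfg, seed = sub_seed),
                    vade_args)
          do.call(vade_fit, args)$labels
        } else {
          kmeans_cluster(pca_baseline(Xn, pca_dims), K, seed = sub_seed)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, rate = rates[r], replicate = rep,
          ari = ari(labels, pred), nmi = nmi(labels, pred))
      }
    }
  }
  reps <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(ari, nmi) ~ method + rate, reps, mean)
  summary <- summary[order(summary$method, summary$rate), ]
  structure(list(summary = summary, replicates = reps),
            class = "robustness_result")
}
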