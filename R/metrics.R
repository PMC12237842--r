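#' Cross-tabulate predicted clusters against true labels
#'
#' @param labels_true,labels_pred Equal-length vectors of labels (any
#'   atomic type; tabulated over sorted unique values).
#' @return List of class `contingency_table`: `n_ij` (clusters x classes
#'   counts, predicted in rows), `a_i` row sums, `b_j` column sums, `n`
#'   grand total.
#' @export
cluster_contingency <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("label vectors differ in length (", length(labels_true), " vs ",
         length(labels_pred), ")")
  if (length(labels_true) < 1) stop("need at least one observation")
  tab <- table(pred = factor(labels_pred), true = factor(labels_true))
  n_ij <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                 dimnames = dimnames(tab))
  structure(list(n_ij = n_ij, a_i = rowSums(n_ij), b_j = colSums(n_ij),
                 n = sum(n_ij)),
            class = "contingency_table")
}

as_contingency <- function(t, p) {
  if (inherits(t, "contingency_table")) t else cluster_contingency(t, p)
}

choose2 <- function(x) x * (x - 1) / 2

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for the
#' agreement expected by chance under the permutation model. 1 for
#' identical partitions, ~0 for independent ones; negative values are
#' possible (worse than chance) and are returned as computed.
#'
#' @param labels_true True labels, or a [cluster_contingency] table.
#' @param labels_pred Predicted labels (ignored when a table is given).
#' @return Scalar in `[-1, 1]`.
#' @export
ari <- function(labels_true, labels_pred = NULL) {
  t <- as_contingency(labels_true, labels_pred)
  if (t$n < 2) stop("ARI requires at least two observations")
  sum_ij <- sum(choose2(t$n_ij))
  sum_a <- sum(choose2(t$a_i))
  sum_b <- sum(choose2(t$b_j))
  expected <- sum_a * sum_b / choose2(t$n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' `2 * I(true; pred) / (H(true) + H(pred))`, with `0 log 0 = 0`. The value
#' is independent of the logarithm base. When both partitions are constant
#' (zero entropy) the value is 1 if they induce the same single block,
#' else 0.
#'
#' @inheritParams ari
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(labels_true, labels_pred = NULL) {
  t <- as_contingency(labels_true, labels_pred)
  n <- t$n
  h_a <- -sum(ifelse(t$a_i > 0, t$a_i / n * log(t$a_i / n), 0))
  h_b <- -sum(ifelse(t$b_j > 0, t$b_j / n * log(t$b_j / n), 0))
  if (h_a + h_b == 0) return(1)  # both partitions constant -> identical
  outer_ab <- outer(t$a_i, t$b_j)
  mi_terms <- t$n_ij / n * log(ifelse(t$n_ij > 0,
                                      n * t$n_ij / outer_ab, 1))
  2 * sum(mi_terms) / (h_a + h_b)
}

#' Classification metrics from one-vs-rest counts
#'
#' Computes accuracy, recall, precision and F1 from true/false
#' positive/negative counts. For multiclass input (vectors of counts, one
#' per class) per-class values and their macro averages are returned.
#' Undefined precision/recall (zero denominator) is reported as 0 with
#' `undefined = TRUE`.
#'
#' @param TP,TN,FP,FN Non-negative integer count vectors (length = number
#'   of classes; scalars for binary).
#' @return List with per-class data.frame `per_class` and scalars
#'   `accuracy`, `recall`, `precision`, `f1` (macro averages), plus
#'   `undefined`.
#' @export
classification_metrics <- function(TP, TN, FP, FN) {
  counts <- cbind(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("counts must be non-negative")
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  acc <- safe_div(TP + TN, TP + TN + FP + FN)
  rec <- safe_div(TP, TP + FN)
  prec <- safe_div(TP, TP + FP)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  undefined <- any(TP + FN == 0) || any(TP + FP == 0)
  if (undefined)
    warning("precision or recall undefined for some class; reported as 0")
  list(per_class = data.frame(TP = TP, TN = TN, FP = FP, FN = FN,
                              accuracy = acc, recall = rec,
                              precision = prec, f1 = f1),
       accuracy = mean(acc), recall = mean(rec), precision = mean(prec),
       f1 = mean(f1), undefined = undefined)
}

#' Evaluate a multiclass prediction
#'
#' Convenience wrapper: builds one-vs-rest counts per class from label
#' vectors and returns [classification_metrics] macro averages, plus the
#' plain (micro) accuracy `mean(pred == true)`.
#'
#' @param labels_true,labels_pred Equal-length label vectors.
#' @return As [classification_metrics], with extra element
#'   `overall_accuracy`.
#' @export
evaluate_predictions <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("label vectors differ in length")
  classes <- sort(unique(as.character(labels_true)))
  lt <- as.character(labels_true); lp <- as.character(labels_pred)
  TP <- TN <- FP <- FN <- numeric(length(classes))
  for (j in seq_along(classes)) {
    c <- classes[j]
    TP[j] <- sum(lt == c & lp == c)
    FN[j] <- sum(lt == c & lp != c)
    FP[j] <- sum(lt != c & lp == c)
    TN[j] <- sum(lt != c & lp != c)
  }
  out <- classification_metrics(TP, TN, FP, FN)
  out$per_class$class <- classes
  out$overall_accuracy <- mean(lt == lp)
  out
}
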