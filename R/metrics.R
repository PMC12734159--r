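# Multi-class evaluation: confusion matrix, one-vs-rest precision/recall/F1
# with macro averaging, and ROC/AUC with micro-averaging. Class labels are
# integer indices 1..K throughout.

#' Confusion matrix
#'
#' `K x K` integer matrix with rows indexing the true class and columns the
#' predicted class; cell `(i, j)` counts items of true class `i` predicted
#' as class `j`. All one-vs-rest TP/FP/TN/FN reductions derive from it.
#'
#' @param y_true,y_pred equal-length integer vectors with values in `1..K`
#' @param n_classes K
#' @return `K x K` integer matrix
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length")
  }
  K <- as.integer(n_classes)
  if (length(y_true) > 0 &&
      (min(y_true, y_pred) < 1L || max(y_true, y_pred) > K)) {
    stop("labels must lie in 1..", K)
  }
  idx <- (as.integer(y_pred) - 1L) * K + as.integer(y_true)
  matrix(tabulate(idx, nbins = K * K), K, K)
}

#' Overall accuracy from a confusion matrix
#'
#' Correctly predicted fraction, `trace(cm) / sum(cm)`. For `K = 2` this is
#' the familiar `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cm confusion matrix
#' @return accuracy in `[0, 1]`
#' @export
cm_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' One-vs-rest precision and recall for one class
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`; both are 0 by
#' convention when the denominator is 0 (class never predicted / absent).
#'
#' @param cm confusion matrix
#' @param class_k class index in `1..K`
#' @return named numeric vector `c(precision, recall)`
#' @export
precision_recall <- function(cm, class_k) {
  k <- as.integer(class_k)
  stopifnot(k >= 1L, k <= nrow(cm))
  tp <- cm[k, k]
  fp <- sum(cm[, k]) - tp
  fn <- sum(cm[k, ]) - tp
  c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2PR / (P + R)`, and 0 when both
#' are 0. Vectorised.
#'
#' @param precision,recall values in `[0, 1]`
#' @return F1 values
#' @export
f1_score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s > 0, 2 * precision * recall / s, 0)
}

# Binary ROC by threshold sweep over descending scores (ties grouped),
# returning the curve and its trapezoid AUC. `labels` is logical.
binary_roc <- function(labels, scores) {
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0 || nn == 0) {
    return(list(fpr = NA_real_, tpr = NA_real_, auc = NA_real_))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  keep <- c(s[-length(s)] != s[-1], TRUE)  # last index of each tie group
  tpr <- c(0, cumsum(l)[keep] / np)
  fpr <- c(0, cumsum(!l)[keep] / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Per-class and micro-average ROC curves and AUCs
#'
#' Each class is scored one-vs-rest against its probability column; the
#' micro-average curve pools all (label, score) pairs across classes into a
#' single binary problem before the sweep. AUC is computed by the trapezoid
#' rule (equivalently, the rank statistic with ties counted half). Classes
#' absent from `y_true` get `NA` AUC rather than 0.
#'
#' @param y_true integer labels in `1..K`
#' @param scores `n x K` matrix of class probabilities (rows sum to 1)
#' @return list with `per_class` (list of curves), `auc` (named per-class
#'   vector), `micro` (pooled curve), and `micro_auc`
#' @export
roc_curves <- function(y_true, scores) {
  stopifnot(is.matrix(scores), length(y_true) == nrow(scores))
  K <- ncol(scores)
  per <- vector("list", K)
  aucs <- numeric(K)
  for (k in seq_len(K)) {
    per[[k]] <- binary_roc(y_true == k, scores[, k])
    aucs[k] <- per[[k]]$auc
  }
  onehot <- as.vector(vapply(seq_len(K), function(k) y_true == k,
                             logical(length(y_true))))
  micro <- binary_roc(onehot, as.vector(scores))
  names(aucs) <- colnames(scores)
  list(per_class = per, auc = aucs, micro = micro, micro_auc = micro$auc)
}

#' Full evaluation report
#'
#' Computes the confusion matrix, overall accuracy, per-class one-vs-rest
#' precision/recall/F1, their unweighted macro averages, and (when
#' probabilities are supplied) per-class and micro-average AUCs. Two macro
#' F1 conventions exist in the literature — the mean of per-class F1 values
#' and the harmonic mean of macro precision and macro recall — and both are
#' reported (`macro_f1` and `macro_f1_pr`).
#'
#' @param y_true,y_pred integer labels in `1..K`
#' @param n_classes K; defaults to the largest label seen
#' @param probs optional `n x K` probability matrix for ROC/AUC
#' @param class_names optional class names
#' @return a `metrics_report` list
#' @export
metrics_report <- function(y_true, y_pred, n_classes = max(y_true, y_pred),
                           probs = NULL, class_names = NULL) {
  K <- as.integer(n_classes)
  cm <- confusion_matrix(y_true, y_pred, K)
  pr <- t(vapply(seq_len(K), function(k) precision_recall(cm, k),
                 numeric(2)))
  f1 <- f1_score(pr[, "precision"], pr[, "recall"])
  if (is.null(class_names)) class_names <- paste0("class", seq_len(K))
  per_class <- data.frame(class = class_names,
                          precision = pr[, "precision"],
                          recall = pr[, "recall"],
                          f1 = f1,
                          support = rowSums(cm),
                          stringsAsFactors = FALSE)
  macro_p <- mean(pr[, "precision"])
  macro_r <- mean(pr[, "recall"])
  rep <- list(confusion = cm,
              accuracy = cm_accuracy(cm),
              per_class = per_class,
              macro_precision = macro_p,
              macro_recall = macro_r,
              macro_f1 = mean(f1),
              macro_f1_pr = f1_score(macro_p, macro_r))
  if (!is.null(probs)) {
    roc <- roc_curves(y_true, probs)
    rep$auc <- stats::setNames(roc$auc, class_names)
    rep$micro_auc <- roc$micro_auc
  }
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.4f\n", x$accuracy))
  pc <- x$per_class
  pc$precision <- round(pc$precision, 4)
  pc$recall <- round(pc$recall, 4)
  pc$f1 <- round(pc$f1, 4)
  print(pc, row.names = FALSE)
  cat(sprintf("Macro P/R/F1: %.4f / %.4f / %.4f (F1 of macro P,R: %.4f)\n",
              x$macro_precision, x$macro_recall, x$macro_f1, x$macro_f1_pr))
  if (!is.null(x$micro_auc)) {
    cat(sprintf("Per-class AUC: %s | micro-average AUC: %.4f\n",
                paste(sprintf("%.4f", x$auc), collapse = " "), x$micro_auc))
  }
  invisible(x)
}

#' Export ROC curve points as delimited text
#'
#' One row per (curve, threshold step): columns `curve` (class name or
#' `"micro"`), `fpr`, `tpr`. Curves for classes absent from the truth are
#' omitted.
#'
#' @param roc result of [roc_curves()]
#' @param path output TSV file
#' @param class_names optional class names for the per-class curves
#' @return `path`, invisibly
#' @export
write_roc_points <- function(roc, path, class_names = NULL) {
  K <- length(roc$per_class)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(K))
  rows <- list()
  for (k in seq_len(K)) {
    cv <- roc$per_class[[k]]
    if (length(cv$fpr) > 1 || !is.na(cv$fpr[1])) {
      rows[[length(rows) + 1L]] <- data.frame(curve = class_names[k],
                                              fpr = cv$fpr, tpr = cv$tpr)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(curve = "micro",
                                          fpr = roc$micro$fpr,
                                          tpr = roc$micro$tpr)
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' @param report a [metrics_report()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_metrics_report <- function(report, path) {
  out <- list(accuracy = report$accuracy,
              confusion = report$confusion,
              per_class = report$per_class,
              macro_precision = report$macro_precision,
              macro_recall = report$macro_recall,
              macro_f1 = report$macro_f1,
              macro_f1_pr = report$macro_f1_pr)
  if (!is.null(report$micro_auc)) {
    out$auc <- as.list(report$auc)
    out$micro_auc <- report$micro_auc
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
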