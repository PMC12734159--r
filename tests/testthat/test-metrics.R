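test_that("confusion matrix tallies by true row and predicted column", {
  y_true <- c(1, 1, 2, 2, 3, 3)
  y_pred <- c(1, 2, 2, 2, 1, 3)
  cm <- confusion_matrix(y_true, y_pred, 3)
  expect_equal(cm, matrix(c(1, 0, 1,
                            1, 2, 0,
                            0, 0, 1), 3, 3))
  expect_equal(sum(cm), 6)
  # perfect agreement is diagonal; empty input is the zero matrix
  expect_equal(confusion_matrix(1:4, 1:4, 4), diag(1L, 4), ignore_attr = TRUE)
  expect_equal(confusion_matrix(integer(0), integer(0), 3), matrix(0L, 3, 3))
  expect_error(confusion_matrix(c(0, 1), c(1, 1), 3), "1..3")
})

test_that("accuracy is trace over total, matching the binary form", {
  expect_equal(cm_accuracy(diag(5, 4)), 1.0)
  # TP=3, TN=5, FP=1, FN=1 -> 8/10
  cm <- matrix(c(3, 1, 1, 5), 2, 2, byrow = TRUE)
  expect_equal(cm_accuracy(cm), 0.8)
  off <- matrix(c(0, 2, 3, 0), 2, 2)
  expect_equal(cm_accuracy(off), 0)
  expect_error(cm_accuracy(matrix(0, 3, 3)), "empty")
})

test_that("accuracy equals the direct label-match fraction on random inputs", {
  set.seed(501)
  for (rep in 1:10) {
    n <- sample(5:40, 1); K <- sample(2:5, 1)
    yt <- sample(K, n, replace = TRUE)
    yp <- sample(K, n, replace = TRUE)
    expect_equal(cm_accuracy(confusion_matrix(yt, yp, K)), mean(yt == yp))
  }
})

test_that("one-vs-rest precision/recall and degenerate conventions", {
  cm <- confusion_matrix(c(1, 1, 2, 2, 3, 3), c(1, 2, 2, 2, 1, 3), 3)
  # class 1: TP=1, FP=1, FN=1
  expect_equal(precision_recall(cm, 1), c(precision = 0.5, recall = 0.5))
  # class 2: TP=2, FP=1, FN=0
  expect_equal(precision_recall(cm, 2), c(precision = 2 / 3, recall = 1))
  # diagonal: all ones
  d <- diag(3L, 4)
  for (k in 1:4) {
    expect_equal(precision_recall(d, k), c(precision = 1, recall = 1))
  }
  # never-predicted class has precision 0 by convention
  cm2 <- confusion_matrix(c(1, 2), c(1, 1), 2)
  expect_equal(unname(precision_recall(cm2, 2)), c(0, 0))
})

test_that("F1 reproduces the published per-class values to four decimals", {
  # precision/recall pairs as printed for the four-class MRI comparison;
  # the harmonic mean must give back the printed F1 at 4 d.p.
  rows <- list(
    list(p = 0.9330, r = 0.8889, f1 = 0.9104),  # VGG16, glioma
    list(p = 0.9483, r = 0.9053, f1 = 0.9263),  # ResNet18, glioma
    list(p = 0.9660, r = 0.9401, f1 = 0.9529),  # proposed, glioma
    list(p = 0.9905, r = 0.9905, f1 = 0.9905),  # proposed, pituitary
    list(p = 0.9803, r = 0.9933, f1 = 0.9868)   # proposed, normal
  )
  for (row in rows) {
    expect_equal(round(f1_score(row$p, row$r), 4), row$f1)
  }
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(c(0.5, 0), c(1, 0)), c(2 / 3, 0))
})

test_that("macro averages are unweighted means and both F1 conventions appear", {
  set.seed(502)
  yt <- sample(3, 60, replace = TRUE)
  yp <- sample(3, 60, replace = TRUE)
  rep <- metrics_report(yt, yp, n_classes = 3)
  expect_equal(rep$macro_precision, mean(rep$per_class$precision))
  expect_equal(rep$macro_recall, mean(rep$per_class$recall))
  expect_equal(rep$macro_f1, mean(rep$per_class$f1))
  expect_equal(rep$macro_f1_pr,
               f1_score(rep$macro_precision, rep$macro_recall))
  expect_equal(rep$accuracy, mean(yt == yp))
  expect_equal(rep$per_class$f1,
               f1_score(rep$per_class$precision, rep$per_class$recall))
})

test_that("ROC endpoints: perfect separation gives 1, label-free scores 0.5", {
  yt <- c(1, 1, 2, 2, 3, 3)
  perfect <- matrix(0.05, 6, 3)
  perfect[cbind(1:6, yt)] <- 0.9
  roc <- roc_curves(yt, perfect)
  expect_equal(unname(roc$auc), rep(1, 3))
  expect_equal(roc$micro_auc, 1)
  flat <- matrix(1 / 3, 6, 3)
  roc2 <- roc_curves(yt, flat)
  expect_equal(unname(roc2$auc), rep(0.5, 3))
  expect_equal(roc2$micro_auc, 0.5)
})

test_that("trapezoid AUC equals the rank-sum oracle on random instances", {
  set.seed(503)
  for (rep in 1:15) {
    n <- sample(8:30, 1); K <- sample(2:4, 1)
    yt <- sample(K, n, replace = TRUE)
    scores <- matrix(stats::runif(n * K), n, K)
    # quantise some scores to force ties
    scores[stats::runif(n * K) < 0.3] <- 0.5
    scores <- scores / rowSums(scores)
    roc <- roc_curves(yt, scores)
    for (k in seq_len(K)) {
      expect_equal(roc$auc[[k]], rank_sum_auc(yt == k, scores[, k]),
                   tolerance = 1e-12)
    }
    onehot <- as.vector(vapply(seq_len(K), function(k) yt == k,
                               logical(n)))
    expect_equal(roc$micro_auc, rank_sum_auc(onehot, as.vector(scores)),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(504)
  y <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  s <- stats::runif(40)
  ours <- stripfuse:::binary_roc(y, s)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, s,
                                                         direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("classes absent from the truth get NA AUC, not zero", {
  yt <- c(1, 1, 2)
  scores <- matrix(c(0.6, 0.7, 0.2,
                     0.3, 0.2, 0.7,
                     0.1, 0.1, 0.1), 3, 3)
  roc <- roc_curves(yt, scores)
  expect_true(is.na(roc$auc[[3]]))
  expect_false(is.na(roc$auc[[1]]))
})

test_that("reports serialise to JSON with per-class and aggregate fields", {
  set.seed(505)
  yt <- sample(4, 40, replace = TRUE)
  probs <- matrix(stats::runif(160), 40, 4)
  probs <- probs / rowSums(probs)
  yp <- max.col(probs)
  rep <- metrics_report(yt, yp, n_classes = 4, probs = probs,
                        class_names = c("glioma", "meningioma",
                                        "pituitary", "notumor"))
  path <- tempfile(fileext = ".json")
  write_metrics_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$accuracy, rep$accuracy)
  expect_equal(length(parsed$per_class), 4)
  expect_equal(parsed$micro_auc, rep$micro_auc, tolerance = 1e-12)
})

test_that("ROC curve points export with endpoints at (0,0) and (1,1)", {
  yt <- c(1, 1, 2, 2)
  scores <- matrix(c(0.9, 0.8, 0.3, 0.1,
                     0.1, 0.2, 0.7, 0.9), 4, 2)
  roc <- roc_curves(yt, scores)
  path <- tempfile(fileext = ".tsv")
  write_roc_points(roc, path, class_names = c("a", "b"))
  pts <- utils::read.delim(path)
  expect_setequal(unique(pts$curve), c("a", "b", "micro"))
  for (cv in split(pts, pts$curve)) {
    expect_equal(cv$fpr[1], 0)
    expect_equal(cv$tpr[1], 0)
    expect_equal(cv$fpr[nrow(cv)], 1)
    expect_equal(cv$tpr[nrow(cv)], 1)
  }
})
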