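make_manifest <- function(class_sizes) {
  rows <- list()
  j <- 0
  for (cl in names(class_sizes)) {
    for (i in seq_len(class_sizes[[cl]])) {
      j <- j + 1
      rows[[j]] <- data.frame(global_id = sprintf("g%06d", j),
                              source_id = sprintf("%s-%d", cl, i),
                              path = NA_character_, class_label = cl,
                              split = NA_character_,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("global-ID assignment deduplicates across sources", {
  m1 <- data.frame(source_id = c("a1", "a2", "a3", "a4"), path = "p",
                   class_label = "x", stringsAsFactors = FALSE)
  m2 <- data.frame(source_id = c("b1", "b2", "b3", "b4", "a2"), path = "p",
                   class_label = "x", stringsAsFactors = FALSE)
  m3 <- data.frame(source_id = c("c1", "c2", "c3", "c4", "c5", "b3"),
                   path = "p", class_label = "x", stringsAsFactors = FALSE)
  # disjoint sources preserve every record
  out12 <- assign_global_ids(list(m1, m2[1:4, ]))
  expect_equal(nrow(out12), 8)
  # one duplicated record leaves one survivor
  outdup <- assign_global_ids(list(m1, m1))
  expect_equal(nrow(outdup), 4)
  # 4 + 5 + 6 records with 2 cross-source duplicates -> 13
  out <- assign_global_ids(list(m1, m2, m3))
  expect_equal(nrow(out), 13)
  expect_equal(anyDuplicated(out$global_id), 0)
  expect_equal(anyDuplicated(out$source_id), 0)
})

test_that("7:3 split arithmetic reproduces the published per-class table", {
  sizes <- c(meningioma = 1621, glioma = 1645, pituitary = 1757,
             normal = 2000)
  sc <- split_counts(sizes)
  expect_equal(sc$train, c(1135, 1152, 1230, 1400))
  expect_equal(sc$test, c(486, 493, 527, 600))
  expect_equal(sum(sc$train), 4917)
  expect_equal(sum(sc$test), 2106)
  expect_equal(sum(sc$class_size), 7023)
  # the same counts fall out of an actual manifest split
  manifest <- split_dataset(make_manifest(as.list(sizes)), seed = 11)
  got <- tapply(manifest$split %in% c("train", "internal_val"),
                manifest$class_label, sum)
  expect_equal(as.vector(got[names(sizes)]), c(1135, 1152, 1230, 1400))
})

test_that("split invariants: coverage, determinism, and the 15% carve-out", {
  manifest <- make_manifest(list(a = 10, b = 37, c = 101))
  s1 <- split_dataset(manifest, seed = 5)
  s2 <- split_dataset(manifest, seed = 5)
  expect_identical(s1$split, s2$split)
  s3 <- split_dataset(manifest, seed = 6)
  expect_false(identical(s1$split, s3$split))
  expect_true(all(s1$split %in% c("train", "internal_val", "test")))
  # no global ID in two splits (each record appears exactly once)
  expect_equal(anyDuplicated(s1$global_id), 0)
  for (cl in c("a", "b", "c")) {
    n <- sum(manifest$class_label == cl)
    tr_total <- round_half_up(0.7 * n)
    sel <- s1$class_label == cl
    expect_equal(sum(sel & s1$split != "test"), tr_total)
    expect_equal(sum(sel & s1$split == "internal_val"),
                 round_half_up(0.15 * tr_total))
  }
  # class size 10 -> 7 train-portion / 3 test
  expect_equal(sum(s1$class_label == "a" & s1$split != "test"), 7)
  expect_equal(sum(s1$class_label == "a" & s1$split == "test"), 3)
})

test_that("a zero learning rate leaves parameters unchanged but checkpoints", {
  set.seed(601)
  data <- stripfuse:::phantom_tensors(5, seed = 1, image_side = 96)
  net <- build_model(tiny_model_config("F"))
  before <- nn_state_dict(net)
  cfg <- train_config(learning_rate = 0, epochs = 1, batch_size = 4,
                      seed = 3, augment = FALSE)
  ck <- stripfuse:::train_tensors(net, data$train, data$internal_val, cfg)
  after <- nn_state_dict(net)
  for (nm in names(before)) {
    if (!grepl("\\.buf\\.", nm)) {
      expect_identical(before[[nm]], after[[nm]])
    }
  }
  expect_equal(ck$best_epoch, 1)
  expect_false(is.null(ck$state))
  expect_s3_class(ck, "sf_checkpoint")
})

test_that("training is bit-reproducible under a fixed seed", {
  run <- function() {
    set.seed(77)
    data <- stripfuse:::phantom_tensors(5, seed = 2, image_side = 96)
    net <- build_model(tiny_model_config("F"))
    cfg <- train_config(learning_rate = 1e-3, epochs = 2, batch_size = 4,
                        seed = 9)
    stripfuse:::train_tensors(net, data$train, data$internal_val, cfg)
  }
  ck1 <- run()
  ck2 <- run()
  expect_identical(ck1$history, ck2$history)
  expect_identical(ck1$state, ck2$state)
  # the checkpointed accuracy is the running maximum of the history
  expect_equal(ck1$best_val_acc, max(ck1$history$val_acc))
})

test_that("non-finite losses abort with a divergence error", {
  set.seed(602)
  data <- stripfuse:::phantom_tensors(5, seed = 3, image_side = 96)
  net <- build_model(tiny_model_config("F"))
  net$children$classifier$par$W[1] <- NaN
  cfg <- train_config(epochs = 1, batch_size = 4, seed = 1, augment = FALSE)
  expect_error(
    stripfuse:::train_tensors(net, data$train, data$internal_val, cfg),
    class = "stripfuse_divergence")
})

test_that("checkpoints restore, evaluate deterministically, and self-agree", {
  set.seed(603)
  data <- stripfuse:::phantom_tensors(5, seed = 4, image_side = 96)
  net <- build_model(tiny_model_config("F"))
  cfg <- train_config(learning_rate = 1e-3, epochs = 1, batch_size = 4,
                      seed = 2, augment = FALSE)
  ck <- stripfuse:::train_tensors(net, data$train, data$internal_val, cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  net2 <- restore_model(ck2)
  ev1 <- stripfuse:::eval_tensors(net2, data$test)
  ev2 <- stripfuse:::eval_tensors(restore_model(ck), data$test)
  expect_identical(ev1$pred, ev2$pred)
  rep <- metrics_report(data$test$y, ev1$pred, n_classes = 4,
                        probs = ev1$probs)
  # report accuracy equals trace/total of its own confusion matrix
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
})

test_that("evaluation behaves correctly for oracle and random predictors", {
  set.seed(604)
  y <- rep(1:4, each = 50)
  # oracle predictor
  expect_equal(metrics_report(y, y, 4)$accuracy, 1.0)
  # uniform-random predictor on a balanced set: near chance, within a
  # generous binomial envelope (5 sigma ~ 0.153 for n = 200)
  yp <- sample(4, 200, replace = TRUE)
  acc <- metrics_report(y, yp, 4)$accuracy
  expect_lt(abs(acc - 0.25), 5 * sqrt(0.25 * 0.75 / 200))
})
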