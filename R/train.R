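# Training: AdamW (and the other common first-order optimisers), softmax
# cross-entropy, the epoch loop with best-validation checkpointing, and
# evaluation of a checkpoint on a manifest split.

#' Training configuration
#'
#' Defaults are the tuned hyperparameters of the reference protocol:
#' batch size 32, learning rate 1e-4, AdamW with L2 weight-decay
#' coefficient 1e-4, cross-entropy loss, 50 epochs, dropout 0.3.
#'
#' @param batch_size mini-batch size
#' @param learning_rate optimiser step size
#' @param optimizer one of `"adamw"`, `"adam"`, `"rmsprop"`, `"sgd"`
#' @param weight_decay L2 weight-decay coefficient (decoupled for AdamW)
#' @param epochs number of training epochs
#' @param dropout dropout rate inside the combination heads
#' @param seed integer seed governing shuffling, augmentation, and dropout
#' @param augment logical; apply training-time augmentation
#' @return a `train_config` list
#' @export
train_config <- function(batch_size = 32L, learning_rate = 1e-4,
                         optimizer = c("adamw", "adam", "rmsprop", "sgd"),
                         weight_decay = 1e-4, epochs = 50L, dropout = 0.3,
                         seed = 1L, augment = TRUE) {
  optimizer <- match.arg(optimizer)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer = optimizer,
                 weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 dropout = dropout,
                 seed = as.integer(seed),
                 augment = isTRUE(augment)),
            class = "train_config")
}

# First-order optimiser over the parameter handles of a module.
make_optimizer <- function(net, cfg) {
  params <- nn_parameters(net)
  kind <- cfg$optimizer
  lr <- cfg$learning_rate
  wd <- cfg$weight_decay
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m <- lapply(params, function(p) 0)
  v <- lapply(params, function(p) 0)
  t <- 0L
  step <- function() {
    t <<- t + 1L
    for (i in seq_along(params)) {
      p <- params[[i]]
      w <- p$env$par[[p$name]]
      g <- p$env$grad[[p$name]]
      if (kind == "sgd") {
        w <- w - lr * (g + wd * w)
      } else if (kind == "rmsprop") {
        v[[i]] <<- 0.99 * v[[i]] + 0.01 * g^2
        w <- w - lr * (g / (sqrt(v[[i]]) + eps) + wd * w)
      } else {
        m[[i]] <<- b1 * m[[i]] + (1 - b1) * g
        v[[i]] <<- b2 * v[[i]] + (1 - b2) * g^2
        mh <- m[[i]] / (1 - b1^t)
        vh <- v[[i]] / (1 - b2^t)
        if (kind == "adamw") {
          # decoupled weight decay
          w <- w - lr * (mh / (sqrt(vh) + eps) + wd * w)
        } else {
          w <- w - lr * mh / (sqrt(vh) + eps)
        }
      }
      p$env$par[[p$name]] <- w
    }
  }
  list(step = step)
}

#' Softmax cross-entropy loss and gradient
#'
#' @param logits `(batch, K)` matrix of unnormalised scores
#' @param y integer labels in `1..K`
#' @return list with `loss` (mean negative log-likelihood), `grad`
#'   (gradient w.r.t. the logits), and `pred` (argmax class)
#' @export
cross_entropy <- function(logits, y) {
  n <- nrow(logits)
  z <- logits - apply(logits, 1L, max)
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  loss <- -mean(logp[cbind(seq_len(n), y)])
  p <- exp(logp)
  onehot <- matrix(0, n, ncol(logits))
  onehot[cbind(seq_len(n), y)] <- 1
  list(loss = loss, grad = (p - onehot) / n, pred = max.col(p, "first"))
}

#' Load and preprocess one manifest split into tensors
#'
#' Reads every image of the chosen split, runs the deterministic
#' preprocessing chain, and stacks the results into a `(n, 1, side, side)`
#' array. Class indices follow the sorted order of the class labels present
#' in the whole manifest.
#'
#' @param manifest manifest data frame with splits assigned
#' @param split one of `"train"`, `"internal_val"`, `"test"`
#' @param side image side expected by the model
#' @param preprocess named list overriding [preprocess_image()] defaults
#'   (`unsharp_radius`, `unsharp_amount`, `sobel_weight`)
#' @return list with `x` (array), `y` (integer labels), `global_id`, and
#'   `class_names`
#' @export
load_split_tensors <- function(manifest, split, side,
                               preprocess = list()) {
  class_names <- sort(unique(manifest$class_label))
  rows <- manifest[!is.na(manifest$split) & manifest$split == split, ,
                   drop = FALSE]
  if (nrow(rows) == 0L) stop("split '", split, "' is empty")
  pp <- utils::modifyList(list(unsharp_radius = 100, unsharp_amount = 1.0,
                               sobel_weight = 0.5), preprocess)
  x <- array(0, dim = c(nrow(rows), 1L, side, side))
  for (i in seq_len(nrow(rows))) {
    x[i, 1L, , ] <- preprocess_image(rows$path[i], side = side,
                                     unsharp_radius = pp$unsharp_radius,
                                     unsharp_amount = pp$unsharp_amount,
                                     sobel_weight = pp$sobel_weight)
  }
  list(x = x, y = match(rows$class_label, class_names),
       global_id = rows$global_id, class_names = class_names)
}

#' Train a network
#'
#' Minimises softmax cross-entropy with the configured optimiser. After
#' every epoch the internal-validation accuracy is evaluated and the
#' parameters are snapshotted whenever it improves (checkpoint-on-best).
#' Training aborts with an error of class `stripfuse_divergence` if the
#' loss becomes non-finite. With a fixed `cfg$seed` the run is bit-for-bit
#' reproducible on CPU.
#'
#' @param net a network built with [build_model()]; its parameters are
#'   updated in place
#' @param manifest manifest with `train` and `internal_val` splits assigned
#' @param cfg a [train_config()]
#' @param preprocess preprocessing overrides, see [load_split_tensors()]
#' @param verbose print one line per epoch
#' @return a checkpoint list: `state` (best parameters), `model_config`,
#'   `train_config`, `class_names`, `history` (per-epoch data frame),
#'   `best_val_acc`, `best_epoch`
#' @export
train_model <- function(net, manifest, cfg = train_config(),
                        preprocess = list(), verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  side <- net$config$image_side
  tr <- load_split_tensors(manifest, "train", side, preprocess)
  va <- load_split_tensors(manifest, "internal_val", side, preprocess)
  train_tensors(net, tr, va, cfg, verbose = verbose)
}

# Core loop over pre-loaded tensors (shared by train_model and the
# acceptance-scale experiments, which reuse tensors across runs).
train_tensors <- function(net, tr, va, cfg, verbose = FALSE) {
  if (dim(tr$x)[1] == 0L) stop("training split is empty")
  if (dim(va$x)[1] == 0L) {
    stop("internal validation split is empty; increase the dataset size ",
         "or the validation fraction")
  }
  set.seed(cfg$seed)
  opt <- make_optimizer(net, cfg)
  n <- dim(tr$x)[1]
  bs <- cfg$batch_size
  history <- data.frame()
  best_acc <- -Inf
  best_state <- NULL
  best_epoch <- NA_integer_
  for (epoch in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq(1L, n, by = bs)) {
      bidx <- idx[start:min(start + bs - 1L, n)]
      xb <- tr$x[bidx, , , , drop = FALSE]
      if (cfg$augment) {
        for (i in seq_along(bidx)) {
          xb[i, 1L, , ] <- augment(xb[i, 1L, , ])
        }
      }
      logits <- net$forward(xb, training = TRUE)
      ce <- cross_entropy(logits, tr$y[bidx])
      if (!is.finite(ce$loss)) {
        stop(structure(class = c("stripfuse_divergence", "error", "condition"),
                       list(message = sprintf(
                         "training diverged (non-finite loss at epoch %d)",
                         epoch),
                         call = sys.call())))
      }
      nn_zero_grad(net)
      net$backward(ce$grad)
      opt$step()
      ep_loss <- ep_loss + ce$loss * length(bidx)
      ep_correct <- ep_correct + sum(ce$pred == tr$y[bidx])
    }
    vl <- eval_tensors(net, va, bs)
    history <- rbind(history, data.frame(
      epoch = epoch,
      train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = vl$loss, val_acc = vl$acc))
    if (vl$acc > best_acc) {
      best_acc <- vl$acc
      best_state <- nn_state_dict(net)
      best_epoch <- epoch
    }
    if (verbose) {
      message(sprintf("[%s] epoch %2d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      format(Sys.time(), "%H:%M:%S"), epoch,
                      ep_loss / n, ep_correct / n, vl$loss, vl$acc))
    }
  }
  structure(list(state = best_state,
                 model_config = net$config,
                 train_config = cfg,
                 class_names = tr$class_names,
                 history = history,
                 best_val_acc = best_acc,
                 best_epoch = best_epoch),
            class = "sf_checkpoint")
}

eval_tensors <- function(net, data, batch_size = 32L) {
  n <- dim(data$x)[1]
  loss <- 0; correct <- 0L
  preds <- integer(n)
  probs <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    bidx <- start:min(start + batch_size - 1L, n)
    logits <- net$forward(data$x[bidx, , , , drop = FALSE], training = FALSE)
    ce <- cross_entropy(logits, data$y[bidx])
    loss <- loss + ce$loss * length(bidx)
    correct <- correct + sum(ce$pred == data$y[bidx])
    preds[bidx] <- ce$pred
    probs <- rbind(probs, row_softmax(logits))
  }
  list(loss = loss / n, acc = correct / n, pred = preds, probs = probs)
}

#' Save / load a checkpoint
#'
#' The checkpoint is a single archive holding the named parameter tensors,
#' the model and training configurations, the class names, and the training
#' history.
#'
#' @param checkpoint result of [train_model()]
#' @param path file path
#' @return `path` / the checkpoint
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "sf_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "sf_checkpoint"))
  ck
}

#' Rebuild the network stored in a checkpoint
#'
#' @param checkpoint an `sf_checkpoint`
#' @return a network with the checkpointed parameters loaded
#' @export
restore_model <- function(checkpoint) {
  net <- with_local_seed(0L, build_model(checkpoint$model_config))
  nn_load_state_dict(net, checkpoint$state)
  net
}

#' Evaluate a checkpoint on a manifest split
#'
#' Deterministic: restores the best parameters, preprocesses the split, and
#' returns the full [metrics_report()] (including per-class and
#' micro-average AUC).
#'
#' @param checkpoint an `sf_checkpoint` or a path to one
#' @param manifest manifest with splits assigned
#' @param split split to evaluate, default `"test"`
#' @param preprocess preprocessing overrides
#' @param batch_size evaluation batch size
#' @return a [metrics_report()]
#' @export
evaluate_model <- function(checkpoint, manifest, split = "test",
                           preprocess = list(), batch_size = 32L) {
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  net <- restore_model(checkpoint)
  data <- load_split_tensors(manifest, split, net$config$image_side,
                             preprocess)
  if (!identical(data$class_names, checkpoint$class_names)) {
    stop("class labels in the manifest do not match the checkpoint (",
         paste(data$class_names, collapse = ","), " vs ",
         paste(checkpoint$class_names, collapse = ","), ")")
  }
  ev <- eval_tensors(net, data, batch_size)
  metrics_report(data$y, ev$pred, n_classes = length(data$class_names),
                 probs = ev$probs, class_names = data$class_names)
}
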