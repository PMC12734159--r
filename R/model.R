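# Full network assembly: three spatial blocks, four residual blocks, two
# strip-pooling combination heads tapped after the third spatial block and
# the fourth residual block, cross-scale concatenation, linear classifier,
# softmax. Ablation variants A-F keep or drop components.

#' Model configuration
#'
#' The default channel plan — spatial widths (32, 64, 128), residual widths
#' (128, 192, 384, 512) with strides (1, 2, 2, 2), head dimension 256 —
#' places the full model near 9.8 million trainable parameters. Shallow
#' layers downsample through pooling (max then average), deep layers through
#' strided convolutions, so a 224 x 224 input passes stages
#' 224 -> 112 -> 56 -> 56 -> 28 -> 14 -> 7.
#'
#' @param input_channels input image channels (1: preprocessed grayscale)
#' @param num_classes number of output classes
#' @param image_side input side length in pixels; must be a multiple of 32
#'   and at least 96 so the deepest feature map is at least 3 x 3
#' @param spatial_widths output channels of the three spatial blocks
#'   (non-decreasing)
#' @param residual_widths output channels of the four residual blocks
#' @param residual_strides strides of the four residual blocks, each 1 or 2
#' @param head_dim feature-vector length emitted by each head
#' @param dropout dropout rate inside the combination heads
#' @param variant ablation variant letter, `"A"` to `"F"` (`"F"` = full model)
#' @return a `model_config` list
#' @export
model_config <- function(input_channels = 1L, num_classes = 4L,
                         image_side = 224L,
                         spatial_widths = c(32L, 64L, 128L),
                         residual_widths = c(128L, 192L, 384L, 512L),
                         residual_strides = c(1L, 2L, 2L, 2L),
                         head_dim = 256L, dropout = 0.3,
                         variant = "F") {
  variant <- match.arg(variant, LETTERS[1:6])
  stopifnot(length(spatial_widths) == 3L, length(residual_widths) == 4L,
            length(residual_strides) == 4L, all(residual_strides %in% 1:2),
            head_dim >= 1L, num_classes >= 2L)
  if (any(diff(c(input_channels, spatial_widths)) < 0)) {
    stop("spatial widths must be non-decreasing (widening backbone)")
  }
  if (image_side %% 32L != 0L || image_side < 96L) {
    stop("image_side must be a multiple of 32 and at least 96")
  }
  structure(list(input_channels = as.integer(input_channels),
                 num_classes = as.integer(num_classes),
                 image_side = as.integer(image_side),
                 spatial_widths = as.integer(spatial_widths),
                 residual_widths = as.integer(residual_widths),
                 residual_strides = as.integer(residual_strides),
                 head_dim = as.integer(head_dim),
                 dropout = dropout,
                 variant = variant),
            class = "model_config")
}

variant_plan <- function(variant) {
  switch(variant,
         A = list(spatial = TRUE, residual = FALSE, shallow = "plain", deep = NULL),
         B = list(spatial = TRUE, residual = FALSE, shallow = "combo", deep = NULL),
         C = list(spatial = FALSE, residual = TRUE, shallow = NULL, deep = "plain"),
         D = list(spatial = FALSE, residual = TRUE, shallow = NULL, deep = "combo"),
         E = list(spatial = TRUE, residual = TRUE, shallow = "plain", deep = "plain"),
         F = list(spatial = TRUE, residual = TRUE, shallow = "combo", deep = "combo"),
         stop("unknown variant: ", variant))
}

make_head <- function(kind, channels, cfg) {
  if (kind == "combo") combo_head(channels, cfg$head_dim, cfg$dropout)
  else plain_head(channels, cfg$head_dim)
}

#' Build the classification network
#'
#' Assembles the backbone and heads described by a [model_config()]. Weights
#' are initialised from the caller's RNG; seed it with [set.seed()] for
#' reproducible builds.
#'
#' @param cfg a [model_config()]
#' @return a network module
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  plan <- variant_plan(cfg$variant)
  net <- new_module("model")
  net$config <- cfg
  sw <- cfg$spatial_widths
  rw <- cfg$residual_widths
  rs <- cfg$residual_strides

  if (plan$spatial) {
    net$children$spatial1 <- spatial_block(cfg$input_channels, sw[1], pool = "max")
    # nothing consumes the gradient w.r.t. the image batch
    net$children$spatial1$children$conv$need_dx <- FALSE
    net$children$spatial2 <- spatial_block(sw[1], sw[2], pool = "avg")
    net$children$spatial3 <- spatial_block(sw[2], sw[3], pool = "none")
  }
  if (plan$residual) {
    res_in <- if (plan$spatial) sw[3] else cfg$input_channels
    ins <- c(res_in, rw[1:3])
    for (i in 1:4) {
      net$children[[paste0("res", i)]] <- residual_block(ins[i], rw[i], rs[i])
    }
  }
  heads <- list()
  if (!is.null(plan$shallow)) {
    net$children$head_shallow <- make_head(plan$shallow, sw[3], cfg)
    heads$shallow <- "spatial"
  }
  if (!is.null(plan$deep)) {
    net$children$head_deep <- make_head(plan$deep, rw[4], cfg)
    heads$deep <- "residual"
  }
  net$head_taps <- heads
  # near-zero classifier initialisation: initial logits start near zero, so
  # the first optimisation steps are not spent unlearning random margins
  net$children$classifier <- layer_linear(length(heads) * cfg$head_dim,
                                          cfg$num_classes, init_sd = 0.01)

  net$forward <- function(x, training = FALSE) {
    d <- check_feature_map(x)
    if (d[2] != cfg$input_channels || d[3] != cfg$image_side ||
        d[4] != cfg$image_side) {
      stop("expected input of shape (batch, ", cfg$input_channels, ", ",
           cfg$image_side, ", ", cfg$image_side, "), got (",
           paste(d, collapse = ", "), ")")
    }
    k <- net$children
    cur <- x
    taps <- list()
    if (plan$spatial) {
      for (nm in c("spatial1", "spatial2", "spatial3")) {
        cur <- k[[nm]]$forward(cur, training)
      }
      taps$spatial <- cur
    }
    if (plan$residual) {
      for (nm in paste0("res", 1:4)) cur <- k[[nm]]$forward(cur, training)
      taps$residual <- cur
    }
    feats <- lapply(names(heads), function(h) {
      k[[paste0("head_", h)]]$forward(taps[[heads[[h]]]], training)
    })
    k$classifier$forward(do.call(cbind, feats), training)
  }

  net$backward <- function(dlogits) {
    k <- net$children
    dfeat <- k$classifier$backward(dlogits)
    D <- cfg$head_dim
    dtap <- list(spatial = NULL, residual = NULL)
    for (i in seq_along(heads)) {
      h <- names(heads)[i]
      dh <- k[[paste0("head_", h)]]$backward(dfeat[, (i - 1L) * D + seq_len(D),
                                                   drop = FALSE])
      tp <- heads[[h]]
      dtap[[tp]] <- if (is.null(dtap[[tp]])) dh else dtap[[tp]] + dh
    }
    dcur <- NULL
    if (plan$residual) {
      dcur <- dtap$residual
      for (nm in rev(paste0("res", 1:4))) dcur <- k[[nm]]$backward(dcur)
      if (plan$spatial) {
        dtap$spatial <- if (is.null(dtap$spatial)) dcur else dtap$spatial + dcur
        dcur <- NULL
      }
    }
    if (plan$spatial) {
      dcur <- dtap$spatial
      for (nm in rev(c("spatial1", "spatial2", "spatial3"))) {
        dcur <- k[[nm]]$backward(dcur)
      }
    }
    dcur
  }
  net
}

#' Build an ablation variant
#'
#' * A — spatial blocks with a plain pooled head
#' * B — A plus the shallow strip-pooling combination head
#' * C — residual blocks with a plain pooled head
#' * D — C plus the deep strip-pooling combination head
#' * E — full backbone (spatial + residual), plain heads at both taps
#' * F — the complete model, strip-pooling combination heads at both taps
#'
#' @param variant letter `"A"` to `"F"`
#' @param cfg base [model_config()]; its `variant` field is overridden
#' @return a network module
#' @export
build_variant <- function(variant, cfg = model_config()) {
  variant <- match.arg(variant, LETTERS[1:6])
  cfg$variant <- variant
  build_model(cfg)
}

row_softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' Forward pass returning class probabilities
#'
#' Evaluation-mode forward through the network followed by a row-wise
#' softmax; every output row is nonnegative and sums to one.
#'
#' @param net a network from [build_model()]
#' @param batch `(batch, channels, height, width)` input array
#' @return `(batch, num_classes)` matrix of class probabilities
#' @export
model_forward <- function(net, batch) {
  row_softmax(net$forward(batch, training = FALSE))
}

#' Batched evaluation-mode prediction
#'
#' @param net a network
#' @param x `(n, channels, height, width)` array
#' @param batch_size mini-batch size used internally
#' @return `(n, num_classes)` probability matrix
#' @export
model_predict <- function(net, x, batch_size = 32L) {
  n <- dim(x)[1]
  out <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    p <- model_forward(net, x[idx, , , , drop = FALSE])
    out <- rbind(out, p)
  }
  out
}

#' Per-module parameter counts
#'
#' @param net a network
#' @return data frame with module paths and parameter counts
#' @export
model_summary <- function(net) {
  paths <- character(0)
  counts <- integer(0)
  for (nm in names(net$children)) {
    paths <- c(paths, nm)
    counts <- c(counts, nn_n_params(net$children[[nm]]))
  }
  data.frame(module = paths, n_params = counts,
             stringsAsFactors = FALSE)
}
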