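# Strip pooling: 1-D pooling along entire rows or columns of a feature map,
# the attention gate built from it, and the two head types that produce the
# fixed-length feature vectors fused before classification.

#' Horizontal strip pooling (per-row means)
#'
#' Averages a `(batch, channels, height, width)` feature map across its full
#' width while fixing the height:
#' `out[b, c, h] = mean_j Z[b, c, h, j]`.
#'
#' @param z rank-4 feature map array
#' @return `(batch, channels, height)` array of row means
#' @export
strip_pool_h <- function(z) {
  d <- check_feature_map(z)
  m <- z
  dim(m) <- c(d[1] * d[2] * d[3], d[4])
  out <- .rowMeans(m, nrow(m), ncol(m))
  dim(out) <- d[1:3]
  out
}

#' Vertical strip pooling (per-column means)
#'
#' Averages a feature map across its full height while fixing the width:
#' `out[b, c, j] = mean_h Z[b, c, h, j]`.
#'
#' @param z rank-4 feature map array
#' @return `(batch, channels, width)` array of column means
#' @export
strip_pool_v <- function(z) {
  d <- check_feature_map(z)
  strip_pool_h(aperm(z, c(1L, 2L, 4L, 3L)))
}

# Broadcast a (B, C, H) descriptor along a new trailing width axis.
expand_rows <- function(p, W) {
  d <- dim(p)
  out <- rep(as.vector(p), times = W)
  dim(out) <- c(d, W)
  out
}

# Broadcast a (B, C, W) descriptor along a new height axis (position 3).
expand_cols <- function(p, H) {
  aperm(expand_rows(p, H), c(1L, 2L, 4L, 3L))
}

#' Strip-pooling attention module
#'
#' Computes per-row and per-column mean descriptors of the input map, passes
#' each through a channel-mixing 1-D convolution (kernel 3, same padding)
#' and batch normalisation, broadcasts both back to the full spatial size,
#' sums them, applies a 1 x 1 convolution and a sigmoid to obtain a gate
#' `G` in `(0, 1)`, and returns `Z * G`. The directional pooling makes the
#' gate sensitive to elongated, anisotropic structures that square pooling
#' windows average away.
#'
#' @param channels channel count of the gated feature map
#' @return a composite module; its forward pass requires spatial dimensions
#'   of at least 3
#' @export
strip_attention <- function(channels) {
  C <- as.integer(channels)
  e <- new_module("strip_attention")
  e$children$conv_h <- layer_conv1d(C, C, 3L)
  e$children$bn_h <- layer_batchnorm(C)
  e$children$conv_v <- layer_conv1d(C, C, 3L)
  e$children$bn_v <- layer_batchnorm(C)
  # near-neutral gate at initialisation (sigmoid of a small pre-activation
  # stays close to 0.5), so the attended branch starts as a stable, scaled
  # copy of its input while gradients still reach the directional convs
  e$children$conv_mix <- layer_conv2d(C, C, 1L, pad = 0L, init_sd = 0.01)
  e$forward <- function(z, training = FALSE) {
    d <- check_feature_map(z)
    if (d[3] < 3L || d[4] < 3L) {
      stop("strip attention needs spatial dimensions >= 3, got ",
           d[3], "x", d[4])
    }
    k <- e$children
    ph <- k$bn_h$forward(k$conv_h$forward(strip_pool_h(z), training), training)
    pv <- k$bn_v$forward(k$conv_v$forward(strip_pool_v(z), training), training)
    s <- expand_rows(ph, d[4]) + expand_cols(pv, d[3])
    g <- 1 / (1 + exp(-k$conv_mix$forward(s, training)))
    if (training) e$cache <- list(z = z, g = g, d = d)
    z * g
  }
  e$backward <- function(dy) {
    cc <- e$cache
    d <- cc$d
    k <- e$children
    dz <- dy * cc$g
    dt <- dy * cc$z * cc$g * (1 - cc$g)
    ds <- k$conv_mix$backward(dt)
    # collapse the broadcasts: sum over width for the row branch, over
    # height for the column branch
    m <- ds
    dim(m) <- c(d[1] * d[2] * d[3], d[4])
    dph <- .rowSums(m, nrow(m), ncol(m))
    dim(dph) <- d[1:3]
    mv <- aperm(ds, c(1L, 2L, 4L, 3L))
    dim(mv) <- c(d[1] * d[2] * d[4], d[3])
    dpv <- .rowSums(mv, nrow(mv), ncol(mv))
    dim(dpv) <- c(d[1], d[2], d[4])
    dh <- k$conv_h$backward(k$bn_h$backward(dph))
    dv <- k$conv_v$backward(k$bn_v$backward(dpv))
    dz <- dz + expand_rows(dh / d[4], d[4]) + expand_cols(dv / d[3], d[3])
    dz
  }
  e
}

#' Strip-pooling combination head
#'
#' The side branch tapped off the backbone: strip-pooling attention, global
#' average pooling, dropout (training only), and a fully connected layer
#' producing a fixed-length feature vector. The shallow head (after the
#' third spatial block) and the deep head (after the fourth residual block)
#' both emit vectors of the same length so their concatenation is balanced.
#'
#' @param channels channel count at the tap point
#' @param dim output feature-vector length
#' @param dropout dropout rate, default 0.3
#' @return a composite module mapping a feature map to a `(batch, dim)` matrix
#' @export
combo_head <- function(channels, dim = 256L, dropout = 0.3) {
  e <- new_module("combo_head")
  e$children$attn <- strip_attention(channels)
  e$children$gap <- layer_gap()
  e$children$drop <- layer_dropout(dropout)
  e$children$fc <- layer_linear(channels, dim)
  seqn <- names(e$children)
  e$forward <- function(x, training = FALSE) {
    for (nm in seqn) x <- e$children[[nm]]$forward(x, training)
    x
  }
  e$backward <- function(dy) {
    for (nm in rev(seqn)) dy <- e$children[[nm]]$backward(dy)
    dy
  }
  e
}

#' Plain pooled head (ablation baseline)
#'
#' Global average pooling followed by a fully connected layer — the head
#' used by ablation variants that drop the strip-pooling attention, so those
#' variants differ from the full model only in the component under test.
#'
#' @inheritParams combo_head
#' @return a composite module mapping a feature map to a `(batch, dim)` matrix
#' @export
plain_head <- function(channels, dim = 256L) {
  e <- new_module("plain_head")
  e$children$gap <- layer_gap()
  e$children$fc <- layer_linear(channels, dim)
  e$forward <- function(x, training = FALSE) {
    e$children$fc$forward(e$children$gap$forward(x, training), training)
  }
  e$backward <- function(dy) {
    e$children$gap$backward(e$children$fc$backward(dy))
  }
  e
}
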