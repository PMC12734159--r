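# Functional operator surfaces (single-channel 2-D forms of the network's
# convolution and pooling) plus the two backbone block types.

#' Valid 2-D convolution (cross-correlation form)
#'
#' For an `M x N` input and an `r x s` kernel the output is
#' `(M - r + 1) x (N - s + 1)` with
#' `y[m, n] = sum_p sum_q f[m + p - 1, n + q - 1] * k[p, q]`,
#' i.e. the weighted sum of each local input region — the operation applied
#' by every convolutional layer in the network (those add zero padding to
#' preserve the spatial size).
#'
#' @param f numeric matrix, the input feature map
#' @param k numeric matrix, the kernel, no larger than `f`
#' @return numeric matrix of size `(M - r + 1) x (N - s + 1)`
#' @export
conv2d_valid <- function(f, k) {
  stopifnot(is.matrix(f), is.matrix(k))
  if (nrow(k) > nrow(f) || ncol(k) > ncol(f)) {
    stop("kernel (", nrow(k), "x", ncol(k), ") larger than input (",
         nrow(f), "x", ncol(f), ")")
  }
  x <- f
  dim(x) <- c(1L, 1L, nrow(f), ncol(f))
  w <- k
  dim(w) <- c(1L, 1L, nrow(k), ncol(k))
  y <- cpp_conv2d_forward(x, dim(x), w, dim(w), 0, 1L, 0L, 0L)
  matrix(y, dim(y)[3], dim(y)[4])
}

#' 2-D pooling over sliding windows
#'
#' Average pooling takes `y = mean(window)`, max pooling `y = max(window)`;
#' windows of size `window = c(r, s)` advance by `stride` in both directions
#' and must fit entirely inside the input.
#'
#' @param f numeric matrix
#' @param kind `"max"` or `"avg"`
#' @param window window size, scalar or `c(r, s)`
#' @param stride window stride, a positive integer
#' @return numeric matrix of pooled values
#' @export
pool2d <- function(f, kind = c("max", "avg"), window = 2L, stride = 2L) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(f))
  window <- rep(as.integer(window), length.out = 2L)
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  if (any(window < 1L) || window[1] > nrow(f) || window[2] > ncol(f)) {
    stop("pooling window must fit inside the input")
  }
  ho <- (nrow(f) - window[1]) %/% stride + 1L
  wo <- (ncol(f) - window[2]) %/% stride + 1L
  out <- matrix(0, ho, wo)
  agg <- if (kind == "max") max else mean
  for (i in seq_len(ho)) {
    ri <- (i - 1L) * stride + seq_len(window[1])
    for (j in seq_len(wo)) {
      cj <- (j - 1L) * stride + seq_len(window[2])
      out[i, j] <- agg(f[ri, cj])
    }
  }
  out
}

#' Shallow spatial block
#'
#' A VGG-style unit: 3 x 3 same-padding convolution, batch normalisation,
#' ReLU, then an optional 2 x 2 stride-2 pool. In the backbone the first
#' block max-pools, the second average-pools, and the third has no pool so
#' its output can feed both the residual stack and the shallow strip-pooling
#' head.
#'
#' @param in_channels,out_channels channel counts; the backbone widens, so
#'   `out_channels >= in_channels` is required
#' @param pool `"none"`, `"max"`, or `"avg"`
#' @return a composite module
#' @export
spatial_block <- function(in_channels, out_channels, pool = c("none", "max", "avg")) {
  pool <- match.arg(pool)
  if (out_channels < in_channels) {
    stop("spatial blocks widen the backbone: out_channels >= in_channels required")
  }
  e <- new_module("spatial_block")
  e$children$conv <- layer_conv2d(in_channels, out_channels, 3L)
  e$children$bn <- layer_batchnorm(out_channels)
  e$children$relu <- layer_relu()
  if (pool == "max") e$children$pool <- layer_maxpool2()
  if (pool == "avg") e$children$pool <- layer_avgpool2()
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

#' Deep residual block
#'
#' Two 3 x 3 same-padding convolutions: the first followed by batch
#' normalisation and ReLU, the second by ReLU only; the branch output is
#' added to a shortcut. The shortcut is the identity when the block
#' preserves shape, otherwise a 1 x 1 convolution carrying the block's
#' stride (projection shortcut). There is no activation after the addition,
#' so a block with all-zero weights is exactly the identity.
#'
#' @param in_channels,out_channels channel counts
#' @param stride 1 or 2; stride 2 halves the spatial size via the first
#'   convolution
#' @return a composite module
#' @export
residual_block <- function(in_channels, out_channels, stride = 1L) {
  stopifnot(stride %in% c(1L, 2L))
  e <- new_module("residual_block")
  e$children$conv1 <- layer_conv2d(in_channels, out_channels, 3L, stride = stride)
  e$children$bn1 <- layer_batchnorm(out_channels)
  e$children$relu1 <- layer_relu()
  e$children$conv2 <- layer_conv2d(out_channels, out_channels, 3L)
  e$children$relu2 <- layer_relu()
  projected <- stride != 1L || in_channels != out_channels
  if (projected) {
    e$children$proj <- layer_conv2d(in_channels, out_channels, 1L,
                                    stride = stride, pad = 0L)
  }
  e$forward <- function(x, training = FALSE) {
    k <- e$children
    branch <- k$relu2$forward(
      k$conv2$forward(
        k$relu1$forward(k$bn1$forward(k$conv1$forward(x, training), training),
                        training),
        training),
      training)
    shortcut <- if (projected) k$proj$forward(x, training) else x
    branch + shortcut
  }
  e$backward <- function(dy) {
    k <- e$children
    db <- k$conv1$backward(
      k$bn1$backward(k$relu1$backward(k$conv2$backward(k$relu2$backward(dy)))))
    ds <- if (projected) k$proj$backward(dy) else dy
    db + ds
  }
  e
}
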