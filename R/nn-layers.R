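# Leaf layers. Every layer caches whatever its backward pass needs during
# forward(training = TRUE); evaluation-mode forwards are deterministic and
# never touch the RNG.

#' 2-D convolution layer
#'
#' Same-padding by default for odd kernels (`pad = (k - 1) / 2`), matching
#' the backbone convention where spatial size only changes at pools and
#' strided convolutions. Weights use He-normal initialisation drawn from the
#' caller's RNG.
#'
#' @param in_channels,out_channels channel counts
#' @param kernel kernel size, scalar or `c(kh, kw)`
#' @param stride stride (same in both directions)
#' @param pad padding, scalar or `c(pad_h, pad_w)`; default keeps "same" size
#'   at stride 1
#' @param init_sd weight initialisation scale; `NULL` (default) gives
#'   He-normal `sqrt(2 / fan_in)`
#' @return a layer module
#' @export
layer_conv2d <- function(in_channels, out_channels, kernel = 3L, stride = 1L,
                         pad = NULL, init_sd = NULL) {
  kernel <- rep(as.integer(kernel), length.out = 2L)
  if (is.null(pad)) pad <- (kernel - 1L) %/% 2L
  pad <- rep(as.integer(pad), length.out = 2L)
  e <- new_module("conv2d")
  e$in_channels <- as.integer(in_channels)
  e$out_channels <- as.integer(out_channels)
  e$stride <- as.integer(stride)
  e$pad <- pad
  fan_in <- in_channels * prod(kernel)
  if (is.null(init_sd)) init_sd <- sqrt(2 / fan_in)
  e$par$W <- array(stats::rnorm(out_channels * fan_in, sd = init_sd),
                   dim = c(out_channels, in_channels, kernel[1], kernel[2]))
  e$par$b <- numeric(out_channels)
  e$grad$W <- array(0, dim(e$par$W))
  e$grad$b <- numeric(out_channels)
  e$forward <- function(x, training = FALSE) {
    d <- check_feature_map(x)
    if (d[2] != e$in_channels) {
      stop("channel mismatch: got ", d[2], ", expected ", e$in_channels)
    }
    if (training) {
      # fill a persistent im2col buffer, reused by the backward pass and
      # across steps (reallocated only when the batch shape changes)
      wd <- dim(e$par$W)
      ho <- (d[3] + 2L * e$pad[1] - wd[3]) %/% e$stride + 1L
      wo <- (d[4] + 2L * e$pad[2] - wd[4]) %/% e$stride + 1L
      K <- wd[2] * wd[3] * wd[4]
      N <- d[1] * ho * wo
      if (is.null(e$col) || nrow(e$col) != K || ncol(e$col) != N) {
        e$col <- matrix(0, K, N)
      }
      e$xdim <- dim(x)
      return(cpp_conv2d_forward_fill(x, dim(x), e$par$W, dim(e$par$W),
                                     e$par$b, e$stride, e$pad[1], e$pad[2],
                                     e$col))
    }
    cpp_conv2d_forward(x, dim(x), e$par$W, dim(e$par$W), e$par$b,
                       e$stride, e$pad[1], e$pad[2])
  }
  e$need_dx <- TRUE
  e$backward <- function(dy) {
    if (e$need_dx) {
      r <- cpp_conv2d_backward_cached(e$col, e$xdim, e$par$W, dim(e$par$W),
                                      dy, e$stride, e$pad[1], e$pad[2])
    } else {
      r <- cpp_conv2d_backward_nodx(e$col, e$xdim, dim(e$par$W), dy,
                                    e$stride, e$pad[1], e$pad[2])
      r$dx <- NULL
    }
    e$grad$W <- e$grad$W + r$dw
    e$grad$b <- e$grad$b + r$db
    r$dx
  }
  e
}

#' 1-D convolution layer for strip-pooled descriptors
#'
#' Channel-mixing convolution along the length axis of a `(batch, channels,
#' length)` tensor, kernel 3 with same padding. Internally a degenerate 2-D
#' convolution with a 1 x k kernel.
#'
#' @inheritParams layer_conv2d
#' @param kernel kernel length
#' @return a layer module
#' @export
layer_conv1d <- function(in_channels, out_channels, kernel = 3L) {
  kernel <- as.integer(kernel)
  e <- new_module("conv1d")
  e$in_channels <- as.integer(in_channels)
  fan_in <- in_channels * kernel
  e$par$W <- array(stats::rnorm(out_channels * fan_in, sd = sqrt(2 / fan_in)),
                   dim = c(out_channels, in_channels, 1L, kernel))
  e$par$b <- numeric(out_channels)
  e$grad$W <- array(0, dim(e$par$W))
  e$grad$b <- numeric(out_channels)
  pad_w <- (kernel - 1L) %/% 2L
  e$forward <- function(x, training = FALSE) {
    stopifnot(length(dim(x)) == 3L)
    d <- dim(x)
    x4 <- x
    dim(x4) <- c(d[1], d[2], 1L, d[3])
    if (training) e$x <- x4
    y <- cpp_conv2d_forward(x4, dim(x4), e$par$W, dim(e$par$W), e$par$b,
                            1L, 0L, pad_w)
    dy <- dim(y)
    dim(y) <- c(dy[1], dy[2], dy[4])
    y
  }
  e$backward <- function(dy) {
    d <- dim(dy)
    dim(dy) <- c(d[1], d[2], 1L, d[3])
    r <- cpp_conv2d_backward(e$x, dim(e$x), e$par$W, dim(e$par$W), dy,
                             1L, 0L, pad_w)
    e$grad$W <- e$grad$W + r$dw
    e$grad$b <- e$grad$b + r$db
    dx <- r$dx
    dd <- dim(dx)
    dim(dx) <- c(dd[1], dd[2], dd[4])
    dx
  }
  e
}

#' Batch normalisation layer
#'
#' Works on rank-3 `(batch, channels, length)` or rank-4 `(batch, channels,
#' height, width)` tensors; statistics are taken per channel over all other
#' axes. Training mode uses batch statistics (biased variance) and updates
#' exponential running statistics; evaluation mode is the deterministic
#' affine map through the running statistics.
#'
#' @param channels number of channels
#' @param eps numerical stabiliser added to the variance
#' @param momentum running-statistics update weight
#' @return a layer module
#' @export
layer_batchnorm <- function(channels, eps = 1e-5, momentum = 0.1) {
  C <- as.integer(channels)
  e <- new_module("batchnorm")
  e$par$gamma <- rep(1, C)
  e$par$beta <- rep(0, C)
  e$grad$gamma <- numeric(C)
  e$grad$beta <- numeric(C)
  e$buffers$running_mean <- rep(0, C)
  e$buffers$running_var <- rep(1, C)
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)
    stopifnot(length(d) %in% c(3L, 4L), d[2] == C)
    B <- d[1]
    n <- length(x) / C
    if (training) {
      st <- cpp_channel_stats(x, B, C)
      mu <- st$sum / n
      vr <- pmax(st$sumsq / n - mu^2, 0)
      invstd <- 1 / sqrt(vr + eps)
      # the normalised map xn is itself affine in x; rebuild it lazily in
      # the backward pass instead of holding a second array here
      e$cache <- list(x = x, mu = mu, invstd = invstd, n = n, B = B)
      e$buffers$running_mean <- (1 - momentum) * e$buffers$running_mean + momentum * mu
      uvar <- if (n > 1) vr * n / (n - 1) else vr
      e$buffers$running_var <- (1 - momentum) * e$buffers$running_var + momentum * uvar
    } else {
      mu <- e$buffers$running_mean
      invstd <- 1 / sqrt(e$buffers$running_var + eps)
    }
    a <- e$par$gamma * invstd
    cpp_affine_channels(x, B, C, a, e$par$beta - mu * a)
  }
  e$backward <- function(dy) {
    cc <- e$cache
    B <- cc$B
    n <- cc$n
    xn <- cpp_affine_channels(cc$x, B, C, cc$invstd, -cc$mu * cc$invstd)
    st <- cpp_bn_grad_stats(dy, xn, B, C)
    e$grad$gamma <- e$grad$gamma + st$sum_dyxn
    e$grad$beta <- e$grad$beta + st$sum_dy
    cpp_bn_dx(dy, xn, e$par$gamma * cc$invstd, st$sum_dy / n,
              st$sum_dyxn / n, B, C)
  }
  e
}

#' ReLU activation layer
#' @return a layer module
#' @export
layer_relu <- function() {
  e <- new_module("relu")
  e$forward <- function(x, training = FALSE) {
    if (training) e$x <- x
    cpp_relu(x)
  }
  e$backward <- function(dy) cpp_relu_backward(dy, e$x)
  e
}

check_pool_dims <- function(x) {
  d <- dim(x)
  if (d[3] %% 2L != 0L || d[4] %% 2L != 0L) {
    stop("2x2 stride-2 pooling needs even spatial dimensions, got ",
         d[3], "x", d[4])
  }
  d
}

#' 2 x 2 stride-2 max-pooling layer
#'
#' Ties resolve to the first window element in fixed (top-left, bottom-left,
#' top-right, bottom-right) order, keeping the backward pass deterministic.
#' @return a layer module
#' @export
layer_maxpool2 <- function() {
  e <- new_module("maxpool2")
  e$forward <- function(x, training = FALSE) {
    d <- check_pool_dims(x)
    r <- cpp_maxpool2_forward(x, d)
    if (training) e$cache <- list(idx = r$idx, dims = d)
    r$y
  }
  e$backward <- function(dy) {
    cpp_maxpool2_backward(dy, e$cache$idx, e$cache$dims)
  }
  e
}

#' 2 x 2 stride-2 average-pooling layer
#' @return a layer module
#' @export
layer_avgpool2 <- function() {
  e <- new_module("avgpool2")
  e$forward <- function(x, training = FALSE) {
    d <- check_pool_dims(x)
    if (training) e$dims <- d
    cpp_avgpool2_forward(x, d)
  }
  e$backward <- function(dy) cpp_avgpool2_backward(dy, e$dims)
  e
}

#' Global average pooling layer
#'
#' Averages a `(batch, channels, height, width)` map over its spatial axes,
#' returning a `(batch, channels)` matrix.
#' @return a layer module
#' @export
layer_gap <- function() {
  e <- new_module("gap")
  e$forward <- function(x, training = FALSE) {
    d <- check_feature_map(x)
    if (training) e$dims <- d
    m <- x
    dim(m) <- c(d[1] * d[2], d[3] * d[4])
    matrix(.rowMeans(m, nrow(m), ncol(m)), d[1], d[2])
  }
  e$backward <- function(dy) {
    d <- e$dims
    hw <- d[3] * d[4]
    dx <- rep(as.vector(dy) / hw, times = hw)
    dim(dx) <- d
    dx
  }
  e
}

#' Dropout layer
#'
#' Inverted dropout: active only in training mode, identity at evaluation.
#' A rate of 1 zeroes the input entirely (degenerate but well-defined).
#'
#' @param rate drop probability in `[0, 1]`
#' @return a layer module
#' @export
layer_dropout <- function(rate = 0.3) {
  stopifnot(rate >= 0, rate <= 1)
  e <- new_module("dropout")
  e$rate <- rate
  e$forward <- function(x, training = FALSE) {
    if (!training || rate == 0) {
      e$mask <- NULL
      return(x)
    }
    if (rate >= 1) {
      e$mask <- 0
      return(x * 0)
    }
    mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
    dim(mask) <- dim(x)
    e$mask <- mask
    x * mask
  }
  e$backward <- function(dy) if (is.null(e$mask)) dy else dy * e$mask
  e
}

#' Fully connected (linear) layer
#'
#' @param in_features,out_features sizes of the input and output vectors
#' @param init_sd weight initialisation scale; `NULL` (default) gives
#'   He-normal `sqrt(2 / fan_in)`
#' @return a layer module
#' @export
layer_linear <- function(in_features, out_features, init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- sqrt(2 / in_features)
  e <- new_module("linear")
  e$par$W <- matrix(stats::rnorm(out_features * in_features, sd = init_sd),
                    out_features, in_features)
  e$par$b <- numeric(out_features)
  e$grad$W <- matrix(0, out_features, in_features)
  e$grad$b <- numeric(out_features)
  e$forward <- function(x, training = FALSE) {
    stopifnot(is.matrix(x), ncol(x) == ncol(e$par$W))
    if (training) e$x <- x
    sweep(x %*% t(e$par$W), 2L, e$par$b, "+")
  }
  e$backward <- function(dy) {
    e$grad$W <- e$grad$W + t(dy) %*% e$x
    e$grad$b <- e$grad$b + .colSums(dy, nrow(dy), ncol(dy))
    dy %*% e$par$W
  }
  e
}
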