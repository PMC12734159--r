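# Independent brute-force oracles used across the suite. These deliberately
# reimplement each operation with plain loops so the tests do not share code
# paths with the implementations they check.

# Eq.-style valid convolution by quadruple loop.
brute_conv2d <- function(f, k) {
  M <- nrow(f); N <- ncol(f); r <- nrow(k); s <- ncol(k)
  out <- matrix(0, M - r + 1, N - s + 1)
  for (m in seq_len(M - r + 1)) for (n in seq_len(N - s + 1)) {
    acc <- 0
    for (p in seq_len(r)) for (q in seq_len(s)) {
      acc <- acc + f[m + p - 1, n + q - 1] * k[p, q]
    }
    out[m, n] <- acc
  }
  out
}

# Window-enumeration pooling.
brute_pool2d <- function(f, kind, window, stride) {
  window <- rep(window, length.out = 2)
  ho <- (nrow(f) - window[1]) %/% stride + 1
  wo <- (ncol(f) - window[2]) %/% stride + 1
  out <- matrix(0, ho, wo)
  for (i in seq_len(ho)) for (j in seq_len(wo)) {
    win <- f[(i - 1) * stride + seq_len(window[1]),
             (j - 1) * stride + seq_len(window[2])]
    out[i, j] <- if (kind == "max") max(win) else mean(win)
  }
  out
}

# Mann-Whitney AUC: fraction of (positive, negative) pairs ranked correctly,
# ties counted half.
rank_sum_auc <- function(labels, scores) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Evaluation-mode batch norm as a plain affine map from the layer's
# parameters and running statistics.
bn_eval_oracle <- function(x_c, layer, c_idx, eps = 1e-5) {
  g <- layer$par$gamma[c_idx]
  b <- layer$par$beta[c_idx]
  rm <- layer$buffers$running_mean[c_idx]
  rv <- layer$buffers$running_var[c_idx]
  g * (x_c - rm) / sqrt(rv + eps) + b
}

# Same-padding multi-channel convolution assembled from brute_conv2d,
# operating on one batch item of a (1, C, H, W) array.
brute_conv_same <- function(x, W, b, stride = 1) {
  Cout <- dim(W)[1]; Cin <- dim(W)[2]; kh <- dim(W)[3]; kw <- dim(W)[4]
  H <- dim(x)[3]; Wd <- dim(x)[4]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  Ho <- (H + 2 * ph - kh) %/% stride + 1
  Wo <- (Wd + 2 * pw - kw) %/% stride + 1
  out <- array(0, c(1, Cout, Ho, Wo))
  for (co in seq_len(Cout)) {
    acc <- matrix(b[co], H + 2 * ph - kh + 1, Wd + 2 * pw - kw + 1)
    for (ci in seq_len(Cin)) {
      xp <- matrix(0, H + 2 * ph, Wd + 2 * pw)
      xp[ph + seq_len(H), pw + seq_len(Wd)] <- x[1, ci, , ]
      acc <- acc + brute_conv2d(xp, matrix(W[co, ci, , ], kh, kw))
    }
    sel_r <- seq(1, nrow(acc), by = stride)[seq_len(Ho)]
    sel_c <- seq(1, ncol(acc), by = stride)[seq_len(Wo)]
    out[1, co, , ] <- acc[sel_r, sel_c]
  }
  out
}

# Set every trainable tensor of a module to a constant (default 0).
set_all_params <- function(module, value = 0) {
  for (p in stripfuse:::nn_parameters(module)) {
    p$env$par[[p$name]][] <- value
  }
  invisible(module)
}

# A tiny model configuration cheap enough for structural smoke tests.
tiny_model_config <- function(variant = "F") {
  model_config(image_side = 96L, spatial_widths = c(2L, 3L, 4L),
               residual_widths = c(4L, 6L, 6L, 8L), head_dim = 4L,
               dropout = 0.3, variant = variant)
}

# Bounding-box aspect ratio (long side / short side) of a logical mask.
mask_aspect <- function(mask) {
  rows <- range(which(apply(mask, 1, any)))
  cols <- range(which(apply(mask, 2, any)))
  h <- diff(rows) + 1
  w <- diff(cols) + 1
  max(h, w) / min(h, w)
}
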