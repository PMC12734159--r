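test_that("strip pooling means match brute-force row/column means", {
  set.seed(201)
  z <- array(rnorm(1 * 2 * 3 * 4), c(1, 2, 3, 4))
  h <- strip_pool_h(z)
  v <- strip_pool_v(z)
  for (c_idx in 1:2) {
    for (i in 1:3) expect_equal(h[1, c_idx, i], mean(z[1, c_idx, i, ]))
    for (j in 1:4) expect_equal(v[1, c_idx, j], mean(z[1, c_idx, , j]))
  }
  # constant map
  zc <- array(0.7, c(2, 3, 4, 5))
  expect_equal(as.vector(strip_pool_h(zc)), rep(0.7, 2 * 3 * 4))
  expect_equal(as.vector(strip_pool_v(zc)), rep(0.7, 2 * 3 * 5))
  # single hot pixel spreads 1/W into its row only
  z1 <- array(0, c(1, 1, 4, 5))
  z1[1, 1, 2, 3] <- 1
  expect_equal(as.vector(strip_pool_h(z1)), c(0, 1 / 5, 0, 0))
  # vertical pooling is horizontal pooling of the transpose
  expect_equal(strip_pool_v(z), strip_pool_h(aperm(z, c(1, 2, 4, 3))))
})

test_that("strip pooling transforms predictably under flips", {
  set.seed(202)
  for (rep in 1:5) {
    z <- array(rnorm(2 * 3 * 4 * 6), c(2, 3, 4, 6))
    zf <- z[, , , 6:1, drop = FALSE]  # horizontal flip
    expect_equal(strip_pool_h(zf), strip_pool_h(z))
    expect_equal(strip_pool_v(zf), strip_pool_v(z)[, , 6:1, drop = FALSE])
    zv <- z[, , 4:1, , drop = FALSE]  # vertical flip
    expect_equal(strip_pool_v(zv), strip_pool_v(z))
    expect_equal(strip_pool_h(zv), strip_pool_h(z)[, , 4:1, drop = FALSE])
  }
})

test_that("zero-weight strip attention gates at exactly one half", {
  set.seed(203)
  sa <- strip_attention(3)
  set_all_params(sa, 0)
  z <- array(rnorm(2 * 3 * 5 * 4), c(2, 3, 5, 4))
  expect_equal(sa$forward(z, training = FALSE), 0.5 * z)
  expect_equal(sa$forward(z, training = TRUE), 0.5 * z)
})

test_that("strip attention gate stays inside (0,1) and bounds the output", {
  set.seed(204)
  sa <- strip_attention(4)
  z <- array(rnorm(2 * 4 * 6 * 6), c(2, 4, 6, 6))
  out <- sa$forward(z, training = FALSE)
  expect_true(all(abs(out) < abs(z) | z == 0))
  expect_true(sum(out^2) < sum(z^2))
  g <- out / ifelse(z == 0, 1, z)
  g <- g[z != 0]
  expect_true(all(g > 0 & g < 1))
  expect_error(sa$forward(array(0, c(1, 4, 2, 5))), ">= 3")
})

test_that("strip attention equals step-by-step recomposition", {
  set.seed(205)
  conv1d_oracle <- function(p, W, b) {
    # p: (B, C, L); W: (Cout, Cin, 1, 3); zero padding
    B <- dim(p)[1]; C <- dim(p)[2]; L <- dim(p)[3]
    out <- array(0, c(B, dim(W)[1], L))
    for (bi in seq_len(B)) for (co in seq_len(dim(W)[1])) for (l in seq_len(L)) {
      acc <- b[co]
      for (ci in seq_len(C)) for (d in 1:3) {
        ll <- l + d - 2
        if (ll >= 1 && ll <= L) acc <- acc + W[co, ci, 1, d] * p[bi, ci, ll]
      }
      out[bi, co, l] <- acc
    }
    out
  }
  for (side in 4:8) {
    sa <- strip_attention(2)
    # non-neutral normalisation statistics
    sa$children$bn_h$buffers$running_mean <- c(0.1, -0.2)
    sa$children$bn_h$buffers$running_var <- c(1.2, 0.8)
    sa$children$bn_v$buffers$running_mean <- c(-0.05, 0.3)
    sa$children$bn_v$buffers$running_var <- c(0.9, 1.4)
    z <- array(rnorm(1 * 2 * side * side), c(1, 2, side, side))
    got <- sa$forward(z, training = FALSE)

    ph <- conv1d_oracle(strip_pool_h(z), sa$children$conv_h$par$W,
                        sa$children$conv_h$par$b)
    pv <- conv1d_oracle(strip_pool_v(z), sa$children$conv_v$par$W,
                        sa$children$conv_v$par$b)
    for (c_idx in 1:2) {
      ph[1, c_idx, ] <- bn_eval_oracle(ph[1, c_idx, ], sa$children$bn_h, c_idx)
      pv[1, c_idx, ] <- bn_eval_oracle(pv[1, c_idx, ], sa$children$bn_v, c_idx)
    }
    ref <- array(0, dim(z))
    Wm <- sa$children$conv_mix$par$W
    bm <- sa$children$conv_mix$par$b
    for (co in 1:2) for (i in seq_len(side)) for (j in seq_len(side)) {
      s1 <- ph[1, 1, i] + pv[1, 1, j]
      s2 <- ph[1, 2, i] + pv[1, 2, j]
      t <- Wm[co, 1, 1, 1] * s1 + Wm[co, 2, 1, 1] * s2 + bm[co]
      ref[1, co, i, j] <- z[1, co, i, j] / (1 + exp(-t))
    }
    expect_lt(max(abs(got - ref)), 1e-5)
  }
})

test_that("combo head is deterministic in evaluation mode", {
  set.seed(206)
  ch <- combo_head(3, dim = 5, dropout = 0.3)
  z <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
  out1 <- ch$forward(z, training = FALSE)
  out2 <- ch$forward(z, training = FALSE)
  expect_identical(out1, out2)
  expect_equal(dim(out1), c(2, 5))
})

test_that("combo head with full dropout reduces to the FC bias", {
  set.seed(207)
  ch <- combo_head(3, dim = 4, dropout = 1.0)
  z <- array(rnorm(1 * 3 * 4 * 4), c(1, 3, 4, 4))
  out <- ch$forward(z, training = TRUE)
  expect_equal(as.vector(out), ch$children$fc$par$b)
})

test_that("combo head closed-form trace: constant map, zero strip weights", {
  set.seed(208)
  ch <- combo_head(3, dim = 4, dropout = 0)
  set_all_params(ch$children$attn, 0)
  v <- 0.8
  z <- array(v, c(1, 3, 5, 5))
  out <- ch$forward(z, training = FALSE)
  # gate 0.5 everywhere -> pooled vector is 0.5 * v per channel -> FC
  fc <- ch$children$fc
  ref <- fc$par$W %*% rep(0.5 * v, 3) + fc$par$b
  expect_equal(as.vector(out), as.vector(ref))
})

test_that("gradients flow to every strip-attention parameter", {
  set.seed(209)
  sa <- strip_attention(2)
  z <- array(rnorm(2 * 2 * 4 * 4), c(2, 2, 4, 4))
  out <- sa$forward(z, training = TRUE)
  dy <- array(rnorm(length(out)), dim(out))
  nn_zero_grad(sa)
  invisible(sa$backward(dy))
  loss <- function() sum(sa$forward(z, training = TRUE) * dy)
  eps <- 1e-5
  for (p in stripfuse:::nn_parameters(sa)) {
    g <- p$env$grad[[p$name]]
    expect_gt(sum(abs(g)), 0)
    i <- which.max(abs(g))
    w0 <- p$env$par[[p$name]][i]
    p$env$par[[p$name]][i] <- w0 + eps; lp <- loss()
    p$env$par[[p$name]][i] <- w0 - eps; lm <- loss()
    p$env$par[[p$name]][i] <- w0
    expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})
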