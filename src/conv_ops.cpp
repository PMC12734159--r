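// Batched 2-D convolution kernels (im2col + GEMM) and a separable Gaussian
// blur. Feature maps are R arrays with dim c(B, C, H, W) in column-major
// order, i.e. element (b, c, h, w) sits at b + B*(c + C*(h + H*w)).
// Kernels are arrays with dim c(Cout, Cin, kh, kw), so the (Cout x K)
// GEMM matrix with K = Cin*kh*kw is a plain reshape of the kernel array.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Fill the im2col matrix col (K x N) with N = B*Ho*Wo, n = b + B*(ho + Ho*wo)
// and K = Cin*kh*kw, k = ci + Cin*(p + kh*q). Out-of-range taps are zero.
static void im2col_fill(const double* x, int B, int C, int H, int W,
                        int kh, int kw, int stride, int pad_h, int pad_w,
                        int Ho, int Wo, arma::mat& col) {
  const int K = C * kh * kw;
  double* cp = col.memptr();
  // writes every entry (zeros for out-of-range taps), so the caller never
  // needs a separate clearing pass and the buffer can be reused
  for (int wo = 0; wo < Wo; ++wo) {
    for (int q = 0; q < kw; ++q) {
      const int wim = wo * stride + q - pad_w;
      const bool wok = wim >= 0 && wim < W;
      for (int ho = 0; ho < Ho; ++ho) {
        const int n0 = B * (ho + Ho * wo);
        for (int p = 0; p < kh; ++p) {
          const int him = ho * stride + p - pad_h;
          const bool ok = wok && him >= 0 && him < H;
          for (int ci = 0; ci < C; ++ci) {
            const int k = ci + C * (p + kh * q);
            double* cs = cp + k + (std::size_t)K * n0;
            if (ok) {
              const double* xs = x + (std::size_t)B * (ci + (std::size_t)C * (him + (std::size_t)H * wim));
              for (int b = 0; b < B; ++b) cs[(std::size_t)K * b] = xs[b];
            } else {
              for (int b = 0; b < B; ++b) cs[(std::size_t)K * b] = 0.0;
            }
          }
        }
      }
    }
  }
}

// Scatter-add the K x N column matrix back onto the input gradient.
static void col2im_add(const arma::mat& col, double* dx,
                       int B, int C, int H, int W,
                       int kh, int kw, int stride, int pad_h, int pad_w,
                       int Ho, int Wo) {
  const int K = C * kh * kw;
  const double* cp = col.memptr();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int q = 0; q < kw; ++q) {
      const int wim = wo * stride + q - pad_w;
      if (wim < 0 || wim >= W) continue;
      for (int ho = 0; ho < Ho; ++ho) {
        const int n0 = B * (ho + Ho * wo);
        for (int p = 0; p < kh; ++p) {
          const int him = ho * stride + p - pad_h;
          if (him < 0 || him >= H) continue;
          for (int ci = 0; ci < C; ++ci) {
            const int k = ci + C * (p + kh * q);
            double* xs = dx + (std::size_t)B * (ci + (std::size_t)C * (him + (std::size_t)H * wim));
            const double* cs = cp + k + (std::size_t)K * n0;
            for (int b = 0; b < B; ++b) xs[b] += cs[(std::size_t)K * b];
          }
        }
      }
    }
  }
}

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector bias,
                                 int stride, int pad_h, int pad_w) {
  const int B = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Cout = wdim[0], Cin = wdim[1], kh = wdim[2], kw = wdim[3];
  if (Cin != C) stop("channel mismatch: input has %d channels, kernel expects %d", C, Cin);
  const int Ho = out_size(H, kh, stride, pad_h);
  const int Wo = out_size(W, kw, stride, pad_w);
  if (Ho < 1 || Wo < 1) stop("kernel larger than (padded) input");
  const int K = Cin * kh * kw;
  const std::size_t N = (std::size_t)B * Ho * Wo;

  arma::mat col(K, N);
  im2col_fill(x.begin(), B, C, H, W, kh, kw, stride, pad_h, pad_w, Ho, Wo, col);
  const arma::mat Wm(const_cast<double*>(w.begin()), Cout, K, false, true);
  arma::mat Y = Wm * col;  // Cout x N

  NumericVector out((std::size_t)Cout * N);
  double* yp = out.begin();
  const double* Yp = Y.memptr();
  const double* bp = bias.begin();
  // y[b, co, ho, wo] at b + B*(co + Cout*(ho + Ho*wo)); Y(co, n) with
  // n = b + B*(ho + Ho*wo).
  for (std::size_t n = 0; n < N; ++n) {
    const std::size_t b = n % B, s = n / B;  // s = ho + Ho*wo
    double* yo = yp + b + (std::size_t)B * Cout * s;
    const double* Yc = Yp + (std::size_t)Cout * n;
    for (int co = 0; co < Cout; ++co) yo[(std::size_t)B * co] = Yc[co] + bp[co];
  }
  out.attr("dim") = IntegerVector::create(B, Cout, Ho, Wo);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector dy,
                         int stride, int pad_h, int pad_w) {
  const int B = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Cout = wdim[0], Cin = wdim[1], kh = wdim[2], kw = wdim[3];
  const int Ho = out_size(H, kh, stride, pad_h);
  const int Wo = out_size(W, kw, stride, pad_w);
  const int K = Cin * kh * kw;
  const std::size_t N = (std::size_t)B * Ho * Wo;

  arma::mat col(K, N);
  im2col_fill(x.begin(), B, C, H, W, kh, kw, stride, pad_h, pad_w, Ho, Wo, col);

  // Gather dy (dim B,Cout,Ho,Wo) into the Cout x N layout used by the GEMMs.
  arma::mat dYm(Cout, N);
  {
    const double* dp = dy.begin();
    double* Dp = dYm.memptr();
    for (std::size_t n = 0; n < N; ++n) {
      const std::size_t b = n % B, s = n / B;
      const double* dyo = dp + b + (std::size_t)B * Cout * s;
      double* Dc = Dp + (std::size_t)Cout * n;
      for (int co = 0; co < Cout; ++co) Dc[co] = dyo[(std::size_t)B * co];
    }
  }

  arma::mat dWm = dYm * col.t();          // Cout x K, same layout as w
  arma::vec dbv = arma::sum(dYm, 1);      // Cout
  const arma::mat Wm(const_cast<double*>(w.begin()), Cout, K, false, true);
  arma::mat dcol = Wm.t() * dYm;          // K x N

  NumericVector dx((std::size_t)B * C * H * W);
  std::fill(dx.begin(), dx.end(), 0.0);
  col2im_add(dcol, dx.begin(), B, C, H, W, kh, kw, stride, pad_h, pad_w, Ho, Wo);
  dx.attr("dim") = xdim;

  NumericVector dw(dWm.memptr(), dWm.memptr() + (std::size_t)Cout * K);
  dw.attr("dim") = wdim;
  NumericVector db(dbv.memptr(), dbv.memptr() + Cout);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Separable Gaussian blur of a single H x W matrix, kernel truncated at
// three standard deviations, reflecting boundaries.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;

  auto reflect = [](int i, int n) {
    // reflect-101-free simple mirroring: ... 2 1 0 | 0 1 2 ... | n-1 n-1 ...
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - i - 1;
    }
    return i;
  };

  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * img(reflect(i + d, H), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * tmp(i, reflect(j + d, W));
      out(i, j) = acc;
    }
  return out;
}

// Forward pass that fills a caller-owned im2col buffer (reused across
// steps) so the backward pass can skip rebuilding it. `colR` must already
// have the right dimensions (K x B*Ho*Wo).
// [[Rcpp::export]]
NumericVector cpp_conv2d_forward_fill(NumericVector x, IntegerVector xdim,
                                      NumericVector w, IntegerVector wdim,
                                      NumericVector bias,
                                      int stride, int pad_h, int pad_w,
                                      NumericMatrix colR) {
  const int B = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Cout = wdim[0], Cin = wdim[1], kh = wdim[2], kw = wdim[3];
  if (Cin != C) stop("channel mismatch: input has %d channels, kernel expects %d", C, Cin);
  const int Ho = out_size(H, kh, stride, pad_h);
  const int Wo = out_size(W, kw, stride, pad_w);
  if (Ho < 1 || Wo < 1) stop("kernel larger than (padded) input");
  const int K = Cin * kh * kw;
  const std::size_t N = (std::size_t)B * Ho * Wo;
  if ((std::size_t)colR.nrow() != (std::size_t)K || (std::size_t)colR.ncol() != N) {
    stop("im2col buffer has the wrong shape");
  }
  arma::mat col(colR.begin(), K, N, false, true);
  im2col_fill(x.begin(), B, C, H, W, kh, kw, stride, pad_h, pad_w, Ho, Wo, col);
  const arma::mat Wm(const_cast<double*>(w.begin()), Cout, K, false, true);
  arma::mat Y = Wm * col;

  NumericVector out((std::size_t)Cout * N);
  double* yp = out.begin();
  const double* Yp = Y.memptr();
  const double* bp = bias.begin();
  for (std::size_t n = 0; n < N; ++n) {
    const std::size_t b = n % B, s = n / B;
    double* yo = yp + b + (std::size_t)B * Cout * s;
    const double* Yc = Yp + (std::size_t)Cout * n;
    for (int co = 0; co < Cout; ++co) yo[(std::size_t)B * co] = Yc[co] + bp[co];
  }
  out.attr("dim") = IntegerVector::create(B, Cout, Ho, Wo);
  return out;
}

// Backward pass reusing a cached im2col matrix.
// [[Rcpp::export]]
List cpp_conv2d_backward_cached(NumericMatrix colR, IntegerVector xdim,
                                NumericVector w, IntegerVector wdim,
                                NumericVector dy,
                                int stride, int pad_h, int pad_w) {
  const int B = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Cout = wdim[0], Cin = wdim[1], kh = wdim[2], kw = wdim[3];
  const int Ho = out_size(H, kh, stride, pad_h);
  const int Wo = out_size(W, kw, stride, pad_w);
  const int K = Cin * kh * kw;
  const std::size_t N = (std::size_t)B * Ho * Wo;
  const arma::mat col(colR.begin(), K, N, false, true);

  arma::mat dYm(Cout, N);
  {
    const double* dp = dy.begin();
    double* Dp = dYm.memptr();
    for (std::size_t n = 0; n < N; ++n) {
      const std::size_t b = n % B, s = n / B;
      const double* dyo = dp + b + (std::size_t)B * Cout * s;
      double* Dc = Dp + (std::size_t)Cout * n;
      for (int co = 0; co < Cout; ++co) Dc[co] = dyo[(std::size_t)B * co];
    }
  }
  arma::mat dWm = dYm * col.t();
  arma::vec dbv = arma::sum(dYm, 1);
  const arma::mat Wm(const_cast<double*>(w.begin()), Cout, K, false, true);
  arma::mat dcol = Wm.t() * dYm;

  NumericVector dx((std::size_t)B * C * H * W);
  std::fill(dx.begin(), dx.end(), 0.0);
  col2im_add(dcol, dx.begin(), B, C, H, W, kh, kw, stride, pad_h, pad_w, Ho, Wo);
  dx.attr("dim") = xdim;
  NumericVector dw(dWm.memptr(), dWm.memptr() + (std::size_t)Cout * K);
  dw.attr("dim") = wdim;
  NumericVector db(dbv.memptr(), dbv.memptr() + Cout);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Per-channel sums and sums of squares of a (B, C, ...) array in one pass.
// [[Rcpp::export]]
List cpp_channel_stats(NumericVector x, int B, int C) {
  const std::size_t S = x.size() / ((std::size_t)B * C);
  NumericVector sum(C), sumsq(C);
  const double* xp = x.begin();
  for (std::size_t s = 0; s < S; ++s) {
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + (std::size_t)B * (c + (std::size_t)C * s);
      double acc = 0.0, acc2 = 0.0;
      for (int b = 0; b < B; ++b) { acc += xs[b]; acc2 += xs[b] * xs[b]; }
      sum[c] += acc;
      sumsq[c] += acc2;
    }
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq);
}

// Elementwise per-channel affine map y = a[c] * x + b[c] on a (B, C, ...)
// array.
// [[Rcpp::export]]
NumericVector cpp_affine_channels(NumericVector x, int B, int C,
                                  NumericVector a, NumericVector b) {
  const std::size_t n = x.size();
  const std::size_t S = n / ((std::size_t)B * C);
  NumericVector y(n);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (std::size_t s = 0; s < S; ++s) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)B * (c + (std::size_t)C * s);
      const double ac = a[c], bc = b[c];
      for (int b2 = 0; b2 < B; ++b2) yp[off + b2] = ac * xp[off + b2] + bc;
    }
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// Per-channel sums of dy and of dy * xn in one pass (batch-norm backward).
// [[Rcpp::export]]
List cpp_bn_grad_stats(NumericVector dy, NumericVector xn, int B, int C) {
  const std::size_t S = dy.size() / ((std::size_t)B * C);
  NumericVector sdy(C), sdyxn(C);
  const double* dp = dy.begin();
  const double* np = xn.begin();
  for (std::size_t s = 0; s < S; ++s) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)B * (c + (std::size_t)C * s);
      double a = 0.0, b = 0.0;
      for (int b2 = 0; b2 < B; ++b2) {
        a += dp[off + b2];
        b += dp[off + b2] * np[off + b2];
      }
      sdy[c] += a;
      sdyxn[c] += b;
    }
  }
  return List::create(_["sum_dy"] = sdy, _["sum_dyxn"] = sdyxn);
}

// dx = scale[c] * (dy - t1[c] - xn * t2[c])
// [[Rcpp::export]]
NumericVector cpp_bn_dx(NumericVector dy, NumericVector xn,
                        NumericVector scale, NumericVector t1,
                        NumericVector t2, int B, int C) {
  const std::size_t n = dy.size();
  const std::size_t S = n / ((std::size_t)B * C);
  NumericVector dx(n);
  const double* dp = dy.begin();
  const double* np = xn.begin();
  double* op = dx.begin();
  for (std::size_t s = 0; s < S; ++s) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)B * (c + (std::size_t)C * s);
      const double sc = scale[c], a = t1[c], b = t2[c];
      for (int b2 = 0; b2 < B; ++b2) {
        op[off + b2] = sc * (dp[off + b2] - a - np[off + b2] * b);
      }
    }
  }
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const std::size_t n = x.size();
  for (std::size_t i = 0; i < n; ++i) yp[i] = xp[i] > 0.0 ? xp[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector dy, NumericVector x) {
  NumericVector dx(dy.size());
  const double* dp = dy.begin();
  const double* xp = x.begin();
  double* op = dx.begin();
  const std::size_t n = dy.size();
  for (std::size_t i = 0; i < n; ++i) op[i] = xp[i] > 0.0 ? dp[i] : 0.0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

#include <dlfcn.h>

// Pin OpenBLAS to a fixed thread count when available; on a single core the
// threaded GEMM path loses to the serial one through scheduling overhead.
// [[Rcpp::export]]
bool cpp_set_blas_threads(int n) {
  typedef void (*fn_t)(int);
  fn_t f = (fn_t)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (f == nullptr) return false;
  f(n);
  return true;
}

// 2x2 stride-2 max pooling with argmax indices (1-based, position in the
// 2x2 window: 1=tl, 2=bl, 3=tr, 4=br matching the R slice order).
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x, IntegerVector xdim) {
  const int B = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  const std::size_t n_out = (std::size_t)B * C * Ho * Wo;
  NumericVector y(n_out);
  IntegerVector idx(n_out);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  const std::size_t BC = (std::size_t)B * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* a = xp + BC * (2 * ho + (std::size_t)H * (2 * wo));
      const double* b = xp + BC * (2 * ho + 1 + (std::size_t)H * (2 * wo));
      const double* c = xp + BC * (2 * ho + (std::size_t)H * (2 * wo + 1));
      const double* d = xp + BC * (2 * ho + 1 + (std::size_t)H * (2 * wo + 1));
      double* yo = yp + BC * (ho + (std::size_t)Ho * wo);
      int* io = ip + BC * (ho + (std::size_t)Ho * wo);
      for (std::size_t k = 0; k < BC; ++k) {
        double best = a[k]; int bi = 1;
        if (b[k] > best) { best = b[k]; bi = 2; }
        if (c[k] > best) { best = c[k]; bi = 3; }
        if (d[k] > best) { best = d[k]; bi = 4; }
        yo[k] = best;
        io[k] = bi;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(B, C, Ho, Wo);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector idx,
                                    IntegerVector xdim) {
  const int B = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((std::size_t)B * C * H * W);
  std::fill(dx.begin(), dx.end(), 0.0);
  const double* dp = dy.begin();
  const int* ip = idx.begin();
  double* op = dx.begin();
  const std::size_t BC = (std::size_t)B * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* dyo = dp + BC * (ho + (std::size_t)Ho * wo);
      const int* io = ip + BC * (ho + (std::size_t)Ho * wo);
      double* a = op + BC * (2 * ho + (std::size_t)H * (2 * wo));
      double* b = op + BC * (2 * ho + 1 + (std::size_t)H * (2 * wo));
      double* c = op + BC * (2 * ho + (std::size_t)H * (2 * wo + 1));
      double* d = op + BC * (2 * ho + 1 + (std::size_t)H * (2 * wo + 1));
      for (std::size_t k = 0; k < BC; ++k) {
        switch (io[k]) {
          case 1: a[k] += dyo[k]; break;
          case 2: b[k] += dyo[k]; break;
          case 3: c[k] += dyo[k]; break;
          default: d[k] += dyo[k];
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_forward(NumericVector x, IntegerVector xdim) {
  const int B = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::size_t)B * C * Ho * Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  const std::size_t BC = (std::size_t)B * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* a = xp + BC * (2 * ho + (std::size_t)H * (2 * wo));
      const double* b = xp + BC * (2 * ho + 1 + (std::size_t)H * (2 * wo));
      const double* c = xp + BC * (2 * ho + (std::size_t)H * (2 * wo + 1));
      const double* d = xp + BC * (2 * ho + 1 + (std::size_t)H * (2 * wo + 1));
      double* yo = yp + BC * (ho + (std::size_t)Ho * wo);
      for (std::size_t k = 0; k < BC; ++k) {
        yo[k] = 0.25 * (a[k] + b[k] + c[k] + d[k]);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(B, C, Ho, Wo);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_backward(NumericVector dy, IntegerVector xdim) {
  const int B = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((std::size_t)B * C * H * W);
  const double* dp = dy.begin();
  double* op = dx.begin();
  const std::size_t BC = (std::size_t)B * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* dyo = dp + BC * (ho + (std::size_t)Ho * wo);
      double* a = op + BC * (2 * ho + (std::size_t)H * (2 * wo));
      double* b = op + BC * (2 * ho + 1 + (std::size_t)H * (2 * wo));
      double* c = op + BC * (2 * ho + (std::size_t)H * (2 * wo + 1));
      double* d = op + BC * (2 * ho + 1 + (std::size_t)H * (2 * wo + 1));
      for (std::size_t k = 0; k < BC; ++k) {
        const double v = 0.25 * dyo[k];
        a[k] = v; b[k] = v; c[k] = v; d[k] = v;
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Weight/bias gradients only — for the first layer, whose input gradient
// nothing consumes.
// [[Rcpp::export]]
List cpp_conv2d_backward_nodx(NumericMatrix colR, IntegerVector xdim,
                              IntegerVector wdim, NumericVector dy,
                              int stride, int pad_h, int pad_w) {
  const int B = xdim[0], H = xdim[2], W = xdim[3];
  const int Cout = wdim[0], Cin = wdim[1], kh = wdim[2], kw = wdim[3];
  const int Ho = out_size(H, kh, stride, pad_h);
  const int Wo = out_size(W, kw, stride, pad_w);
  const int K = Cin * kh * kw;
  const std::size_t N = (std::size_t)B * Ho * Wo;
  const arma::mat col(colR.begin(), K, N, false, true);
  arma::mat dYm(Cout, N);
  {
    const double* dp = dy.begin();
    double* Dp = dYm.memptr();
    for (std::size_t n = 0; n < N; ++n) {
      const std::size_t b = n % B, s = n / B;
      const double* dyo = dp + b + (std::size_t)B * Cout * s;
      double* Dc = Dp + (std::size_t)Cout * n;
      for (int co = 0; co < Cout; ++co) Dc[co] = dyo[(std::size_t)B * co];
    }
  }
  arma::mat dWm = dYm * col.t();
  arma::vec dbv = arma::sum(dYm, 1);
  NumericVector dw(dWm.memptr(), dWm.memptr() + (std::size_t)Cout * K);
  dw.attr("dim") = wdim;
  NumericVector db(dbv.memptr(), dbv.memptr() + Cout);
  return List::create(_["dw"] = dw, _["db"] = db);
}

// Bilinear rotation about the image centre, zero outside the source.
// Matches the documented (row, column) convention: positive angles rotate
// counter-clockwise.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_bilinear(NumericMatrix img, double angle_deg) {
  const int H = img.nrow(), W = img.ncol();
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cr = (H + 1) / 2.0, cc = (W + 1) / 2.0;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    const double tc = (j + 1) - cc;
    for (int i = 0; i < H; ++i) {
      const double tr = (i + 1) - cr;
      const double sr = ct * tr + st * tc + cr;
      const double sc = -st * tr + ct * tc + cc;
      const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      const double fr = sr - r0, fc = sc - c0;
      auto at = [&](int ri, int ci) -> double {
        if (ri < 1 || ri > H || ci < 1 || ci > W) return 0.0;
        return img(ri - 1, ci - 1);
      };
      out(i, j) = (1 - fr) * (1 - fc) * at(r0, c0) +
                  fr * (1 - fc) * at(r0 + 1, c0) +
                  (1 - fr) * fc * at(r0, c0 + 1) +
                  fr * fc * at(r0 + 1, c0 + 1);
    }
  }
  return out;
}
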