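// Low-level tensor kernels for the attention-augmented mobile-bottleneck
// network. Tensors are R arrays with dim = c(H, W, C, N), column-major, so
// element (h, w, c, n) sits at h + H*(w + W*(c + C*n)) (0-based).
// Convolution weights: dim = c(kh, kw, Cin, Cout); depthwise: c(k, k, C).
// All heavy linear algebra is routed through BLAS via Armadillo.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Training allocates and frees many ~10-100 MB tensors per minibatch. With
// glibc's default mmap threshold every one is a fresh mmap/munmap pair, so
// the process spends most of its time page-faulting. Raising the mmap
// threshold keeps those blocks on the heap for reuse; a moderate trim
// threshold still returns large idle stretches to the kernel so peak
// memory stays bounded.
// [[Rcpp::export(name = ".cpp_tune_allocator")]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 768 << 20);
#endif
}

static inline IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d tensor (H, W, C, N)");
  return d;
}

// zero = false skips initialization: only for outputs that every code path
// fully overwrites; accumulator outputs must pass zero = true.
static inline NumericVector make4(int H, int W, int C, int N, bool zero = false) {
  R_xlen_t len = static_cast<R_xlen_t>(H) * W * C * N;
  NumericVector y = zero ? NumericVector(len) : NumericVector(no_init(len));
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// ---------------------------------------------------------------- im2col ---

// col is K x (Ho*Wo) with K = kh*kw*Cin; row index ki + kh*(kj + kw*c),
// column index oh + Ho*ow.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + static_cast<size_t>(c) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* dst = col + static_cast<size_t>(ki + kh * (kj + kw * c));
        const size_t K = static_cast<size_t>(kh) * kw * C;
        for (int ow = 0; ow < Wo; ++ow) {
          int win = ow * stride - pad + kj;
          for (int oh = 0; oh < Ho; ++oh) {
            int hin = oh * stride - pad + ki;
            double v = 0.0;
            if (hin >= 0 && hin < H && win >= 0 && win < W)
              v = xc[hin + static_cast<size_t>(win) * H];
            dst[K * (oh + static_cast<size_t>(Ho) * ow)] = v;
          }
        }
      }
    }
  }
}

static void col2im_acc(const double* col, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, double* x) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + static_cast<size_t>(c) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* src = col + static_cast<size_t>(ki + kh * (kj + kw * c));
        const size_t K = static_cast<size_t>(kh) * kw * C;
        for (int ow = 0; ow < Wo; ++ow) {
          int win = ow * stride - pad + kj;
          if (win < 0 || win >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            int hin = oh * stride - pad + ki;
            if (hin < 0 || hin >= H) continue;
            xc[hin + static_cast<size_t>(win) * H] +=
              src[K * (oh + static_cast<size_t>(Ho) * ow)];
          }
        }
      }
    }
  }
}

// ----------------------------------------------------------- conv2d ---

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be (kh, kw, Cin, Cout)");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv2d");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d output would be empty");
  NumericVector y = make4(Ho, Wo, Cout, N);

  arma::vec b;
  bool has_b = bias.isNotNull();
  if (has_b) b = as<arma::vec>(bias.get());

  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    // pointwise: per sample (H*W, Cin) %*% (Cin, Cout)
    arma::mat Wm(const_cast<double*>(w.begin()), Cin, Cout, false, true);
    size_t hw = static_cast<size_t>(H) * W;
    for (int n = 0; n < N; ++n) {
      arma::mat Xn(const_cast<double*>(x.begin()) + hw * C * n, hw, Cin, false, true);
      arma::mat Yn(y.begin() + hw * Cout * n, hw, Cout, false, true);
      Yn = Xn * Wm;
      if (has_b) Yn.each_row() += b.t();
    }
    return y;
  }

  size_t K = static_cast<size_t>(kh) * kw * C;
  size_t P = static_cast<size_t>(Ho) * Wo;
  arma::mat col(K, P);
  // weight matrix: (K, Cout)
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + static_cast<size_t>(H) * W * C * n,
           H, W, C, kh, kw, stride, pad, Ho, Wo, col.memptr());
    // Yn: (P, Cout) laid out exactly as the (Ho, Wo, Cout) slab
    arma::mat Yn(y.begin() + P * Cout * n, P, Cout, false, true);
    Yn = col.t() * Wm;
    if (has_b) Yn.each_row() += b.t();
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, bool has_bias) {
  IntegerVector xd = dims4(x), wd = w.attr("dim"), yd = dims4(dy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx = make4(H, W, C, N, true);
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(Cout);

  size_t P = static_cast<size_t>(Ho) * Wo;
  arma::mat dWm(dw.begin(), static_cast<size_t>(kh) * kw * C, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);

  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    arma::mat Wm(const_cast<double*>(w.begin()), C, Cout, false, true);
    size_t hw = static_cast<size_t>(H) * W;
    for (int n = 0; n < N; ++n) {
      arma::mat Xn(const_cast<double*>(x.begin()) + hw * C * n, hw, C, false, true);
      arma::mat dYn(const_cast<double*>(dy.begin()) + hw * Cout * n, hw, Cout, false, true);
      arma::mat dXn(dx.begin() + hw * C * n, hw, C, false, true);
      dXn = dYn * Wm.t();
      dWm += Xn.t() * dYn;
      if (has_bias) dbv += arma::sum(dYn, 0).t();
    }
  } else {
    size_t K = static_cast<size_t>(kh) * kw * C;
    arma::mat col(K, P), dcol(K, P);
    arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
    for (int n = 0; n < N; ++n) {
      im2col(x.begin() + static_cast<size_t>(H) * W * C * n,
             H, W, C, kh, kw, stride, pad, Ho, Wo, col.memptr());
      arma::mat dYn(const_cast<double*>(dy.begin()) + P * Cout * n, P, Cout, false, true);
      dWm += col * dYn;
      dcol = Wm * dYn.t();
      col2im_acc(dcol.memptr(), H, W, C, kh, kw, stride, pad, Ho, Wo,
                 dx.begin() + static_cast<size_t>(H) * W * C * n);
      if (has_bias) dbv += arma::sum(dYn, 0).t();
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// --------------------------------------------------------- depthwise ---

// [[Rcpp::export(name = ".cpp_dwconv_fwd")]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w,
                             int stride, int pad) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 3) stop("depthwise weights must be (k, k, C)");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("channel mismatch in depthwise conv");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector y = make4(Ho, Wo, C, N);
  // copy each channel slice into a zero-padded buffer once, then run the
  // inner taps without bounds checks
  int Hp = H + 2 * pad, Wp = W + 2 * pad;
  std::vector<double> padBuf(static_cast<size_t>(Hp) * Wp, 0.0);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + static_cast<size_t>(H) * W * (c + static_cast<size_t>(C) * n);
      const double* wc = w.begin() + static_cast<size_t>(kh) * kw * c;
      double* yc = y.begin() + static_cast<size_t>(Ho) * Wo * (c + static_cast<size_t>(C) * n);
      for (int col = 0; col < W; ++col)
        std::copy(xc + static_cast<size_t>(col) * H,
                  xc + static_cast<size_t>(col) * H + H,
                  padBuf.data() + pad + static_cast<size_t>(col + pad) * Hp);
      for (int ow = 0; ow < Wo; ++ow) {
        const double* base = padBuf.data() + static_cast<size_t>(ow) * stride * Hp;
        double* ycol = yc + static_cast<size_t>(Ho) * ow;
        for (int oh = 0; oh < Ho; ++oh) {
          const double* px = base + oh * stride;
          double acc = 0.0;
          for (int kj = 0; kj < kw; ++kj) {
            const double* pc = px + static_cast<size_t>(kj) * Hp;
            for (int ki = 0; ki < kh; ++ki)
              acc += pc[ki] * wc[ki + kh * kj];
          }
          ycol[oh] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_dwconv_bwd")]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = dims4(x), wd = w.attr("dim"), yd = dims4(dy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx = make4(H, W, C, N);
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  int Hp = H + 2 * pad, Wp = W + 2 * pad;
  std::vector<double> padX(static_cast<size_t>(Hp) * Wp, 0.0);
  std::vector<double> padDX(static_cast<size_t>(Hp) * Wp);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + static_cast<size_t>(H) * W * (c + static_cast<size_t>(C) * n);
      const double* wc = w.begin() + static_cast<size_t>(kh) * kw * c;
      const double* dyc = dy.begin() + static_cast<size_t>(Ho) * Wo * (c + static_cast<size_t>(C) * n);
      double* dxc = dx.begin() + static_cast<size_t>(H) * W * (c + static_cast<size_t>(C) * n);
      double* dwc = dw.begin() + static_cast<size_t>(kh) * kw * c;
      for (int col = 0; col < W; ++col)
        std::copy(xc + static_cast<size_t>(col) * H,
                  xc + static_cast<size_t>(col) * H + H,
                  padX.data() + pad + static_cast<size_t>(col + pad) * Hp);
      std::fill(padDX.begin(), padDX.end(), 0.0);
      double dwloc[49] = {0.0};           // k <= 7
      for (int ow = 0; ow < Wo; ++ow) {
        const double* xbase = padX.data() + static_cast<size_t>(ow) * stride * Hp;
        double* dxbase = padDX.data() + static_cast<size_t>(ow) * stride * Hp;
        const double* dycol = dyc + static_cast<size_t>(Ho) * ow;
        for (int oh = 0; oh < Ho; ++oh) {
          double g = dycol[oh];
          if (g == 0.0) continue;
          const double* px = xbase + oh * stride;
          double* pdx = dxbase + oh * stride;
          for (int kj = 0; kj < kw; ++kj) {
            const double* pxc = px + static_cast<size_t>(kj) * Hp;
            double* pdxc = pdx + static_cast<size_t>(kj) * Hp;
            double* dwk = dwloc + kh * kj;
            for (int ki = 0; ki < kh; ++ki) {
              pdxc[ki] += g * wc[ki + kh * kj];
              dwk[ki] += g * pxc[ki];
            }
          }
        }
      }
      for (int k = 0; k < kh * kw; ++k) dwc[k] += dwloc[k];
      for (int col = 0; col < W; ++col)
        std::copy(padDX.data() + pad + static_cast<size_t>(col + pad) * Hp,
                  padDX.data() + pad + static_cast<size_t>(col + pad) * Hp + H,
                  dxc + static_cast<size_t>(col) * H);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ---------------------------------------------------------- batchnorm ---

// [[Rcpp::export(name = ".cpp_bn_stats")]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = static_cast<size_t>(H) * W;
  double m = static_cast<double>(hw) * N;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + hw * (c + static_cast<size_t>(C) * n);
      for (size_t i = 0; i < hw; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    mu[c] = s / m;
    var[c] = s2 / m - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export(name = ".cpp_bn_apply")]]
NumericVector cpp_bn_apply(NumericVector x, NumericVector mu, NumericVector var,
                           NumericVector gamma, NumericVector beta, double eps) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = static_cast<size_t>(H) * W;
  NumericVector y = make4(H, W, C, N);
  for (int c = 0; c < C; ++c) {
    double inv = gamma[c] / std::sqrt(var[c] + eps);
    double off = beta[c] - mu[c] * inv;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + hw * (c + static_cast<size_t>(C) * n);
      double* yc = y.begin() + hw * (c + static_cast<size_t>(C) * n);
      for (size_t i = 0; i < hw; ++i) yc[i] = xc[i] * inv + off;
    }
  }
  return y;
}

// Training-mode backward (batch statistics were used in the forward pass).
// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, NumericVector mu,
                NumericVector var, NumericVector gamma, double eps) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = static_cast<size_t>(H) * W;
  double m = static_cast<double>(hw) * N;
  NumericVector dx = make4(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double sdy = 0.0, sdyxh = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + hw * (c + static_cast<size_t>(C) * n);
      const double* dyc = dy.begin() + hw * (c + static_cast<size_t>(C) * n);
      for (size_t i = 0; i < hw; ++i) {
        double xh = (xc[i] - mu[c]) * inv;
        sdy += dyc[i];
        sdyxh += dyc[i] * xh;
      }
    }
    dgamma[c] = sdyxh;
    dbeta[c] = sdy;
    double k = gamma[c] * inv / m;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + hw * (c + static_cast<size_t>(C) * n);
      const double* dyc = dy.begin() + hw * (c + static_cast<size_t>(C) * n);
      double* dxc = dx.begin() + hw * (c + static_cast<size_t>(C) * n);
      for (size_t i = 0; i < hw; ++i) {
        double xh = (xc[i] - mu[c]) * inv;
        dxc[i] = k * (m * dyc[i] - sdy - xh * sdyxh);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// --------------------------------------------------------- activations ---

// forward value, optionally also the sigmoid (cached for backward during
// training so the backward pass needs no second exp sweep)
// [[Rcpp::export(name = ".cpp_silu_fwd")]]
SEXP cpp_silu_fwd(NumericVector x, bool want_sig = false) {
  const R_xlen_t n = x.size();
  NumericVector y(no_init(n));
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  if (!want_sig) {
    for (R_xlen_t i = 0; i < n; ++i)
      yp[i] = xp[i] / (1.0 + std::exp(-xp[i]));
    return y;
  }
  NumericVector sig(no_init(n));
  double* sp = sig.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double s = 1.0 / (1.0 + std::exp(-xp[i]));
    sp[i] = s;
    yp[i] = xp[i] * s;
  }
  return List::create(_["y"] = y, _["sig"] = sig);
}

// [[Rcpp::export(name = ".cpp_silu_bwd")]]
NumericVector cpp_silu_bwd(NumericVector dy, NumericVector x,
                           Nullable<NumericVector> sig = R_NilValue) {
  const R_xlen_t n = x.size();
  NumericVector dx(no_init(n));
  dx.attr("dim") = x.attr("dim");
  const double* dyp = dy.begin();
  const double* xp = x.begin();
  double* dxp = dx.begin();
  if (sig.isNotNull()) {
    NumericVector sv(sig.get());
    const double* sp = sv.begin();
    for (R_xlen_t i = 0; i < n; ++i)
      dxp[i] = dyp[i] * sp[i] * (1.0 + xp[i] * (1.0 - sp[i]));
  } else {
    for (R_xlen_t i = 0; i < n; ++i) {
      double s = 1.0 / (1.0 + std::exp(-xp[i]));
      dxp[i] = dyp[i] * s * (1.0 + xp[i] * (1.0 - s));
    }
  }
  return dx;
}

// ------------------------------------------------------------- pooling ---

// global average pool over H, W -> (C, N)
// [[Rcpp::export(name = ".cpp_gap_fwd")]]
NumericMatrix cpp_gap_fwd(NumericVector x) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = static_cast<size_t>(H) * W;
  NumericMatrix out(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + hw * (c + static_cast<size_t>(C) * n);
      double s = 0.0;
      for (size_t i = 0; i < hw; ++i) s += xc[i];
      out(c, n) = s / hw;
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_gap_bwd")]]
NumericVector cpp_gap_bwd(NumericMatrix ds, int H, int W) {
  int C = ds.nrow(), N = ds.ncol();
  size_t hw = static_cast<size_t>(H) * W;
  NumericVector dx = make4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double v = ds(c, n) / hw;
      double* dxc = dx.begin() + hw * (c + static_cast<size_t>(C) * n);
      for (size_t i = 0; i < hw; ++i) dxc[i] = v;
    }
  return dx;
}

// global max pool over H, W -> values (C, N) and 0-based argmax within H*W
// [[Rcpp::export(name = ".cpp_gmax_fwd")]]
List cpp_gmax_fwd(NumericVector x) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = static_cast<size_t>(H) * W;
  NumericMatrix val(C, N);
  IntegerMatrix idx(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + hw * (c + static_cast<size_t>(C) * n);
      double best = xc[0]; size_t bi = 0;
      for (size_t i = 1; i < hw; ++i)
        if (xc[i] > best) { best = xc[i]; bi = i; }
      val(c, n) = best;
      idx(c, n) = static_cast<int>(bi);
    }
  return List::create(_["val"] = val, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_gmax_bwd")]]
NumericVector cpp_gmax_bwd(NumericMatrix dval, IntegerMatrix idx, int H, int W) {
  int C = dval.nrow(), N = dval.ncol();
  size_t hw = static_cast<size_t>(H) * W;
  NumericVector dx = make4(H, W, C, N, true);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      dx[hw * (c + static_cast<size_t>(C) * n) + idx(c, n)] += dval(c, n);
  return dx;
}

// channel-wise mean/max -> (H, W, 2, N); idx holds 0-based argmax channel
// [[Rcpp::export(name = ".cpp_chpool_fwd")]]
List cpp_chpool_fwd(NumericVector x) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = static_cast<size_t>(H) * W;
  NumericVector out = make4(H, W, 2, N);
  IntegerVector idx(static_cast<R_xlen_t>(hw) * N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + hw * C * static_cast<size_t>(n);
    double* avg = out.begin() + hw * 2 * static_cast<size_t>(n);
    double* mx = avg + hw;
    int* ix = idx.begin() + hw * static_cast<size_t>(n);
    for (size_t i = 0; i < hw; ++i) {
      double s = xn[i], best = xn[i]; int bc = 0;
      for (int c = 1; c < C; ++c) {
        double v = xn[i + hw * c];
        s += v;
        if (v > best) { best = v; bc = c; }
      }
      avg[i] = s / C;
      mx[i] = best;
      ix[i] = bc;
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_chpool_bwd")]]
NumericVector cpp_chpool_bwd(NumericVector dout, IntegerVector idx, int C) {
  IntegerVector yd = dims4(dout);
  int H = yd[0], W = yd[1], N = yd[3];
  size_t hw = static_cast<size_t>(H) * W;
  NumericVector dx = make4(H, W, C, N, true);
  for (int n = 0; n < N; ++n) {
    const double* davg = dout.begin() + hw * 2 * static_cast<size_t>(n);
    const double* dmx = davg + hw;
    const int* ix = idx.begin() + hw * static_cast<size_t>(n);
    double* dxn = dx.begin() + hw * C * static_cast<size_t>(n);
    for (size_t i = 0; i < hw; ++i) {
      double a = davg[i] / C;
      for (int c = 0; c < C; ++c) dxn[i + hw * c] += a;
      dxn[i + hw * static_cast<size_t>(ix[i])] += dmx[i];
    }
  }
  return dx;
}

// ---------------------------------------------------- broadcast scaling ---

// y(h,w,c,n) = x(h,w,c,n) * s(c,n)
// [[Rcpp::export(name = ".cpp_scale_ch_fwd")]]
NumericVector cpp_scale_ch_fwd(NumericVector x, NumericMatrix s) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = static_cast<size_t>(H) * W;
  NumericVector y = make4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double g = s(c, n);
      const double* xc = x.begin() + hw * (c + static_cast<size_t>(C) * n);
      double* yc = y.begin() + hw * (c + static_cast<size_t>(C) * n);
      for (size_t i = 0; i < hw; ++i) yc[i] = xc[i] * g;
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_scale_ch_bwd")]]
List cpp_scale_ch_bwd(NumericVector x, NumericMatrix s, NumericVector dy) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = static_cast<size_t>(H) * W;
  NumericVector dx = make4(H, W, C, N);
  NumericMatrix ds(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double g = s(c, n), acc = 0.0;
      const double* xc = x.begin() + hw * (c + static_cast<size_t>(C) * n);
      const double* dyc = dy.begin() + hw * (c + static_cast<size_t>(C) * n);
      double* dxc = dx.begin() + hw * (c + static_cast<size_t>(C) * n);
      for (size_t i = 0; i < hw; ++i) {
        dxc[i] = dyc[i] * g;
        acc += dyc[i] * xc[i];
      }
      ds(c, n) = acc;
    }
  return List::create(_["dx"] = dx, _["ds"] = ds);
}

// y(h,w,c,n) = x(h,w,c,n) * m(h,w,n); m passed as (H, W, 1, N) tensor
// [[Rcpp::export(name = ".cpp_scale_sp_fwd")]]
NumericVector cpp_scale_sp_fwd(NumericVector x, NumericVector m) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = static_cast<size_t>(H) * W;
  NumericVector y = make4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    const double* mn = m.begin() + hw * static_cast<size_t>(n);
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + hw * (c + static_cast<size_t>(C) * n);
      double* yc = y.begin() + hw * (c + static_cast<size_t>(C) * n);
      for (size_t i = 0; i < hw; ++i) yc[i] = xc[i] * mn[i];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_scale_sp_bwd")]]
List cpp_scale_sp_bwd(NumericVector x, NumericVector m, NumericVector dy) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = static_cast<size_t>(H) * W;
  NumericVector dx = make4(H, W, C, N);
  NumericVector dm = make4(H, W, 1, N, true);
  for (int n = 0; n < N; ++n) {
    const double* mn = m.begin() + hw * static_cast<size_t>(n);
    double* dmn = dm.begin() + hw * static_cast<size_t>(n);
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + hw * (c + static_cast<size_t>(C) * n);
      const double* dyc = dy.begin() + hw * (c + static_cast<size_t>(C) * n);
      double* dxc = dx.begin() + hw * (c + static_cast<size_t>(C) * n);
      for (size_t i = 0; i < hw; ++i) {
        dxc[i] = dyc[i] * mn[i];
        dmn[i] += dyc[i] * xc[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dm"] = dm);
}
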