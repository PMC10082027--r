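// Low-level CPU kernels for the network engine: same-padded 2-D
// convolution (forward/backward via im2col + GEMM), 2x2 max pooling,
// batch normalization, and bilinear resampling.  Feature maps are R
// arrays of dim (H, W, C, N); convolution kernels are (k, k, Cin, Cout),
// matching the column-major flattening used on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col layout: colT has H*W*N rows and k*k*C columns; column index
// (di + k*dj + k^2*c), row index (h + H*w + H*W*n).  Built from a
// zero-padded per-plane buffer so the inner copies are branch-free.

template <typename T>
static void build_colT(const double* xp, int H, int W, int C, int N,
                       int k, int pad, arma::Mat<T>& colT,
                       std::vector<T>& xpad) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  xpad.assign((size_t)Hp * Wp, T(0));
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + HW * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w) {
        T* dst = xpad.data() + pad + (size_t)Hp * (w + pad);
        const double* srcc = plane + (size_t)H * w;
        for (int h = 0; h < H; ++h) dst[h] = T(srcc[h]);
      }
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          T* dcol = colT.colptr(di + k * dj + k * k * c) + HW * n;
          for (int w = 0; w < W; ++w) {
            const T* s = xpad.data() + di + (size_t)Hp * (w + dj);
            T* d = dcol + (size_t)H * w;
            std::copy(s, s + H, d);
          }
        }
    }
  }
}

template <typename T>
static NumericVector conv_fwd_impl(const NumericVector& x,
                                   const NumericVector& w,
                                   const IntegerVector& xd,
                                   const IntegerVector& wd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int pad = (k - 1) / 2;
  if (Cin != C) stop("conv: input has %d channels, kernel expects %d", C, Cin);
  const size_t HW = (size_t)H * W;

  arma::Mat<T> Wm(k * k * Cin, Cout);
  for (size_t i = 0; i < Wm.n_elem; ++i) Wm.memptr()[i] = T(w[i]);

  NumericVector y(HW * Cout * N);
  double* yp = REAL(y);
  arma::Mat<T> out;
  if (k == 1) {
    arma::Mat<T> xm(HW * N, C);
    const double* xp = REAL(x);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        T* d = xm.colptr(c) + HW * n;
        const double* s = xp + HW * (c + (size_t)C * n);
        for (size_t i = 0; i < HW; ++i) d[i] = T(s[i]);
      }
    out = xm * Wm;
  } else {
    arma::Mat<T> colT(HW * N, (size_t)k * k * Cin);
    std::vector<T> xpad;
    build_colT<T>(REAL(x), H, W, C, N, k, pad, colT, xpad);
    out = colT * Wm;  // (HW*N) x Cout
  }
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const T* s = out.colptr(co) + HW * n;
      double* d = yp + HW * (co + (size_t)Cout * n);
      for (size_t i = 0; i < HW; ++i) d[i] = (double)s[i];
    }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           bool use_float = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  if (xd.size() != 4 || wd.size() != 4) stop("conv: expected 4-d arrays");
  if (use_float) return conv_fwd_impl<float>(x, w, xd, wd);
  return conv_fwd_impl<double>(x, w, xd, wd);
}

template <typename T>
static List conv_bwd_impl(const NumericVector& x, const NumericVector& w,
                          const NumericVector& dy, const IntegerVector& xd,
                          const IntegerVector& wd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;

  arma::Mat<T> Wm(k * k * Cin, Cout);
  for (size_t i = 0; i < Wm.n_elem; ++i) Wm.memptr()[i] = T(w[i]);

  arma::Mat<T> dYs(HW * N, Cout);
  const double* dyp = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      T* d = dYs.colptr(co) + HW * n;
      const double* s = dyp + HW * (co + (size_t)Cout * n);
      for (size_t i = 0; i < HW; ++i) d[i] = T(s[i]);
    }

  NumericVector dx(HW * C * N);
  NumericVector dw(w.size());
  double* dxp = REAL(dx);
  arma::Mat<T> dWm;

  if (k == 1) {
    arma::Mat<T> xm(HW * N, C);
    const double* xp = REAL(x);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        T* d = xm.colptr(c) + HW * n;
        const double* s = xp + HW * (c + (size_t)C * n);
        for (size_t i = 0; i < HW; ++i) d[i] = T(s[i]);
      }
    dWm = xm.t() * dYs;
    arma::Mat<T> dxm = dYs * Wm.t();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const T* s = dxm.colptr(c) + HW * n;
        double* d = dxp + HW * (c + (size_t)C * n);
        for (size_t i = 0; i < HW; ++i) d[i] = (double)s[i];
      }
  } else {
    arma::Mat<T> colT(HW * N, (size_t)k * k * Cin);
    std::vector<T> xpad;
    build_colT<T>(REAL(x), H, W, C, N, k, pad, colT, xpad);
    dWm = colT.t() * dYs;
    arma::Mat<T> dcol = dYs * Wm.t();  // (HW*N) x k2C
    const int Hp = H + 2 * pad, Wp = W + 2 * pad;
    std::vector<T> dpad;
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        dpad.assign((size_t)Hp * Wp, T(0));
        for (int dj = 0; dj < k; ++dj)
          for (int di = 0; di < k; ++di) {
            const T* scol = dcol.colptr(di + k * dj + k * k * c) + HW * n;
            for (int w = 0; w < W; ++w) {
              T* d = dpad.data() + di + (size_t)Hp * (w + dj);
              const T* s = scol + (size_t)H * w;
              for (int h = 0; h < H; ++h) d[h] += s[h];
            }
          }
        double* dplane = dxp + HW * (c + (size_t)C * n);
        for (int w = 0; w < W; ++w) {
          const T* s = dpad.data() + pad + (size_t)Hp * (w + pad);
          double* d = dplane + (size_t)H * w;
          for (int h = 0; h < H; ++h) d[h] = (double)s[h];
        }
      }
  }
  for (size_t i = 0; i < dWm.n_elem; ++i) dw[i] = (double)dWm.memptr()[i];
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  bool use_float = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  if (use_float) return conv_bwd_impl<float>(x, w, dy, xd, wd);
  return conv_bwd_impl<double>(x, w, dy, xd, wd);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());  // 1-based flat index into x
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          size_t i00 = base + 2 * h + H * (size_t)(2 * w);
          size_t best = i00;
          double v = xp[i00];
          if (xp[i00 + 1] > v) { v = xp[i00 + 1]; best = i00 + 1; }
          if (xp[i00 + H] > v) { v = xp[i00 + H]; best = i00 + H; }
          if (xp[i00 + H + 1] > v) { v = xp[i00 + H + 1]; best = i00 + H + 1; }
          yp[o] = v;
          ip[o] = (int)best + 1;
        }
    }
  // column-major order above walks h fastest, then w, then c, then n,
  // which is exactly the (Ho, Wo, C, N) layout
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              IntegerVector in_dim) {
  size_t n = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector dx(n);
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  const int* ip = INTEGER(idx);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[ip[i] - 1] += dyp[i];
  dx.attr("dim") = in_dim;
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dout, NumericVector out) {
  NumericVector dx(dout.size());
  const double* dp = REAL(dout);
  const double* op = REAL(out);
  double* q = REAL(dx);
  for (R_xlen_t i = 0; i < dout.size(); ++i) q[i] = op[i] > 0 ? dp[i] : 0;
  dx.attr("dim") = dout.attr("dim");
  return dx;
}

// out = a + b + c in one pass (the three-term residual sum)
// [[Rcpp::export]]
NumericVector cpp_add3(NumericVector a, NumericVector b, NumericVector c) {
  NumericVector y(a.size());
  const double* pa = REAL(a);
  const double* pb = REAL(b);
  const double* pc = REAL(c);
  double* q = REAL(y);
  for (R_xlen_t i = 0; i < a.size(); ++i) q[i] = pa[i] + pb[i] + pc[i];
  y.attr("dim") = a.attr("dim");
  return y;
}

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps, bool training, NumericVector rmean,
                NumericVector rvar, bool relu = false) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  NumericVector mean(C), var(C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = xp + plane * (c + (size_t)C * n);
        for (size_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      const double cnt = (double)plane * N;
      m = s / cnt;
      v = s2 / cnt - m * m;
      if (v < 0) v = 0;
    } else {
      m = rmean[c];
      v = rvar[c];
    }
    mean[c] = m;
    var[c] = v;
    const double invstd = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c] * invstd, b = beta[c] - m * g;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + plane * (c + (size_t)C * n);
      double* q = yp + plane * (c + (size_t)C * n);
      if (relu)
        for (size_t i = 0; i < plane; ++i) {
          double v2 = g * p[i] + b;
          q[i] = v2 > 0 ? v2 : 0;
        }
      else
        for (size_t i = 0; i < plane; ++i) q[i] = g * p[i] + b;
    }
  }
  y.attr("dim") = xd;
  return List::create(_["out"] = y, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mean, NumericVector var, double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  const double cnt = (double)plane * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    const double invstd = 1.0 / std::sqrt(var[c] + eps);
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* p = xp + off;
      const double* d = dyp + off;
      for (size_t i = 0; i < plane; ++i) {
        sdy += d[i];
        sdyx += d[i] * (p[i] - mean[c]) * invstd;
      }
    }
    dbeta[c] = sdy;
    dgamma[c] = sdyx;
    const double a = gamma[c] * invstd / cnt;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* p = xp + off;
      const double* d = dyp + off;
      double* o = dxp + off;
      for (size_t i = 0; i < plane; ++i)
        o[i] = a * (cnt * d[i] - sdy - (p[i] - mean[c]) * invstd * sdyx);
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Bilinear resampling of an (H, W, C) array to (oh, ow, C); pixel-center
// alignment (the convention used by most image libraries for resize).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int oh, int ow) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd.size() >= 3 ? xd[2] : 1;
  NumericVector y((size_t)oh * ow * C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const double sh = (double)H / oh, sw = (double)W / ow;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)H * W * c;
    double* yc = yp + (size_t)oh * ow * c;
    for (int w = 0; w < ow; ++w) {
      double fw = (w + 0.5) * sw - 0.5;
      int w0 = (int)std::floor(fw);
      double tw = fw - w0;
      int w0c = std::min(std::max(w0, 0), W - 1);
      int w1c = std::min(std::max(w0 + 1, 0), W - 1);
      for (int h = 0; h < oh; ++h) {
        double fh = (h + 0.5) * sh - 0.5;
        int h0 = (int)std::floor(fh);
        double th = fh - h0;
        int h0c = std::min(std::max(h0, 0), H - 1);
        int h1c = std::min(std::max(h0 + 1, 0), H - 1);
        double v00 = xc[h0c + (size_t)H * w0c], v10 = xc[h1c + (size_t)H * w0c];
        double v01 = xc[h0c + (size_t)H * w1c], v11 = xc[h1c + (size_t)H * w1c];
        yc[h + (size_t)oh * w] = (1 - th) * ((1 - tw) * v00 + tw * v01) +
                                 th * ((1 - tw) * v10 + tw * v11);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, C);
  return y;
}
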