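// Low-level convolutional kernels for the segmentation engine.
//
// Tensor layout convention (matches R column-major arrays):
//   activations x : dim (H, W, C, N)
//   conv weights  : dim (kh, kw, Cin, F)     -- ordinary convolution
//   convT weights : dim (kh, kw, Cout, Cin)  -- transposed convolution
//
// All convolutions use symmetric zero padding `pad` (may be negative for
// transposed convolutions whose kernel is smaller than the stride).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int dil, int pad) {
  int eff = dil * (k - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// im2col for one sample: cols(K, P), K = kh*kw*C, P = Ho*Wo,
// row index = a + kh*(b + kw*c), col index = ho + Ho*wo.
static void im2col_one(const double* x, int H, int W, int C,
                       int kh, int kw, int stride, int dil, int pad,
                       int Ho, int Wo, double* cols) {
  const int K = kh * kw * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* col = cols + (std::size_t)(ho + Ho * wo) * K;
      const int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (std::size_t)c * H * W;
        for (int b = 0; b < kw; ++b) {
          const int wi = w0 + b * dil;
          for (int a = 0; a < kh; ++a) {
            const int hi = h0 + a * dil;
            col[a + kh * (b + kw * c)] =
              (hi >= 0 && hi < H && wi >= 0 && wi < W) ? xc[hi + (std::size_t)wi * H] : 0.0;
          }
        }
      }
    }
  }
}

// scatter-add of column matrix back to image (adjoint of im2col_one)
static void col2im_one(const double* cols, int H, int W, int C,
                       int kh, int kw, int stride, int dil, int pad,
                       int Ho, int Wo, double* x) {
  const int K = kh * kw * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* col = cols + (std::size_t)(ho + Ho * wo) * K;
      const int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* xc = x + (std::size_t)c * H * W;
        for (int b = 0; b < kw; ++b) {
          const int wi = w0 + b * dil;
          if (wi < 0 || wi >= W) continue;
          for (int a = 0; a < kh; ++a) {
            const int hi = h0 + a * dil;
            if (hi >= 0 && hi < H) xc[hi + (std::size_t)wi * H] += col[a + kh * (b + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector bias,
                        int stride, int dil, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("conv2d_fw: channel mismatch");
  const int Ho = out_dim(H, kh, stride, dil, pad), Wo = out_dim(W, kw, stride, dil, pad);
  const int K = kh * kw * C, P = Ho * Wo;
  NumericVector y(Rcpp::no_init((std::size_t)P * F * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  arma::mat Wm(w.begin(), K, F, false, true);
  arma::mat cols(K, P);
  arma::rowvec bv(bias.begin(), F);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (std::size_t)n * H * W * C, H, W, C,
               kh, kw, stride, dil, pad, Ho, Wo, cols.memptr());
    // (P, F) result is exactly the memory layout of y[, , , n]
    arma::mat Yt(y.begin() + (std::size_t)n * P * F, P, F, false, true);
    Yt = cols.t() * Wm;
    Yt.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int dil, int pad, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int K = kh * kw * C, P = Ho * Wo;
  arma::mat Wm(w.begin(), K, F, false, true);
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), K, F, false, true);
  NumericVector db(F);
  arma::vec dbv(db.begin(), F, false, true);
  NumericVector dx;
  if (need_dx) { dx = NumericVector((std::size_t)H * W * C * N); dx.attr("dim") = xd; }
  arma::mat cols(K, P), dcols(K, P);
  for (int n = 0; n < N; ++n) {
    arma::mat dYt(const_cast<double*>(dy.begin()) + (std::size_t)n * P * F, P, F, false, true);
    im2col_one(x.begin() + (std::size_t)n * H * W * C, H, W, C,
               kh, kw, stride, dil, pad, Ho, Wo, cols.memptr());
    dWm += cols * dYt;
    dbv += arma::sum(dYt, 0).t();
    if (need_dx) {
      dcols = Wm * dYt.t();
      col2im_one(dcols.memptr(), H, W, C, kh, kw, stride, dil, pad, Ho, Wo,
                 dx.begin() + (std::size_t)n * H * W * C);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution. Output size Ho = stride*(h-1) + kh - 2*pad.
// Choosing pad = (kh - stride)/2 gives Ho = stride*h for kh >= stride (even difference).
// [[Rcpp::export(name = ".convt2d_fw")]]
NumericVector convt2d_fw(NumericVector x, NumericVector w, NumericVector bias,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int h = xd[0], wdt = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[2];
  if (wd[3] != Cin) stop("convt2d_fw: channel mismatch");
  const int Ho = stride * (h - 1) + kh - 2 * pad;
  const int Wo = stride * (wdt - 1) + kw - 2 * pad;
  const int K = kh * kw * Cout, P = h * wdt;
  NumericVector y((std::size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wt(w.begin(), K, Cin, false, true); // (kh*kw*Cout, Cin)
  arma::mat Cn(P, K);
  for (int n = 0; n < N; ++n) {
    arma::mat Xn(const_cast<double*>(x.begin()) + (std::size_t)n * P * Cin, P, Cin, false, true);
    Cn = Xn * Wt.t();
    // scatter: y(i*s+a-pad, j*s+b-pad, o, n) += Cn(p, a+kh*(b+kw*o))
    // this is col2im with "input" = y, Ho_cols = h, Wo_cols = wdt
    col2im_one(Cn.t().eval().memptr(), Ho, Wo, Cout, kh, kw, stride, 1, pad, h, wdt,
               y.begin() + (std::size_t)n * Ho * Wo * Cout);
    double* yn = y.begin() + (std::size_t)n * Ho * Wo * Cout;
    for (int o = 0; o < Cout; ++o) {
      const double bo = bias[o];
      double* yc = yn + (std::size_t)o * Ho * Wo;
      for (int p = 0; p < Ho * Wo; ++p) yc[p] += bo;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".convt2d_bw")]]
List convt2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int h = xd[0], wdt = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[2];
  const int Ho = yd[0], Wo = yd[1];
  const int K = kh * kw * Cout, P = h * wdt;
  arma::mat Wt(w.begin(), K, Cin, false, true);
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  arma::mat dWt(dw.begin(), K, Cin, false, true);
  NumericVector db(Cout);
  NumericVector dx((std::size_t)P * Cin * N); dx.attr("dim") = xd;
  arma::mat dCn(K, P);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (std::size_t)n * Ho * Wo * Cout;
    // gather: dCn(k, p) = dy at scattered positions  == im2col of dy
    im2col_one(dyn, Ho, Wo, Cout, kh, kw, stride, 1, pad, h, wdt, dCn.memptr());
    arma::mat Xn(const_cast<double*>(x.begin()) + (std::size_t)n * P * Cin, P, Cin, false, true);
    arma::mat dXn(dx.begin() + (std::size_t)n * P * Cin, P, Cin, false, true);
    dXn = dCn.t() * Wt;
    dWt += dCn * Xn;
    for (int o = 0; o < Cout; ++o) {
      const double* dyc = dyn + (std::size_t)o * Ho * Wo;
      double s = 0; for (int p = 0; p < Ho * Wo; ++p) s += dyc[p];
      db[o] += s;
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling, kernel k, stride s, symmetric pad (padded cells = -inf).
// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_dim(H, k, stride, 1, pad), Wo = out_dim(W, k, stride, 1, pad);
  NumericVector y((std::size_t)Ho * Wo * C * N);
  IntegerVector arg((std::size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (std::size_t)(c + (std::size_t)n * C) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity(); int bi = -1;
          for (int b = 0; b < k; ++b) {
            const int wi = wo * stride - pad + b;
            if (wi < 0 || wi >= W) continue;
            for (int a = 0; a < k; ++a) {
              const int hi = ho * stride - pad + a;
              if (hi < 0 || hi >= H) continue;
              const double v = xc[hi + (std::size_t)wi * H];
              if (v > best) { best = v; bi = hi + wi * H; }
            }
          }
          std::size_t oi = (std::size_t)(ho + Ho * wo) + (std::size_t)(c + (std::size_t)n * C) * Ho * Wo;
          y[oi] = best; arg[oi] = bi;
          ++q;
        }
    }
  (void)q;
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(NumericVector dy, IntegerVector arg, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx((std::size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + (std::size_t)(c + (std::size_t)n * C) * H * W;
      const std::size_t base = (std::size_t)(c + (std::size_t)n * C) * Ho * Wo;
      for (std::size_t p = 0; p < (std::size_t)Ho * Wo; ++p)
        if (arg[base + p] >= 0) dxc[arg[base + p]] += dy[base + p];
    }
  return dx;
}

// ---- batch-norm and LeakyReLU helpers (hot path) --------------------------

// y = x * sc[c] + sh[c] for (H, W, C, N) layout
// [[Rcpp::export(name = ".bn_affine")]]
NumericVector bn_affine(NumericVector x, NumericVector sc, NumericVector sh) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector y(Rcpp::no_init(x.size()));
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = sc[c], b = sh[c];
      const double* xc = x.begin() + (std::size_t)(c + (std::size_t)n * C) * HW;
      double* yc = y.begin() + (std::size_t)(c + (std::size_t)n * C) * HW;
      for (int p = 0; p < HW; ++p) yc[p] = xc[p] * a + b;
    }
  return y;
}

// per-channel sums of x and x*x over (H, W, N)
// [[Rcpp::export(name = ".bn_stats")]]
List bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector s1(C), s2(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (std::size_t)(c + (std::size_t)n * C) * HW;
      double a = 0, b = 0;
      for (int p = 0; p < HW; ++p) { a += xc[p]; b += xc[p] * xc[p]; }
      s1[c] += a; s2[c] += b;
    }
  return List::create(_["sum"] = s1, _["sumsq"] = s2, _["n"] = HW * N);
}

// batch-norm backward: returns dx and accumulates dgamma/dbeta
// [[Rcpp::export(name = ".bn_bw")]]
List bn_bw(NumericVector x, NumericVector dy, NumericVector mu,
           NumericVector invstd, NumericVector gamma, bool training) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  const double nhw = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)(c + (std::size_t)n * C) * HW;
      const double* xc = x.begin() + off;
      const double* dc = dy.begin() + off;
      const double m = mu[c], is = invstd[c];
      double dg = 0, db = 0;
      for (int p = 0; p < HW; ++p) {
        dg += dc[p] * (xc[p] - m) * is;
        db += dc[p];
      }
      dgamma[c] += dg; dbeta[c] += db;
    }
  NumericVector dx(Rcpp::no_init(x.size()));
  dx.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)(c + (std::size_t)n * C) * HW;
      const double* xc = x.begin() + off;
      const double* dc = dy.begin() + off;
      double* dxc = dx.begin() + off;
      const double m = mu[c], is = invstd[c], g = gamma[c];
      if (training) {
        const double t1 = dbeta[c] / nhw, t2 = dgamma[c] / nhw;
        for (int p = 0; p < HW; ++p)
          dxc[p] = g * is * (dc[p] - t1 - (xc[p] - m) * is * t2);
      } else {
        for (int p = 0; p < HW; ++p) dxc[p] = g * is * dc[p];
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".lrelu_fw")]]
NumericVector lrelu_fw_cpp(NumericVector x, double alpha) {
  NumericVector y(Rcpp::no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const std::size_t n = x.size();
  for (std::size_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : alpha * x[i];
  return y;
}

// [[Rcpp::export(name = ".lrelu_bw")]]
NumericVector lrelu_bw_cpp(NumericVector x, NumericVector dy, double alpha) {
  NumericVector dx(Rcpp::no_init(x.size()));
  dx.attr("dim") = x.attr("dim");
  const std::size_t n = x.size();
  for (std::size_t i = 0; i < n; ++i) dx[i] = x[i] > 0 ? dy[i] : alpha * dy[i];
  return dx;
}
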