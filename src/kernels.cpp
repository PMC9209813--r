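// Numerical kernels: circular-scan forward projection, delay-and-sum
// beamforming, and the convolution / normalization primitives behind the
// CNN engine.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Arrival-time binning of pixelized sources onto detector time axes.
// For a 2D homogeneous medium the quantity t * M(p0)(r_d, ct) (M = circular
// mean) reduces, for a sum of pixel point sources, to a plain weighted
// histogram of arrival times |x_k - r_d| / c: the 1/(2*pi*rho) of the
// circular mean cancels against the t factor.  Linear splitting between the
// two neighbouring time bins.  Returns [n_time x n_det].
// [[Rcpp::export]]
arma::mat cpp_project_arrivals(const arma::vec& px, const arma::vec& py,
                               const arma::vec& val,
                               const arma::vec& detx, const arma::vec& dety,
                               double c, double dt, int n_time) {
  const int nd = detx.n_elem, ns = px.n_elem;
  arma::mat out(n_time, nd, arma::fill::zeros);
  for (int j = 0; j < nd; ++j) {
    const double dxj = detx[j], dyj = dety[j];
    double* col = out.colptr(j);
    for (int k = 0; k < ns; ++k) {
      const double rx = px[k] - dxj, ry = py[k] - dyj;
      const double t = std::sqrt(rx * rx + ry * ry) / (c * dt);
      const int i0 = (int)std::floor(t);
      if (i0 < 0 || i0 >= n_time - 1) continue;
      const double w = t - i0;
      col[i0]     += val[k] * (1.0 - w);
      col[i0 + 1] += val[k] * w;
    }
  }
  return out;
}

// Delay-and-sum: I(x) = sum_d s_d(|x - r_d| / c), linear interpolation in
// time, out-of-window delays contribute zero.  sino is [n_time x n_det].
// [[Rcpp::export]]
arma::vec cpp_das(const arma::mat& sino,
                  const arma::vec& detx, const arma::vec& dety,
                  const arma::vec& pixx, const arma::vec& pixy,
                  double c, double dt) {
  const int nd = detx.n_elem, np = pixx.n_elem, nt = sino.n_rows;
  arma::vec img(np, arma::fill::zeros);
  for (int j = 0; j < nd; ++j) {
    const double dxj = detx[j], dyj = dety[j];
    const double* col = sino.colptr(j);
    for (int p = 0; p < np; ++p) {
      const double rx = pixx[p] - dxj, ry = pixy[p] - dyj;
      const double t = std::sqrt(rx * rx + ry * ry) / (c * dt);
      const int i0 = (int)std::floor(t);
      if (i0 < 0 || i0 >= nt - 1) continue;
      const double w = t - i0;
      img[p] += col[i0] * (1.0 - w) + col[i0 + 1] * w;
    }
  }
  return img;
}

// ---------------------------------------------------------------------------
// Convolution primitives.  Tensor layout is R column-major [H, W, C, N];
// filters are [kh, kw, Cin, Cout].  Patches are laid out as
// K [Ho*Wo, kh*kw*Cin] so that both the patch matrix and the input share
// contiguous runs along the image height (memcpy-able for stride 1), and
// the filter array can be viewed in place as a (kh*kw*Cin) x Cout matrix.

static void im2col_t(const double* x, int H, int W, int C,
                     int kh, int kw, int stride, int dil, int pad,
                     int Ho, int Wo, arma::mat& K) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* col = K.colptr(ki + kh * (kj + kw * c));
        const int oh = ki * dil - pad;   // hi = ho*stride + oh
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj * dil;
          double* dst = col + (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            std::memset(dst, 0, sizeof(double) * Ho);
            continue;
          }
          const double* src = xc + (size_t)H * wi;
          if (stride == 1) {
            // valid ho range: 0 <= ho + oh < H
            int h0 = std::max(0, -oh), h1 = std::min(Ho, H - oh);
            if (h0 > 0) std::memset(dst, 0, sizeof(double) * h0);
            if (h1 > h0)
              std::memcpy(dst + h0, src + h0 + oh,
                          sizeof(double) * (h1 - h0));
            if (h1 < Ho) std::memset(dst + h1, 0, sizeof(double) * (Ho - h1));
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + oh;
              dst[ho] = (hi >= 0 && hi < H) ? src[hi] : 0.0;
            }
          }
        }
      }
    }
  }
}

static void col2im_t_add(const arma::mat& K, double* x, int H, int W, int C,
                         int kh, int kw, int stride, int dil, int pad,
                         int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* col = K.colptr(ki + kh * (kj + kw * c));
        const int oh = ki * dil - pad;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          const double* src = col + (size_t)Ho * wo;
          double* dst = xc + (size_t)H * wi;
          if (stride == 1) {
            int h0 = std::max(0, -oh), h1 = std::min(Ho, H - oh);
            for (int ho = h0; ho < h1; ++ho) dst[ho + oh] += src[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + oh;
              if (hi >= 0 && hi < H) dst[hi] += src[ho];
            }
          }
        }
      }
    }
  }
}

static inline int out_size(int n, int k, int stride, int dil, int pad) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// ---------------------------------------------------------------------------
// Shift-GEMM path for stride-1, same-pad convolutions (the dense blocks).
// The input is copied once into a height-padded buffer; every kernel tap
// then becomes a single GEMM over a contiguous row range, with the height
// padding absorbing would-be column wrap-around.

static arma::mat g_Xp, g_Yp, g_dYp;  // reusable scratch (R is single-threaded)

static void pad_h_copy(const double* x, int H, int W, int C, int d,
                       arma::mat& Xp) {
  const int Hp = H + 2 * d;
  Xp.set_size((size_t)Hp * W, C);
  for (int c = 0; c < C; ++c) {
    double* dst = Xp.colptr(c);
    const double* src = x + (size_t)H * W * c;
    for (int w = 0; w < W; ++w) {
      std::memset(dst, 0, sizeof(double) * d);
      std::memcpy(dst + d, src, sizeof(double) * H);
      std::memset(dst + d + H, 0, sizeof(double) * d);
      dst += Hp; src += H;
    }
  }
}

static arma::mat tap_matrix(const double* w, int k, int C, int Cout,
                            int ki, int kj) {
  arma::mat Wt(C, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < C; ++c)
      Wt(c, co) = w[ki + k * (kj + k * c) + (size_t)k * k * C * co];
  return Wt;
}

static void conv_s1_fwd(const double* x, int H, int W, int C,
                        const double* w, int k, int dil, int Cout,
                        double* y) {
  const int d = dil * (k - 1) / 2;
  const int Hp = H + 2 * d;
  pad_h_copy(x, H, W, C, d, g_Xp);
  g_Yp.zeros((size_t)Hp * W, Cout);
  for (int kj = 0; kj < k; ++kj) {
    const int ow = kj * dil - d;
    const int w0 = std::max(0, -ow), w1 = W - std::max(0, ow);
    if (w1 <= w0) continue;
    const size_t r0 = (size_t)w0 * Hp, r1 = (size_t)w1 * Hp - 1;
    for (int ki = 0; ki < k; ++ki) {
      const long long s = (ki * dil - d) + (long long)Hp * ow;
      const long long hi = (long long)Hp * W - 1;
      const long long a = std::max((long long)r0, -s);
      const long long b = std::min((long long)r1, hi - s);
      if (b < a) continue;
      arma::mat Wt = tap_matrix(w, k, C, Cout, ki, kj);
      g_Yp.rows(a, b) += g_Xp.rows(a + s, b + s) * Wt;
    }
  }
  for (int co = 0; co < Cout; ++co) {
    const double* src = g_Yp.colptr(co);
    double* dst = y + (size_t)H * W * co;
    for (int wcol = 0; wcol < W; ++wcol)
      std::memcpy(dst + (size_t)H * wcol, src + (size_t)Hp * wcol + d,
                  sizeof(double) * H);
  }
}

static void conv_s1_bwd_data(const double* dy, int H, int W, int C,
                             const double* w, int k, int dil, int Cout,
                             double* dx) {
  const int d = dil * (k - 1) / 2;
  const int Hp = H + 2 * d;
  pad_h_copy(dy, H, W, Cout, d, g_dYp);
  g_Xp.zeros((size_t)Hp * W, C);
  for (int kj = 0; kj < k; ++kj) {
    const int ow = kj * dil - d;
    const int w0 = std::max(0, -ow), w1 = W - std::max(0, ow);
    if (w1 <= w0) continue;
    const size_t r0 = (size_t)w0 * Hp, r1 = (size_t)w1 * Hp - 1;
    for (int ki = 0; ki < k; ++ki) {
      const long long s = (ki * dil - d) + (long long)Hp * ow;
      const long long hi = (long long)Hp * W - 1;
      const long long a = std::max((long long)r0, -s);
      const long long b = std::min((long long)r1, hi - s);
      if (b < a) continue;
      arma::mat Wt = tap_matrix(w, k, C, Cout, ki, kj);
      g_Xp.rows(a + s, b + s) += g_dYp.rows(a, b) * Wt.t();
    }
  }
  for (int c = 0; c < C; ++c) {
    const double* src = g_Xp.colptr(c);
    double* dst = dx + (size_t)H * W * c;
    for (int wcol = 0; wcol < W; ++wcol)
      std::memcpy(dst + (size_t)H * wcol, src + (size_t)Hp * wcol + d,
                  sizeof(double) * H);
  }
}

static void conv_s1_bwd_filter(const double* x, const double* dy,
                               int H, int W, int C, int k, int dil,
                               int Cout, double* dw) {
  const int d = dil * (k - 1) / 2;
  const int Hp = H + 2 * d;
  pad_h_copy(x, H, W, C, d, g_Xp);
  pad_h_copy(dy, H, W, Cout, d, g_dYp);
  for (int kj = 0; kj < k; ++kj) {
    const int ow = kj * dil - d;
    const int w0 = std::max(0, -ow), w1 = W - std::max(0, ow);
    if (w1 <= w0) continue;
    const size_t r0 = (size_t)w0 * Hp, r1 = (size_t)w1 * Hp - 1;
    for (int ki = 0; ki < k; ++ki) {
      const long long s = (ki * dil - d) + (long long)Hp * ow;
      const long long hi = (long long)Hp * W - 1;
      const long long a = std::max((long long)r0, -s);
      const long long b = std::min((long long)r1, hi - s);
      if (b < a) continue;
      arma::mat dWt = g_Xp.rows(a + s, b + s).t() * g_dYp.rows(a, b);
      for (int co = 0; co < Cout; ++co)
        for (int c = 0; c < C; ++c)
          dw[ki + k * (kj + k * c) + (size_t)k * k * C * co] += dWt(c, co);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             int stride, int dil, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = out_size(H, kh, stride, dil, pad);
  const int Wo = out_size(W, kw, stride, dil, pad);
  const int KR = kh * kw * C;
  arma::mat Wm(const_cast<double*>(w.begin()), KR, Cout, false, true);
  NumericVector y(R_xlen_t((size_t)Ho * Wo * Cout * N));
  const bool one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  const bool s1 = (stride == 1 && kh == kw && pad == dil * (kh - 1) / 2 &&
                   kh > 1);
  arma::mat K;
  if (!one && !s1) K.set_size((size_t)Ho * Wo, KR);
  for (int n = 0; n < N; ++n) {
    arma::mat Y(y.begin() + (size_t)Ho * Wo * Cout * n,
                (size_t)Ho * Wo, Cout, false, true);
    if (one) {
      arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                  (size_t)H * W, C, false, true);
      Y = X * Wm;
    } else if (s1) {
      conv_s1_fwd(x.begin() + (size_t)H * W * C * n, H, W, C,
                  w.begin(), kh, dil, Cout,
                  y.begin() + (size_t)Ho * Wo * Cout * n);
    } else {
      im2col_t(x.begin() + (size_t)H * W * C * n, H, W, C,
               kh, kw, stride, dil, pad, Ho, Wo, K);
      Y = K * Wm;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// Gradient w.r.t. the input (also the forward pass of transposed conv).
// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_data(NumericVector dy, NumericVector w,
                                  IntegerVector xdim,
                                  int stride, int dil, int pad) {
  IntegerVector yd = dy.attr("dim"), wd = w.attr("dim");
  const int Ho = yd[0], Wo = yd[1], Cout = yd[2], N = yd[3];
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  const int kh = wd[0], kw = wd[1];
  const int KR = kh * kw * C;
  arma::mat Wm(const_cast<double*>(w.begin()), KR, Cout, false, true);
  NumericVector dx(R_xlen_t((size_t)H * W * C * N));
  const bool one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  for (int n = 0; n < N; ++n) {
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false, true);
    if (one) {
      arma::mat dX(dx.begin() + (size_t)H * W * C * n,
                   (size_t)H * W, C, false, true);
      dX = dY * Wm.t();
    } else if (stride == 1 && kh == kw && pad == dil * (kh - 1) / 2 &&
               kh > 1 && H == Ho && W == Wo) {
      conv_s1_bwd_data(dy.begin() + (size_t)Ho * Wo * Cout * n, H, W, C,
                       w.begin(), kh, dil, Cout,
                       dx.begin() + (size_t)H * W * C * n);
    } else {
      arma::mat K = dY * Wm.t();  // [Ho*Wo, KR]
      col2im_t_add(K, dx.begin() + (size_t)H * W * C * n, H, W, C,
                   kh, kw, stride, dil, pad, Ho, Wo);
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Gradient w.r.t. the filters.
// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_filter(NumericVector x, NumericVector dy,
                                    IntegerVector kdim,
                                    int stride, int dil, int pad) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  const int kh = kdim[0], kw = kdim[1];
  const int KR = kh * kw * C;
  NumericVector dw(R_xlen_t((size_t)kh * kw * C * Cout));
  arma::mat dWm(dw.begin(), KR, Cout, false, true);
  const bool one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::mat K;
  if (!one) K.set_size((size_t)Ho * Wo, KR);
  for (int n = 0; n < N; ++n) {
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false, true);
    if (one) {
      arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                  (size_t)H * W, C, false, true);
      dWm += X.t() * dY;
    } else if (stride == 1 && kh == kw && pad == dil * (kh - 1) / 2 &&
               kh > 1 && H == Ho && W == Wo) {
      conv_s1_bwd_filter(x.begin() + (size_t)H * W * C * n,
                         dy.begin() + (size_t)Ho * Wo * Cout * n,
                         H, W, C, kh, dil, Cout, dw.begin());
    } else {
      im2col_t(x.begin() + (size_t)H * W * C * n, H, W, C,
               kh, kw, stride, dil, pad, Ho, Wo, K);
      dWm += K.t() * dY;
    }
  }
  dw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  return dw;
}

// ---------------------------------------------------------------------------
// Elementwise / normalization helpers.

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  double* p = y.begin();
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  const double* d = dy.begin();
  const double* v = y.begin();
  double* o = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = (v[i] > 0) ? d[i] : 0.0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// Per-channel mean and raw variance over (H, W, N) for [H, W, C, N].
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / (HW * N);
    mu[c] = m;
    var[c] = s2 / (HW * N) - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// y = (x - mu_c) * istd_c * gamma_c + beta_c
// [[Rcpp::export]]
NumericVector cpp_bn_fwd(NumericVector x, NumericVector mu,
                         NumericVector istd, NumericVector gamma,
                         NumericVector beta) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector y(x.size());
  for (int c = 0; c < C; ++c) {
    const double a = istd[c] * gamma[c];
    const double b = beta[c] - mu[c] * a;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      double* q = y.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) q[i] = p[i] * a + b;
    }
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// Batch-norm backward (training mode): returns dx, dgamma, dbeta.
// xhat is reconstructed from x, mu, istd on the fly.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dy, NumericVector x, NumericVector mu,
                NumericVector istd, NumericVector gamma, bool training) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const double M = (double)HW * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = HW * (c + (size_t)C * n);
      const double* d = dy.begin() + off;
      const double* p = x.begin() + off;
      for (size_t i = 0; i < HW; ++i) {
        const double xh = (p[i] - mu[c]) * istd[c];
        s1 += d[i];
        s2 += d[i] * xh;
      }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double g = gamma[c], is = istd[c];
    if (training) {
      const double c1 = s1 / M, c2 = s2 / M;
      for (int n = 0; n < N; ++n) {
        const size_t off = HW * (c + (size_t)C * n);
        const double* d = dy.begin() + off;
        const double* p = x.begin() + off;
        double* o = dx.begin() + off;
        for (size_t i = 0; i < HW; ++i) {
          const double xh = (p[i] - mu[c]) * is;
          o[i] = g * is * (d[i] - c1 - xh * c2);
        }
      }
    } else {
      for (int n = 0; n < N; ++n) {
        const size_t off = HW * (c + (size_t)C * n);
        const double* d = dy.begin() + off;
        double* o = dx.begin() + off;
        for (size_t i = 0; i < HW; ++i) o[i] = g * is * d[i];
      }
    }
  }
  dx.attr("dim") = x.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Concatenate along the channel axis: xs is a list of [H, W, Ci, N].
// [[Rcpp::export]]
NumericVector cpp_concat_ch(List xs) {
  const int m = xs.size();
  std::vector<NumericVector> v(m);
  std::vector<int> ch(m);
  int Ctot = 0, H = 0, W = 0, N = 0;
  for (int k = 0; k < m; ++k) {
    v[k] = as<NumericVector>(xs[k]);
    IntegerVector d = v[k].attr("dim");
    H = d[0]; W = d[1]; N = d[3];
    ch[k] = d[2];
    Ctot += d[2];
  }
  const size_t HW = (size_t)H * W;
  NumericVector y(R_xlen_t(HW * Ctot * N));
  for (int n = 0; n < N; ++n) {
    double* dst = y.begin() + HW * (size_t)Ctot * n;
    for (int k = 0; k < m; ++k) {
      const double* src = v[k].begin() + HW * (size_t)ch[k] * n;
      std::memcpy(dst, src, sizeof(double) * HW * ch[k]);
      dst += HW * ch[k];
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Ctot, N);
  return y;
}

// Slice channels [c0, c0+nc) out of [H, W, C, N] (0-based c0).
// [[Rcpp::export]]
NumericVector cpp_slice_ch(NumericVector x, int c0, int nc) {
  IntegerVector d = x.attr("dim");
  const size_t HW = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector y(R_xlen_t(HW * nc * N));
  for (int n = 0; n < N; ++n)
    std::memcpy(y.begin() + HW * (size_t)nc * n,
                x.begin() + HW * ((size_t)C * n + c0),
                sizeof(double) * HW * nc);
  y.attr("dim") = IntegerVector::create(d[0], d[1], nc, N);
  return y;
}

// Fused batch-norm + ReLU: y = max(0, (x - mu) * istd * gamma + beta).
// [[Rcpp::export]]
NumericVector cpp_bn_relu_fwd(NumericVector x, NumericVector mu,
                              NumericVector istd, NumericVector gamma,
                              NumericVector beta) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector y(x.size());
  for (int c = 0; c < C; ++c) {
    const double a = istd[c] * gamma[c];
    const double b = beta[c] - mu[c] * a;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      double* q = y.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        const double v = p[i] * a + b;
        q[i] = v > 0 ? v : 0;
      }
    }
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// Fused backward: the ReLU mask (y > 0) is applied to dy on the fly, then
// the usual batch-norm backward.
// [[Rcpp::export]]
List cpp_bn_relu_bwd(NumericVector dy, NumericVector y, NumericVector x,
                     NumericVector mu, NumericVector istd,
                     NumericVector gamma, bool training) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const double M = (double)HW * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    const double is = istd[c], m = mu[c], g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = HW * (c + (size_t)C * n);
      const double* d = dy.begin() + off;
      const double* yy = y.begin() + off;
      const double* p = x.begin() + off;
      for (size_t i = 0; i < HW; ++i) {
        if (yy[i] <= 0) continue;
        const double xh = (p[i] - m) * is;
        s1 += d[i];
        s2 += d[i] * xh;
      }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    if (training) {
      const double c1 = s1 / M, c2 = s2 / M;
      for (int n = 0; n < N; ++n) {
        const size_t off = HW * (c + (size_t)C * n);
        const double* d = dy.begin() + off;
        const double* yy = y.begin() + off;
        const double* p = x.begin() + off;
        double* o = dx.begin() + off;
        for (size_t i = 0; i < HW; ++i) {
          const double xh = (p[i] - m) * is;
          const double dm = yy[i] > 0 ? d[i] : 0;
          o[i] = g * is * (dm - c1 - xh * c2);
        }
      }
    } else {
      for (int n = 0; n < N; ++n) {
        const size_t off = HW * (c + (size_t)C * n);
        const double* d = dy.begin() + off;
        const double* yy = y.begin() + off;
        double* o = dx.begin() + off;
        for (size_t i = 0; i < HW; ++i)
          o[i] = (yy[i] > 0) ? g * is * d[i] : 0;
      }
    }
  }
  dx.attr("dim") = x.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// In-place Adam update on a parameter and its moment buffers.
// [[Rcpp::export]]
void cpp_adam_update(NumericVector v, NumericVector g, NumericVector m,
                     NumericVector s, double lr, double t, double beta1,
                     double beta2, double eps) {
  const R_xlen_t n = v.size();
  double* pv = v.begin();
  const double* pg = g.begin();
  double* pm = m.begin();
  double* ps = s.begin();
  const double bc1 = 1 - std::pow(beta1, t), bc2 = 1 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = beta1 * pm[i] + (1 - beta1) * pg[i];
    ps[i] = beta2 * ps[i] + (1 - beta2) * pg[i] * pg[i];
    pv[i] -= lr * (pm[i] / bc1) / (std::sqrt(ps[i] / bc2) + eps);
  }
}

// Segment-integrated arrival binning for finite-aperture elements: each
// sub-element is a flat segment [p0, p1]; the source's arrival-time spread
// across the segment is deposited as a uniform box over the covered time
// bins (linearized delay within the segment), which converges quadratically
// in the number of sub-elements.
// [[Rcpp::export]]
arma::mat cpp_project_segments(const arma::vec& px, const arma::vec& py,
                               const arma::vec& val,
                               const arma::vec& e0x, const arma::vec& e0y,
                               const arma::vec& e1x, const arma::vec& e1y,
                               double c, double dt, int n_time) {
  const int nd = e0x.n_elem, ns = px.n_elem;
  arma::mat out(n_time, nd, arma::fill::zeros);
  for (int j = 0; j < nd; ++j) {
    double* col = out.colptr(j);
    for (int k = 0; k < ns; ++k) {
      const double dx0 = px[k] - e0x[j], dy0 = py[k] - e0y[j];
      const double dx1 = px[k] - e1x[j], dy1 = py[k] - e1y[j];
      double t0 = std::sqrt(dx0 * dx0 + dy0 * dy0) / (c * dt);
      double t1 = std::sqrt(dx1 * dx1 + dy1 * dy1) / (c * dt);
      if (t1 < t0) std::swap(t0, t1);
      if (t0 < 0 || t1 >= n_time - 1) continue;
      const double span = t1 - t0;
      if (span < 1e-9) {  // degenerate: point deposit with linear split
        const int i0 = (int)std::floor(t0);
        const double w = t0 - i0;
        col[i0]     += val[k] * (1.0 - w);
        col[i0 + 1] += val[k] * w;
        continue;
      }
      const double dens = val[k] / span;
      const int i0 = (int)std::floor(t0), i1 = (int)std::floor(t1);
      for (int i = i0; i <= i1; ++i) {
        const double lo = std::max(t0, (double)i);
        const double hi = std::min(t1, (double)i + 1);
        if (hi <= lo) continue;
        // distribute the bin's overlap onto the two sample nodes
        const double mid = 0.5 * (lo + hi) - i;
        const double m = dens * (hi - lo);
        col[i]     += m * (1.0 - mid);
        col[i + 1] += m * mid;
      }
    }
  }
  return out;
}
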