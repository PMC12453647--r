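// Core tensor kernels for the convolutional classifier.
//
// Tensors arrive from R as flat numeric vectors in column-major order with
// dimensions (H, W, C, N): H = window rows (hours), W = feature columns,
// C = channels, N = samples.  Convolution weights have dimensions
// (kh, kw, Cin, Cout).  All convolutions are shape-preserving ("same" zero
// padding) with odd kernels; dilation spaces the kernel taps.
//
// Convolutions are evaluated by im2col + GEMM, one sample at a time, so the
// hot loop is a BLAS dgemm call.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int idx4(int i, int j, int k, int n, int H, int W, int C) {
  return i + H * (j + W * (k + C * n));
}

// Fill `colT` ((H*W) x (kh*kw*C)) with dilated, zero-padded patches of
// sample `n` of x, transposed so writes are contiguous in the spatial
// index.  Column order is m + kh*(mm + kw*c), matching the
// (kh,kw,Cin,Cout) weight layout; row order is i + H*j.
static void im2col_t(const double* x, int H, int W, int C, int n,
                     int kh, int kw, int d, arma::mat& colT,
                     R_xlen_t rowOff) {
  const int rh = (kh - 1) / 2, rw = (kw - 1) / 2;
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    for (int mm = 0; mm < kw; ++mm) {
      for (int m = 0; m < kh; ++m) {
        const int kcol = m + kh * (mm + kw * c);
        const int di = (m - rh) * d, dj = (mm - rw) * d;
        double* dst = colT.colptr(kcol) + rowOff;
        const double* base = x + static_cast<R_xlen_t>(n) * H * W * C +
                             static_cast<R_xlen_t>(c) * HW;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          double* dj0 = dst + static_cast<R_xlen_t>(j) * H;
          if (sj < 0 || sj >= W) {
            for (int i = 0; i < H; ++i) dj0[i] = 0.0;
            continue;
          }
          const double* sj0 = base + static_cast<R_xlen_t>(sj) * H;
          const int lo = std::max(0, -di), hi = std::min(H, H - di);
          for (int i = 0; i < lo; ++i) dj0[i] = 0.0;
          for (int i = lo; i < hi; ++i) dj0[i] = sj0[i + di];
          for (int i = hi; i < H; ++i) dj0[i] = 0.0;
        }
      }
    }
  }
}

// Scatter-add of transposed column-gradient patches back onto the input
// gradient (adjoint of im2col_t).
static void col2im_t_add(double* dx, int H, int W, int C, int n,
                         int kh, int kw, int d, const arma::mat& colT,
                         R_xlen_t rowOff) {
  const int rh = (kh - 1) / 2, rw = (kw - 1) / 2;
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    for (int mm = 0; mm < kw; ++mm) {
      for (int m = 0; m < kh; ++m) {
        const int kcol = m + kh * (mm + kw * c);
        const int di = (m - rh) * d, dj = (mm - rw) * d;
        const double* src = colT.colptr(kcol) + rowOff;
        double* base = dx + static_cast<R_xlen_t>(n) * H * W * C +
                       static_cast<R_xlen_t>(c) * HW;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const double* sj0 = src + static_cast<R_xlen_t>(j) * H;
          double* dj0 = base + static_cast<R_xlen_t>(sj) * H;
          const int lo = std::max(0, -di), hi = std::min(H, H - di);
          for (int i = lo; i < hi; ++i) dj0[i + di] += sj0[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dFwd")]]
NumericVector conv2d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector bias, int dilation) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv2d: input has %d channels but kernel expects %d", C, Cin);
  if (kh % 2 == 0 || kw % 2 == 0) stop("conv2d: kernels must be odd-sized");

  NumericVector y(static_cast<R_xlen_t>(H) * W * Cout * N);
  const int K = kh * kw * Cin, HW = H * W;
  arma::mat wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::rowvec b(const_cast<double*>(bias.begin()), Cout, false, true);
  int G = std::max(1, static_cast<int>(4000000 / (static_cast<R_xlen_t>(K) * HW)));
  if (G > N) G = N;
  arma::mat colT(static_cast<R_xlen_t>(HW) * G, K);
  for (int n0 = 0; n0 < N; n0 += G) {
    const int g = std::min(G, N - n0);
    for (int gi = 0; gi < g; ++gi)
      im2col_t(x.begin(), H, W, C, n0 + gi, kh, kw, dilation, colT,
               static_cast<R_xlen_t>(gi) * HW);
    arma::mat out = (g == G ? colT :
      arma::mat(colT.rows(0, static_cast<R_xlen_t>(g) * HW - 1))) * wm;
    for (int co = 0; co < Cout; ++co) out.col(co) += b[co];
    for (int gi = 0; gi < g; ++gi) {
      arma::mat dst(y.begin() + static_cast<R_xlen_t>(n0 + gi) * HW * Cout,
                    HW, Cout, false, true);
      dst = out.rows(static_cast<R_xlen_t>(gi) * HW,
                     static_cast<R_xlen_t>(gi + 1) * HW - 1);
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".conv2dBwd")]]
List conv2d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector w, IntegerVector wdim,
                NumericVector dy, int dilation) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];

  NumericVector dx(x.size());
  NumericVector dw(w.size());
  NumericVector db(Cout);
  const int K = kh * kw * Cin, HW = H * W;
  arma::mat wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dwm(dw.begin(), K, Cout, false, true);
  arma::colvec dbv(db.begin(), Cout, false, true);
  int G = std::max(1, static_cast<int>(4000000 / (static_cast<R_xlen_t>(K) * HW)));
  if (G > N) G = N;
  arma::mat colT(static_cast<R_xlen_t>(HW) * G, K);
  arma::mat gbig(static_cast<R_xlen_t>(HW) * G, Cout);

  for (int n0 = 0; n0 < N; n0 += G) {
    const int g = std::min(G, N - n0);
    for (int gi = 0; gi < g; ++gi) {
      im2col_t(x.begin(), H, W, C, n0 + gi, kh, kw, dilation, colT,
               static_cast<R_xlen_t>(gi) * HW);
      arma::mat gs(const_cast<double*>(dy.begin()) +
                   static_cast<R_xlen_t>(n0 + gi) * HW * Cout,
                   HW, Cout, false, true);
      gbig.rows(static_cast<R_xlen_t>(gi) * HW,
                static_cast<R_xlen_t>(gi + 1) * HW - 1) = gs;
      dbv += arma::sum(gs, 0).t();
    }
    if (g == G) {
      dwm += colT.t() * gbig;                  // (K, Cout)
      arma::mat colg = gbig * wm.t();          // (HW*g, K)
      for (int gi = 0; gi < g; ++gi)
        col2im_t_add(dx.begin(), H, W, C, n0 + gi, kh, kw, dilation, colg,
                     static_cast<R_xlen_t>(gi) * HW);
    } else {
      arma::mat sub = colT.rows(0, static_cast<R_xlen_t>(g) * HW - 1);
      arma::mat gsub = gbig.rows(0, static_cast<R_xlen_t>(g) * HW - 1);
      dwm += sub.t() * gsub;
      arma::mat colg = gsub * wm.t();
      for (int gi = 0; gi < g; ++gi)
        col2im_t_add(dx.begin(), H, W, C, n0 + gi, kh, kw, dilation, colg,
                     static_cast<R_xlen_t>(gi) * HW);
    }
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling with stride 2 (floor on odd extents).  Returns the pooled
// tensor and the flat input index of each maximum for the backward pass.
// [[Rcpp::export(name = ".maxpool2Fwd")]]
List maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) stop("maxpool2: input smaller than pool window");
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector amax(y.size());
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double best = R_NegInf; int besti = -1;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const int p = idx4(2 * i + di, 2 * j + dj, c, n, H, W, C);
              if (x[p] > best) { best = x[p]; besti = p; }
            }
          y[o] = best; amax[o] = besti; ++o;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool2Bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector argmax,
                           IntegerVector xdim) {
  NumericVector dx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t o = 0; o < dy.size(); ++o) dx[argmax[o]] += dy[o];
  dx.attr("dim") = xdim;
  return dx;
}

// ---- elementwise / normalization kernels ----------------------------------
// Layout note: viewing an (H, W, C, N) tensor as an (H*W) x (C*N) matrix is
// copy-free in column-major order; column j belongs to channel j % C.

// [[Rcpp::export(name = ".reluFwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".reluBwd")]]
NumericVector relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// Batch norm forward over channels: per-channel mean/sd across all spatial
// positions and samples.  form 0: denominator sigma + eps (as printed);
// form 1: sqrt(variance + eps).
// [[Rcpp::export(name = ".bnFwdC")]]
List bn_fwd(NumericVector x, IntegerVector xdim, NumericVector gamma,
            NumericVector beta, double eps, int form, bool training,
            NumericVector runMean, NumericVector runSigma) {
  const int HW = xdim[0] * xdim[1], C = xdim[2], N = xdim[3];
  const R_xlen_t per = HW;
  NumericVector mu(C), sig(C), s(C);
  if (training) {
    std::vector<double> sum(C, 0.0), sumsq(C, 0.0);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const double* p = x.begin() + (static_cast<R_xlen_t>(n) * C + c) * per;
        double a = 0, b = 0;
        for (int i = 0; i < HW; ++i) { a += p[i]; b += p[i] * p[i]; }
        sum[c] += a; sumsq[c] += b;
      }
    const double m = static_cast<double>(HW) * N;
    for (int c = 0; c < C; ++c) {
      mu[c] = sum[c] / m;
      double v = sumsq[c] / m - mu[c] * mu[c];
      sig[c] = v > 0 ? std::sqrt(v) : 0.0;
    }
  } else {
    for (int c = 0; c < C; ++c) { mu[c] = runMean[c]; sig[c] = runSigma[c]; }
  }
  for (int c = 0; c < C; ++c)
    s[c] = form == 0 ? sig[c] + eps : std::sqrt(sig[c] * sig[c] + eps);
  NumericVector y(x.size()), xhat(x.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (static_cast<R_xlen_t>(n) * C + c) * per;
      const double inv = 1.0 / s[c], g = gamma[c], b = beta[c], m0 = mu[c];
      const double* p = x.begin() + off;
      double* ph = xhat.begin() + off;
      double* py = y.begin() + off;
      for (int i = 0; i < HW; ++i) {
        ph[i] = (p[i] - m0) * inv;
        py[i] = g * ph[i] + b;
      }
    }
  y.attr("dim") = xdim; xhat.attr("dim") = xdim;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["sigma"] = sig, _["s"] = s);
}

// [[Rcpp::export(name = ".bnBwdC")]]
List bn_bwd(NumericVector dy, NumericVector xhat, IntegerVector xdim,
            NumericVector gamma, NumericVector sig, NumericVector s,
            int form, bool training) {
  const int HW = xdim[0] * xdim[1], C = xdim[2], N = xdim[3];
  const R_xlen_t per = HW;
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> G(C, 0.0), B(C, 0.0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (static_cast<R_xlen_t>(n) * C + c) * per;
      const double* pd = dy.begin() + off;
      const double* ph = xhat.begin() + off;
      double a = 0, b = 0;
      for (int i = 0; i < HW; ++i) { a += pd[i] * ph[i]; b += pd[i]; }
      G[c] += a; B[c] += b;
    }
  for (int c = 0; c < C; ++c) { dgamma[c] = G[c]; dbeta[c] = B[c]; }
  NumericVector dx(dy.size());
  const double m = static_cast<double>(HW) * N;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (static_cast<R_xlen_t>(n) * C + c) * per;
      const double* pd = dy.begin() + off;
      const double* ph = xhat.begin() + off;
      double* px = dx.begin() + off;
      const double g = gamma[c], inv = 1.0 / s[c];
      if (!training) {
        for (int i = 0; i < HW; ++i) px[i] = g * pd[i] * inv;
        continue;
      }
      const double S1 = g * B[c], S2 = g * G[c];
      if (form == 0) {
        // d/dsigma path vanishes when sigma == 0 (all residuals zero)
        const double k3 = sig[c] > 0 ? S2 / (m * sig[c]) : 0.0;
        for (int i = 0; i < HW; ++i)
          px[i] = (g * pd[i] - S1 / m) * inv - k3 * ph[i];
      } else {
        for (int i = 0; i < HW; ++i)
          px[i] = (g * pd[i] - S1 / m - ph[i] * S2 / m) * inv;
      }
    }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
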