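// Dense 2-D convolution and max-pooling kernels (forward + backward).
// Tensors are R arrays in (H, W, C, N) layout, column-major, double precision.
// Convolution is im2col + GEMM; the column matrix is built transposed
// (L x K, L = Ho*Wo, K = k*k*Cin) so the GEMM output lands directly in the
// (Ho*Wo, Cout) layout of the R result array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int in, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// Fill rows [row0, row0+L) of colsT (column-major, L_total x K) from one
// image slab x (H*W*C doubles).
// Row l = row0 + ho + Ho*wo; column r = ki + k*kj + k*k*c (ki indexes height).
static void im2col_t(const double* x, int H, int W, int C,
                     int k, int stride, int pad, int dil,
                     int Ho, int Wo, arma::mat& colsT, int row0) {
  const int L = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        double* dst = colsT.colptr(r) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj * dil;
          const int base = Ho * wo;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) dst[base + ho] = 0.0;
            continue;
          }
          const double* src = xc + (std::size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki * dil;
            dst[base + ho] = (hi < 0 || hi >= H) ? 0.0 : src[hi];
          }
        }
      }
    }
  }
  (void)L;
}

// Scatter-add colsT gradients back onto the input image slab.
static void col2im_t(const arma::mat& dcolsT, double* dx, int H, int W, int C,
                     int k, int stride, int pad, int dil, int Ho, int Wo,
                     int row0) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (std::size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        const double* src = dcolsT.colptr(r) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          double* dstc = xc + (std::size_t)H * wi;
          const int base = Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki * dil;
            if (hi < 0 || hi >= H) continue;
            dstc[hi] += src[base + ho];
          }
        }
      }
    }
  }
}

// Images are processed in chunks whose stacked column matrices stay under a
// fixed memory cap, so small feature maps share one GEMM per chunk while
// large early-layer maps fall back to per-image GEMMs.
static int chunk_images(int N, int L, int K) {
  const double cap = 32e6;  // doubles (~256 MB)
  int per = (int)(cap / ((double)L * K));
  if (per < 1) per = 1;
  if (per > N) per = N;
  return per;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector bias,
                                 int stride, int pad, int dil) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Ho = conv_out_dim(H, k, stride, pad, dil);
  const int Wo = conv_out_dim(W, k, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  const int K = k * k * C, L = Ho * Wo;

  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y((std::size_t)L * Cout * N);
  const bool has_bias = bias.size() == Cout;
  const int per = chunk_images(N, L, K);
  arma::mat colsT(L * per, K);
  for (int n0 = 0; n0 < N; n0 += per) {
    const int nc = std::min(per, N - n0);
    if (nc != per) colsT.set_size(L * nc, K);
    for (int j = 0; j < nc; ++j)
      im2col_t(x.begin() + (std::size_t)H * W * C * (n0 + j), H, W, C,
               k, stride, pad, dil, Ho, Wo, colsT, j * L);
    arma::mat yv = colsT * Wm;                    // (L*nc) x Cout
    for (int j = 0; j < nc; ++j) {
      arma::mat dst(y.begin() + (std::size_t)L * Cout * (n0 + j), L, Cout,
                    false, true);
      dst = yv.rows(j * L, (j + 1) * L - 1);
      if (has_bias)
        dst.each_row() += arma::rowvec(const_cast<double*>(bias.begin()),
                                       Cout, false, true);
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector dy, IntegerVector ydim,
                         int stride, int pad, int dil, bool need_dx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cout = wdim[3];
  const int Ho = ydim[0], Wo = ydim[1];
  const int K = k * k * C, L = Ho * Wo;

  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dw((std::size_t)K * Cout), db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  NumericVector dx(need_dx ? x.size() : 0);

  const int per = chunk_images(N, L, K);
  arma::mat colsT(L * per, K);
  for (int n0 = 0; n0 < N; n0 += per) {
    const int nc = std::min(per, N - n0);
    if (nc != per) colsT.set_size(L * nc, K);
    for (int j = 0; j < nc; ++j)
      im2col_t(x.begin() + (std::size_t)H * W * C * (n0 + j), H, W, C,
               k, stride, pad, dil, Ho, Wo, colsT, j * L);
    arma::mat dyv(L * nc, Cout);
    for (int j = 0; j < nc; ++j)
      dyv.rows(j * L, (j + 1) * L - 1) = arma::mat(
        const_cast<double*>(dy.begin()) + (std::size_t)L * Cout * (n0 + j),
        L, Cout, false, true);
    dWm += colsT.t() * dyv;
    dbv += arma::sum(dyv, 0).t();
    if (need_dx) {
      arma::mat dcolsT = dyv * Wm.t();            // (L*nc) x K
      for (int j = 0; j < nc; ++j)
        col2im_t(dcolsT, dx.begin() + (std::size_t)H * W * C * (n0 + j),
                 H, W, C, k, stride, pad, dil, Ho, Wo, j * L);
    }
  }
  dw.attr("dim") = IntegerVector::create(k, k, C, Cout);
  if (need_dx) dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling. ceil_mode follows the Caffe convention: the output grid is
// ceil((in + 2*pad - k)/stride) + 1, but a window must start inside the
// (padded) input; windows are clipped to the valid region.
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, IntegerVector xdim,
                         int k, int stride, int pad, bool ceil_mode) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  auto out_dim = [&](int in) {
    double v = double(in + 2 * pad - k) / stride;
    int o = (ceil_mode ? (int)std::ceil(v) : (int)std::floor(v)) + 1;
    if (ceil_mode && (o - 1) * stride >= in + pad) --o;
    return o;
  };
  const int Ho = out_dim(H), Wo = out_dim(W);
  if (Ho < 1 || Wo < 1) stop("maxpool: output size would be empty");

  NumericVector y((std::size_t)Ho * Wo * C * N);
  IntegerVector idx((std::size_t)Ho * Wo * C * N);  // slab-local argmax
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (std::size_t)H * W * C * n;
    double* ys = y.begin() + (std::size_t)Ho * Wo * C * n;
    int* is = idx.begin() + (std::size_t)Ho * Wo * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xs + (std::size_t)H * W * c;
      for (int wo = 0; wo < Wo; ++wo) {
        int w0 = wo * stride - pad, w1 = std::min(w0 + k, W);
        w0 = std::max(w0, 0);
        for (int ho = 0; ho < Ho; ++ho) {
          int h0 = ho * stride - pad, h1 = std::min(h0 + k, H);
          h0 = std::max(h0, 0);
          double best = -std::numeric_limits<double>::infinity();
          int best_i = -1;
          for (int wi = w0; wi < w1; ++wi)
            for (int hi = h0; hi < h1; ++hi) {
              const double v = xc[hi + (std::size_t)H * wi];
              if (v > best) { best = v; best_i = hi + H * wi; }
            }
          const std::size_t o = (std::size_t)ho + Ho * wo + (std::size_t)Ho * Wo * c;
          ys[o] = best;
          is[o] = best_i + H * W * c;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector idx,
                                   IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const std::size_t slab = (std::size_t)H * W * C;
  const std::size_t per = (std::size_t)dy.size() / N;
  NumericVector dx(slab * N);
  for (int n = 0; n < N; ++n) {
    double* dxs = dx.begin() + slab * n;
    const double* dys = dy.begin() + per * n;
    const int* is = idx.begin() + per * n;
    for (std::size_t i = 0; i < per; ++i) dxs[is[i]] += dys[i];
  }
  dx.attr("dim") = xdim;
  return dx;
}

// In-place momentum-SGD update: v = momentum*v - lr*(g + wd*w); w += v.
// Mutates w and v directly; the training loop owns private copies.
// [[Rcpp::export]]
void cpp_sgd_step(NumericVector w, NumericVector v, NumericVector g,
                  double lr, double momentum, double wd) {
  const R_xlen_t n = w.size();
  if (v.size() != n || g.size() != n) stop("sgd: length mismatch");
  double* wp = w.begin(); double* vp = v.begin(); const double* gp = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    vp[i] = momentum * vp[i] - lr * (gp[i] + wd * wp[i]);
    wp[i] += vp[i];
  }
}
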