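// GEMM-based 2-D convolution kernels (im2col / col2im) used by the
// residual encoder. Layout convention, fixed project-wide:
//   activations: array [H, W, C, N]   (column-major, R-native)
//   weights:     array [kh, kw, C, K]
// Padding is zero-padding; stride is isotropic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill M (kh*kw*C x OH*OW) with patches of one image.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int OH, int OW, arma::mat& M) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          const int wi = ow * stride - pad + j;
          double* Mcol = M.memptr() + (size_t)M.n_rows * (size_t)OH * ow + r;
          if (wi < 0 || wi >= W) {
            for (int oh = 0; oh < OH; ++oh) Mcol[(size_t)M.n_rows * oh] = 0.0;
            continue;
          }
          for (int oh = 0; oh < OH; ++oh) {
            const int hi = oh * stride - pad + i;
            Mcol[(size_t)M.n_rows * oh] =
              (hi >= 0 && hi < H) ? xc[hi + (size_t)H * wi] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add columns of dM back into dx for one image.
static void col2im(const arma::mat& dM, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int OH, int OW, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* dxc = dx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          const int wi = ow * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int oh = 0; oh < OH; ++oh) {
            const int hi = oh * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            dxc[hi + (size_t)H * wi] += dM(r, oh + (size_t)OH * ow);
          }
        }
      }
    }
  }
}

static arma::mat weight_matrix(const NumericVector& w,
                               int kh, int kw, int C, int K) {
  // rows: K filters, cols: kh*kw*C receptive-field entries
  arma::mat Wm(K, (size_t)kh * kw * C);
  const double* wp = w.begin();
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          Wm(k, i + kh * (j + kw * c)) =
            wp[i + (size_t)kh * (j + (size_t)kw * (c + (size_t)C * k))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cw = wd[2], K = wd[3];
  if (C != Cw) stop("conv2d: input has %d channels but kernel expects %d", C, Cw);
  if (b.size() != K) stop("conv2d: bias length %d != %d filters", (int)b.size(), K);
  const int OH = out_size(H, kh, stride, pad);
  const int OW = out_size(W, kw, stride, pad);

  arma::mat Wm = weight_matrix(w, kh, kw, C, K);
  arma::mat M((size_t)kh * kw * C, (size_t)OH * OW);
  arma::colvec bv(b.begin(), K);

  NumericVector out((size_t)OH * OW * K * N);
  out.attr("dim") = IntegerVector::create(OH, OW, K, N);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, OH, OW, M);
    arma::mat Y = Wm * M;              // K x OH*OW
    Y.each_col() += bv;
    double* op = out.begin() + (size_t)OH * OW * K * n;
    // out layout [OH, OW, K]: transpose K x (OH*OW)
    for (int k = 0; k < K; ++k)
      for (size_t p = 0; p < (size_t)OH * OW; ++p)
        op[p + (size_t)OH * OW * k] = Y(k, p);
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad, bool need_dx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], K = wd[3];
  const int OH = out_size(H, kh, stride, pad);
  const int OW = out_size(W, kw, stride, pad);

  arma::mat Wm = weight_matrix(w, kh, kw, C, K);
  arma::mat M((size_t)kh * kw * C, (size_t)OH * OW);
  arma::mat dWm(K, (size_t)kh * kw * C, arma::fill::zeros);
  arma::colvec db(K, arma::fill::zeros);

  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = xd;

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, OH, OW, M);
    // G: K x OH*OW from dy layout [OH, OW, K]
    arma::mat G(K, (size_t)OH * OW);
    const double* dp = dy.begin() + (size_t)OH * OW * K * n;
    for (int k = 0; k < K; ++k)
      for (size_t p = 0; p < (size_t)OH * OW; ++p)
        G(k, p) = dp[p + (size_t)OH * OW * k];
    dWm += G * M.t();
    db += arma::sum(G, 1);
    if (need_dx) {
      arma::mat dM = Wm.t() * G;
      col2im(dM, H, W, C, kh, kw, stride, pad, OH, OW,
             dx.begin() + (size_t)H * W * C * n);
    }
  }

  NumericVector dwv(w.size());
  dwv.attr("dim") = wd;
  double* dwp = dwv.begin();
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          dwp[i + (size_t)kh * (j + (size_t)kw * (c + (size_t)C * k))] =
            dWm(k, i + kh * (j + kw * c));

  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
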