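// Convolution and pooling kernels for the image models. Activations are
// (H, W, N, C) column-major arrays, matching the R side. Convolutions go
// through an im2col patch matrix so the arithmetic runs in BLAS; the
// backward pass rebuilds the patches rather than caching them, trading a
// little compute for memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// build im2col matrix: rows (h2 + H2*(w2 + W2*n)), cols (i + k*(j + k*c))
static arma::mat im2col(const double* X, int H, int W, int N, int C,
                        int k, int stride, int pad, int H2, int W2) {
  arma::mat P(static_cast<size_t>(H2) * W2 * N, static_cast<size_t>(k) * k * C,
              arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* Xc = X + static_cast<size_t>(H) * W * N * c;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const size_t col = i + k * (j + k * c);
        double* Pcol = P.colptr(col);
        for (int n = 0; n < N; ++n) {
          const double* Xn = Xc + static_cast<size_t>(H) * W * n;
          for (int w2 = 0; w2 < W2; ++w2) {
            const int w = j + stride * w2 - pad;
            if (w < 0 || w >= W) continue;
            const double* Xw = Xn + static_cast<size_t>(H) * w;
            double* Pr = Pcol + static_cast<size_t>(H2) * (w2 + static_cast<size_t>(W2) * n);
            for (int h2 = 0; h2 < H2; ++h2) {
              const int h = i + stride * h2 - pad;
              if (h < 0 || h >= H) continue;
              Pr[h2] = Xw[h];
            }
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector X, NumericVector Wt, NumericVector b,
                           int stride, int pad) {
  IntegerVector xd = X.attr("dim");
  IntegerVector wd = Wt.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  const int k = wd[0], F = wd[3];
  const int H2 = out_size(H, k, stride, pad), W2 = out_size(W, k, stride, pad);
  arma::mat P = im2col(X.begin(), H, W, N, C, k, stride, pad, H2, W2);
  arma::mat Wm(Wt.begin(), static_cast<size_t>(k) * k * C, F, false);
  arma::mat Y = P * Wm;
  Y.each_row() += arma::rowvec(b.begin(), F, false);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(H2, W2, N, F);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector dY, NumericVector X, NumericVector Wt,
                  int stride, int pad) {
  IntegerVector xd = X.attr("dim");
  IntegerVector wd = Wt.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  const int k = wd[0], F = wd[3];
  const int H2 = out_size(H, k, stride, pad), W2 = out_size(W, k, stride, pad);
  const size_t rows = static_cast<size_t>(H2) * W2 * N;
  arma::mat P = im2col(X.begin(), H, W, N, C, k, stride, pad, H2, W2);
  arma::mat dYm(dY.begin(), rows, F, false);
  arma::mat Wm(Wt.begin(), static_cast<size_t>(k) * k * C, F, false);
  arma::mat dW = P.t() * dYm;              // (kkC, F)
  arma::rowvec db = arma::sum(dYm, 0);
  arma::mat dP = dYm * Wm.t();             // (rows, kkC)
  NumericVector dX(static_cast<R_xlen_t>(H) * W * N * C);
  double* dXp = dX.begin();
  for (int c = 0; c < C; ++c) {
    double* dXc = dXp + static_cast<size_t>(H) * W * N * c;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const size_t col = i + k * (j + k * c);
        const double* Pcol = dP.colptr(col);
        for (int n = 0; n < N; ++n) {
          double* dXn = dXc + static_cast<size_t>(H) * W * n;
          for (int w2 = 0; w2 < W2; ++w2) {
            const int w = j + stride * w2 - pad;
            if (w < 0 || w >= W) continue;
            double* dXw = dXn + static_cast<size_t>(H) * w;
            const double* Pr = Pcol + static_cast<size_t>(H2) * (w2 + static_cast<size_t>(W2) * n);
            for (int h2 = 0; h2 < H2; ++h2) {
              const int h = i + stride * h2 - pad;
              if (h < 0 || h >= H) continue;
              dXw[h] += Pr[h2];
            }
          }
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(H, W, N, C);
  NumericVector dWout(dW.begin(), dW.end());
  dWout.attr("dim") = IntegerVector::create(k, k, C, F);
  return List::create(_["dX"] = dX, _["dW"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2; returns pooled values and argmax linear index
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector X) {
  IntegerVector xd = X.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  const int H2 = H / 2, W2 = W / 2;
  NumericVector Y(static_cast<R_xlen_t>(H2) * W2 * N * C);
  IntegerVector arg(Y.size());
  const double* x = X.begin();
  double* y = Y.begin();
  int* a = arg.begin();
  size_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const size_t base = static_cast<size_t>(H) * W * (n + static_cast<size_t>(N) * c);
      for (int w2 = 0; w2 < W2; ++w2)
        for (int h2 = 0; h2 < H2; ++h2, ++o) {
          size_t best = base + static_cast<size_t>(H) * (2 * w2) + 2 * h2;
          double bv = x[best];
          const int hh[2] = {2 * h2, 2 * h2 + 1};
          const int ww[2] = {2 * w2, 2 * w2 + 1};
          for (int jj = 0; jj < 2; ++jj)
            for (int ii = 0; ii < 2; ++ii) {
              const size_t idx = base + static_cast<size_t>(H) * ww[jj] + hh[ii];
              if (x[idx] > bv) { bv = x[idx]; best = idx; }
            }
          y[o] = bv;
          a[o] = static_cast<int>(best);
        }
    }
  // reorder: we filled in (h2, w2) within (n, c) blocks, matching
  // (H2, W2, N, C) layout because h2 runs fastest, then w2, then n, then c
  Y.attr("dim") = IntegerVector::create(H2, W2, N, C);
  return List::create(_["Y"] = Y, _["argmax"] = arg,
                      _["in_dim"] = IntegerVector::create(H, W, N, C));
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dY, IntegerVector argmax,
                               IntegerVector in_dim) {
  NumericVector dX(static_cast<R_xlen_t>(in_dim[0]) * in_dim[1] * in_dim[2] * in_dim[3]);
  double* p = dX.begin();
  const double* g = dY.begin();
  const int* a = argmax.begin();
  for (R_xlen_t o = 0; o < dY.size(); ++o) p[a[o]] += g[o];
  dX.attr("dim") = in_dim;
  return dX;
}

// 3x3 average pooling, stride 1, same (zero) padding with uniform 1/9
// weight; symmetric, so it is its own adjoint
// [[Rcpp::export]]
NumericVector cpp_avgpool3(NumericVector X) {
  IntegerVector xd = X.attr("dim");
  const int H = xd[0], W = xd[1];
  const R_xlen_t planes = static_cast<R_xlen_t>(xd[2]) * xd[3];
  NumericVector Y(X.size());
  const double* x = X.begin();
  double* y = Y.begin();
  for (R_xlen_t p = 0; p < planes; ++p) {
    const double* xp = x + static_cast<size_t>(H) * W * p;
    double* yp = y + static_cast<size_t>(H) * W * p;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double s = 0;
        for (int dw = -1; dw <= 1; ++dw) {
          const int ww = w + dw;
          if (ww < 0 || ww >= W) continue;
          const double* xc = xp + static_cast<size_t>(H) * ww;
          for (int dh = -1; dh <= 1; ++dh) {
            const int hh = h + dh;
            if (hh < 0 || hh >= H) continue;
            s += xc[hh];
          }
        }
        yp[h + static_cast<size_t>(H) * w] = s / 9.0;
      }
  }
  Y.attr("dim") = xd;
  return Y;
}
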