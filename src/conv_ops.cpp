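// Minimal 2-D convolution kernels (im2col / col2im) used by the residual
// backbone.  Activations are stored as (C*H*W) x N matrices; within a
// column, channel blocks are contiguous and spatial positions follow R's
// column-major matrix vectorization (row index fastest).
//
// Patches are built per sample so the working set stays cache-resident.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void im2col(const double* x, int C, int H, int W,
                          int k, int stride, int pad,
                          int Ho, int Wo, mat& P) {
  // P: (C*k*k) x (Ho*Wo); patch layout matches column-major vectorization
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = wo * Ho + ho;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      double* pc = P.colptr(col);
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            const int idx = c * k * k + kw * k + kh;
            pc[idx] = (h >= 0 && h < H && w >= 0 && w < W)
              ? xc[(size_t)w * H + h] : 0.0;
          }
        }
      }
    }
  }
}

static inline void col2im(const mat& P, int C, int H, int W,
                          int k, int stride, int pad,
                          int Ho, int Wo, double* dx) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = wo * Ho + ho;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      const double* pc = P.colptr(col);
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            if (h < 0 || h >= H) continue;
            xc[(size_t)w * H + h] += pc[c * k * k + kw * k + kh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv2d_fwd_cpp(const arma::mat& X, const arma::mat& Wm,
                         const arma::vec& b, int C, int H, int W,
                         int k, int stride, int pad) {
  const int N = X.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.n_rows;
  mat Y((size_t)Cout * Ho * Wo, N);
  mat P(C * k * k, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(X.colptr(n), C, H, W, k, stride, pad, Ho, Wo, P);
    mat y = Wm * P;            // Cout x (Ho*Wo)
    y.each_col() += b;
    Y.col(n) = vectorise(y.t());  // channel blocks contiguous
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_cpp(const arma::mat& X, const arma::mat& Wm,
                          const arma::mat& dY, int C, int H, int W,
                          int k, int stride, int pad) {
  const int N = X.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.n_rows;
  mat dX(size(X), fill::zeros);
  mat dW(size(Wm), fill::zeros);
  vec db(Cout, fill::zeros);
  mat P(C * k * k, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(X.colptr(n), C, H, W, k, stride, pad, Ho, Wo, P);
    // dY column n is (Cout*Ho*Wo) with spatial fastest; undo the transpose
    mat dy = reshape(mat(dY.col(n)), Ho * Wo, Cout).t();  // Cout x HoWo
    dW += dy * P.t();
    db += sum(dy, 1);
    mat dP = Wm.t() * dy;  // (C*k*k) x HoWo
    col2im(dP, C, H, W, k, stride, pad, Ho, Wo, dX.colptr(n));
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
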