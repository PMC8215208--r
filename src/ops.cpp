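#include <Rcpp.h>
using namespace Rcpp;

// Activation layout used throughout: a numeric matrix with C rows and
// H*W*N columns, column index j = h + H*(w + W*n) (h fastest, 0-based).
// Convolution weights are Cout x (k*k*Cin) with patch row index
// r = dh + k*(dw + k*c), so conv is a single GEMM against the im2col
// matrix (the GEMM itself happens in R via %*% / BLAS).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int H, int W, int N,
                         int k, int stride, int pad) {
  const int C = x.nrow();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(k * k * C, Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int j = ho + Ho * (wo + Wo * n);
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          for (int dw = 0; dw < k; ++dw) {
            const int w = w0 + dw;
            for (int dh = 0; dh < k; ++dh) {
              const int h = h0 + dh;
              const int r = dh + k * (dw + k * c);
              if (h >= 0 && h < H && w >= 0 && w < W) {
                out(r, j) = x(c, h + H * (w + W * n));
              } // else stays 0 (zero padding)
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add adjoint of cpp_im2col: cols has k*k*C rows, Ho*Wo*N columns.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& cols, int H, int W, int C,
                         int N, int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C, H * W * N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int j = ho + Ho * (wo + Wo * n);
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          for (int dw = 0; dw < k; ++dw) {
            const int w = w0 + dw;
            if (w < 0 || w >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              const int h = h0 + dh;
              if (h < 0 || h >= H) continue;
              const int r = dh + k * (dw + k * c);
              out(c, h + H * (w + W * n)) += cols(r, j);
            }
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling, stride 2. Returns pooled activations and the 1-based
// linear element index (into the input matrix) of each maximum, for the
// backward scatter.
// [[Rcpp::export]]
List cpp_maxpool(const NumericMatrix& x, int H, int W, int N) {
  const int C = x.nrow();
  const int Ho = H / 2, Wo = W / 2;
  NumericMatrix out(C, Ho * Wo * N);
  IntegerMatrix idx(C, Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int j = ho + Ho * (wo + Wo * n);
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          int best_col = -1;
          for (int dw = 0; dw < 2; ++dw) {
            for (int dh = 0; dh < 2; ++dh) {
              const int col = (2 * ho + dh) + H * ((2 * wo + dw) + W * n);
              const double v = x(c, col);
              if (v > best) { best = v; best_col = col; }
            }
          }
          out(c, j) = best;
          idx(c, j) = c + C * best_col + 1; // 1-based element index
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_backward(const NumericMatrix& gout,
                                   const IntegerMatrix& idx,
                                   int C, int ncol_in) {
  NumericMatrix gin(C, ncol_in);
  const int total = gout.nrow() * gout.ncol();
  for (int t = 0; t < total; ++t) {
    gin[idx[t] - 1] += gout[t];
  }
  return gin;
}
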