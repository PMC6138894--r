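// Low-level image-patch kernels backing the fully convolutional network.
// Activations travel as (B*H*W) x C column-major matrices; the rows of
// sample b are b*H*W .. (b+1)*H*W - 1, within a sample in R plane order
// (row index fastest), so a slab is memory-identical to B stacked
// (H, W, C) arrays per channel column.
//
// im2col rows index output positions as row = b*HoWo + jo*Ho + io and
// columns index patch elements as col = c*(kh*kw) + kj*kh + ki, so a
// convolution is  im2col(x) * W  with W of shape (kh*kw*Cin, Cout).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int ceil_div(int a, int b) { return (a + b - 1) / b; }

// [[Rcpp::export]]
arma::mat im2col_batch_cpp(const arma::mat& x, int H, int W, int B,
                           int kh, int kw, int pad, int stride) {
  const int C = x.n_cols, N = H * W;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int No = Ho * Wo;
  arma::mat cols(B * No, kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* dst = cols.colptr(c * kh * kw + kj * kh + ki);
        const int io_min = std::max(0, ceil_div(pad - ki, stride));
        const int io_max = std::min(Ho - 1, (H - 1 + pad - ki) / stride);
        if (io_max < io_min) continue;
        for (int b = 0; b < B; ++b) {
          for (int jo = 0; jo < Wo; ++jo) {
            const int j = jo * stride - pad + kj;
            if (j < 0 || j >= W) continue;
            const double* s = src + (size_t)b * N + (size_t)j * H - pad + ki;
            double* d = dst + (size_t)b * No + (size_t)jo * Ho;
            if (stride == 1) {
              std::memcpy(d + io_min, s + io_min,
                          (io_max - io_min + 1) * sizeof(double));
            } else {
              for (int io = io_min; io <= io_max; ++io)
                d[io] = s[io * stride];
            }
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add adjoint of im2col_batch; also the forward pass of a
// transposed convolution when `cols` is x * t(W).
// [[Rcpp::export]]
arma::mat col2im_batch_cpp(const arma::mat& cols, int H, int W, int C, int B,
                           int kh, int kw, int pad, int stride) {
  const int N = H * W;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int No = Ho * Wo;
  arma::mat x(B * N, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = x.colptr(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* src = cols.colptr(c * kh * kw + kj * kh + ki);
        const int io_min = std::max(0, ceil_div(pad - ki, stride));
        const int io_max = std::min(Ho - 1, (H - 1 + pad - ki) / stride);
        if (io_max < io_min) continue;
        for (int b = 0; b < B; ++b) {
          for (int jo = 0; jo < Wo; ++jo) {
            const int j = jo * stride - pad + kj;
            if (j < 0 || j >= W) continue;
            double* d = dst + (size_t)b * N + (size_t)j * H - pad + ki;
            const double* s = src + (size_t)b * No + (size_t)jo * Ho;
            for (int io = io_min; io <= io_max; ++io)
              d[io * stride] += s[io];
          }
        }
      }
    }
  }
  return x;
}

// size x size max pooling over a whole batch. idx holds the 0-based flat row
// index (into the input matrix) of each selected maximum; earliest position
// wins ties, for determinism.
// [[Rcpp::export]]
List maxpool_fwd_batch_cpp(const arma::mat& x, int H, int W, int B, int size) {
  const int C = x.n_cols, N = H * W;
  const int Ho = H / size, Wo = W / size, No = Ho * Wo;
  arma::mat out(B * No, C);
  IntegerMatrix idx(B * No, C);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = out.colptr(c);
    for (int b = 0; b < B; ++b) {
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double best = -std::numeric_limits<double>::infinity();
          size_t best_flat = 0;
          for (int kj = 0; kj < size; ++kj) {
            const size_t base = (size_t)b * N + (size_t)(jo * size + kj) * H
                                + io * size;
            for (int ki = 0; ki < size; ++ki) {
              const double v = src[base + ki];
              if (v > best) { best = v; best_flat = base + ki; }
            }
          }
          const size_t orow = (size_t)b * No + (size_t)jo * Ho + io;
          dst[orow] = best;
          idx(orow, c) = (int)best_flat;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat maxpool_bwd_batch_cpp(const arma::mat& dout, const IntegerMatrix& idx,
                                int n_rows) {
  const int C = dout.n_cols, No = dout.n_rows;
  arma::mat dx(n_rows, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* s = dout.colptr(c);
    double* d = dx.colptr(c);
    for (int r = 0; r < No; ++r) d[idx(r, c)] += s[r];
  }
  return dx;
}
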