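// im2col / col2im kernels for the BLAS-backed convolutions.
//
// Activation layout everywhere: (H, W, N, C) column-major, i.e. linear
// index i + H*(j + W*(n + N*c)). The im2col matrix has one row per output
// location (i, j, n) and one column per kernel tap (ki, kj, c), matching
// matrix(W, k*k*Cin, Cout) on the R side. Zero padding is folded in here,
// so no padded copy of the input is ever materialised.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// valid output range [lo, hi) for source index i*stride + koff - pad in [0, limit)
static inline void valid_range(int koff, int pad, int stride, int limit,
                               int out, int* lo, int* hi) {
  int l = 0;
  int off = koff - pad;
  if (off < 0) l = (-off + stride - 1) / stride;
  int h = out;
  // need i*stride + off <= limit - 1  =>  i <= (limit - 1 - off) / stride
  int hmax = (limit - 1 - off);
  if (hmax < 0) h = 0; else h = std::min(out, hmax / stride + 1);
  *lo = std::min(l, out);
  *hi = std::max(h, *lo);
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  const int ho = (H + 2 * pad - k) / stride + 1;
  const int wo = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t m = (R_xlen_t)ho * wo * N;
  NumericMatrix cols(no_init(m, (R_xlen_t)k * k * C));
  const double* xp = x.begin();
  double* out = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      int jlo, jhi;
      valid_range(kj, pad, stride, W, wo, &jlo, &jhi);
      for (int ki = 0; ki < k; ++ki) {
        int ilo, ihi;
        valid_range(ki, pad, stride, H, ho, &ilo, &ihi);
        const int col = ki + k * (kj + k * c);
        double* dst = out + (R_xlen_t)col * m;
        for (int n = 0; n < N; ++n) {
          const double* plane = xp + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
          double* dcol = dst + (R_xlen_t)ho * wo * n;
          for (int j = 0; j < wo; ++j, dcol += ho) {
            if (j < jlo || j >= jhi) {
              std::memset(dcol, 0, sizeof(double) * ho);
              continue;
            }
            const double* s = plane + (R_xlen_t)H * (j * stride + kj - pad)
                              + (ki - pad);
            if (ilo > 0) std::memset(dcol, 0, sizeof(double) * ilo);
            if (stride == 1) {
              std::memcpy(dcol + ilo, s + ilo, sizeof(double) * (ihi - ilo));
            } else {
              for (int i = ilo; i < ihi; ++i) dcol[i] = s[(R_xlen_t)i * stride];
            }
            if (ihi < ho) std::memset(dcol + ihi, 0,
                                      sizeof(double) * (ho - ihi));
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcols, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  const int ho = (H + 2 * pad - k) / stride + 1;
  const int wo = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t m = (R_xlen_t)ho * wo * N;
  NumericVector dx((R_xlen_t)H * W * N * C);
  const double* src0 = dcols.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      int jlo, jhi;
      valid_range(kj, pad, stride, W, wo, &jlo, &jhi);
      for (int ki = 0; ki < k; ++ki) {
        int ilo, ihi;
        valid_range(ki, pad, stride, H, ho, &ilo, &ihi);
        const int col = ki + k * (kj + k * c);
        const double* src = src0 + (R_xlen_t)col * m;
        for (int n = 0; n < N; ++n) {
          double* plane = dxp + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
          const double* scol = src + (R_xlen_t)ho * wo * n;
          for (int j = jlo; j < jhi; ++j) {
            double* d = plane + (R_xlen_t)H * (j * stride + kj - pad)
                        + (ki - pad);
            const double* s = scol + (R_xlen_t)ho * j;
            if (stride == 1) {
              for (int i = ilo; i < ihi; ++i) d[i] += s[i];
            } else {
              for (int i = ilo; i < ihi; ++i) d[(R_xlen_t)i * stride] += s[i];
            }
          }
        }
      }
    }
  }
  return dx;
}
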