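// Patch extraction (im2col) and its adjoint (col2im) for 3x3 convolutions
// with zero padding 1 and stride 1 or 2, on tensors laid out (H, W, N, C)
// column-major. These two loops dominate the U-Net's runtime; the matrix
// products themselves are left to R's BLAS.

#include <Rcpp.h>
using namespace Rcpp;

// x: (H, W, N, Cin) -> M: (Ho*Wo*N, 9*Cin); column q = (kx*3 + ky)*Cin + c
// holds input pixel (i*stride + ky - 1, j*stride + kx - 1) of channel c.
// [[Rcpp::export(name = ".im2col3")]]
NumericMatrix im2col3(NumericVector x, int H, int W, int N, int Cin,
                      int stride) {
  const int Ho = (H + stride - 1) / stride;
  const int Wo = (W + stride - 1) / stride;
  const R_xlen_t rows = (R_xlen_t)Ho * Wo * N;
  NumericMatrix M(no_init(rows, 9 * Cin));
  const double *px = x.begin();
  double *pm = M.begin();
  for (int kx = 0; kx < 3; ++kx) {
    for (int ky = 0; ky < 3; ++ky) {
      for (int c = 0; c < Cin; ++c) {
        const int q = (kx * 3 + ky) * Cin + c;
        double *col = pm + (R_xlen_t)q * rows;
        const double *chan = px + (R_xlen_t)c * H * W * N;
        R_xlen_t r = 0;
        for (int n = 0; n < N; ++n) {
          const double *img = chan + (R_xlen_t)n * H * W;
          for (int j = 0; j < Wo; ++j) {
            const int sw = j * stride + kx - 1;
            if (sw < 0 || sw >= W) {
              for (int i = 0; i < Ho; ++i) col[r++] = 0.0;
              continue;
            }
            const double *colsrc = img + (R_xlen_t)sw * H;
            for (int i = 0; i < Ho; ++i) {
              const int sh = i * stride + ky - 1;
              col[r++] = (sh < 0 || sh >= H) ? 0.0 : colsrc[sh];
            }
          }
        }
      }
    }
  }
  return M;
}

// adjoint of im2col3: scatter-add patch gradients back onto the input grid
// [[Rcpp::export(name = ".col2im3")]]
NumericVector col2im3(NumericMatrix gM, int H, int W, int N, int Cin,
                      int stride) {
  const int Ho = (H + stride - 1) / stride;
  const int Wo = (W + stride - 1) / stride;
  const R_xlen_t rows = (R_xlen_t)Ho * Wo * N;
  NumericVector gx((R_xlen_t)H * W * N * Cin);
  const double *pm = gM.begin();
  double *px = gx.begin();
  for (int kx = 0; kx < 3; ++kx) {
    for (int ky = 0; ky < 3; ++ky) {
      for (int c = 0; c < Cin; ++c) {
        const int q = (kx * 3 + ky) * Cin + c;
        const double *col = pm + (R_xlen_t)q * rows;
        double *chan = px + (R_xlen_t)c * H * W * N;
        R_xlen_t r = 0;
        for (int n = 0; n < N; ++n) {
          double *img = chan + (R_xlen_t)n * H * W;
          for (int j = 0; j < Wo; ++j) {
            const int sw = j * stride + kx - 1;
            if (sw < 0 || sw >= W) { r += Ho; continue; }
            double *coldst = img + (R_xlen_t)sw * H;
            for (int i = 0; i < Ho; ++i, ++r) {
              const int sh = i * stride + ky - 1;
              if (sh >= 0 && sh < H) coldst[sh] += col[r];
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, N, Cin);
  return gx;
}
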