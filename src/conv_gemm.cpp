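// Fused 3x3 convolution (zero padding 1, stride 1 or 2) and its backward
// pass. Patches are gathered per image into a small reusable buffer and
// multiplied with BLAS dgemm, so no full im2col matrix is ever
// materialized; the backward pass regathers patches instead of caching
// them. Tensors are (H, W, N, C) column-major; weights are
// (9*Cin x Cout) with column block q = (kx*3 + ky)*Cin + c.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// gather the 3x3 patch matrix (HoWo x 9Cin) of image n into buf
static void gather_image(const double *x, int H, int W, int N, int Cin,
                         int stride, int n, int Ho, int Wo, double *buf) {
  const int rows = Ho * Wo;
  for (int kx = 0; kx < 3; ++kx) {
    for (int ky = 0; ky < 3; ++ky) {
      for (int c = 0; c < Cin; ++c) {
        double *col = buf + (size_t)((kx * 3 + ky) * Cin + c) * rows;
        const double *img = x + ((R_xlen_t)c * N + n) * H * W;
        size_t r = 0;
        for (int j = 0; j < Wo; ++j) {
          const int sw = j * stride + kx - 1;
          if (sw < 0 || sw >= W) {
            for (int i = 0; i < Ho; ++i) col[r++] = 0.0;
            continue;
          }
          const double *src = img + (size_t)sw * H;
          for (int i = 0; i < Ho; ++i) {
            const int sh = i * stride + ky - 1;
            col[r++] = (sh < 0 || sh >= H) ? 0.0 : src[sh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3_gemm")]]
NumericVector conv3_gemm(NumericVector x, int H, int W, int N, int Cin,
                         NumericMatrix w, NumericVector b, int stride) {
  const int Ho = (H + stride - 1) / stride;
  const int Wo = (W + stride - 1) / stride;
  const int rows = Ho * Wo;
  const int K = 9 * Cin;
  const int Cout = w.ncol();
  NumericVector y(no_init((R_xlen_t)rows * N * Cout));
  std::vector<double> buf((size_t)rows * K);
  const double one = 1.0, zero = 0.0;
  const double *pw = w.begin();
  double *py = y.begin();
  std::vector<double> out((size_t)rows * Cout);
  for (int n = 0; n < N; ++n) {
    gather_image(x.begin(), H, W, N, Cin, stride, n, Ho, Wo, buf.data());
    F77_CALL(dgemm)("N", "N", &rows, &Cout, &K, &one, buf.data(), &rows,
                    pw, &K, &zero, out.data(), &rows FCONE FCONE);
    // scatter (rows x Cout) into (Ho, Wo, N, Cout) with bias
    for (int c = 0; c < Cout; ++c) {
      double *dst = py + ((R_xlen_t)c * N + n) * rows;
      const double *src = out.data() + (size_t)c * rows;
      const double bc = b[c];
      for (int r = 0; r < rows; ++r) dst[r] = src[r] + bc;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, Cout);
  return y;
}

// [[Rcpp::export(name = ".conv3_gemm_bwd")]]
List conv3_gemm_bwd(NumericVector x, NumericVector dy, int H, int W, int N,
                    int Cin, NumericMatrix w, int stride) {
  const int Ho = (H + stride - 1) / stride;
  const int Wo = (W + stride - 1) / stride;
  const int rows = Ho * Wo;
  const int K = 9 * Cin;
  const int Cout = w.ncol();
  NumericVector gx((R_xlen_t)H * W * N * Cin);
  NumericMatrix gw(K, Cout);
  NumericVector gb(Cout);
  std::vector<double> buf((size_t)rows * K), dyn((size_t)rows * Cout),
      gm((size_t)rows * K);
  const double one = 1.0, zero = 0.0;
  const double *pdy = dy.begin(), *pw = w.begin();
  for (int n = 0; n < N; ++n) {
    // collect this image's dy block (rows x Cout) and the bias gradient
    for (int c = 0; c < Cout; ++c) {
      const double *src = pdy + ((R_xlen_t)c * N + n) * rows;
      double *dst = dyn.data() + (size_t)c * rows;
      double s = 0;
      for (int r = 0; r < rows; ++r) { dst[r] = src[r]; s += src[r]; }
      gb[c] += s;
    }
    gather_image(x.begin(), H, W, N, Cin, stride, n, Ho, Wo, buf.data());
    // gw += buf^T dyn
    F77_CALL(dgemm)("T", "N", &K, &Cout, &rows, &one, buf.data(), &rows,
                    dyn.data(), &rows, &one, gw.begin(), &K FCONE FCONE);
    // gm = dyn w^T, then scatter-add onto the input grid
    F77_CALL(dgemm)("N", "T", &rows, &K, &Cout, &one, dyn.data(), &rows,
                    pw, &K, &zero, gm.data(), &rows FCONE FCONE);
    for (int kx = 0; kx < 3; ++kx) {
      for (int ky = 0; ky < 3; ++ky) {
        for (int c = 0; c < Cin; ++c) {
          const double *col = gm.data() +
            (size_t)((kx * 3 + ky) * Cin + c) * rows;
          double *img = gx.begin() + ((R_xlen_t)c * N + n) * H * W;
          size_t r = 0;
          for (int j = 0; j < Wo; ++j) {
            const int sw = j * stride + kx - 1;
            if (sw < 0 || sw >= W) { r += Ho; continue; }
            double *dst = img + (size_t)sw * H;
            for (int i = 0; i < Ho; ++i, ++r) {
              const int sh = i * stride + ky - 1;
              if (sh >= 0 && sh < H) dst[sh] += col[r];
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, N, Cin);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
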