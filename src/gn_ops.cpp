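// Group normalization forward/backward on the (HW, N*C) pixel-major view
// (column (n, c) = n + N*c is one image-channel plane of HW pixels).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".gn_fwd_cpp")]]
List gn_fwd_cpp(NumericVector x, int HW, int N, int C, int groups,
                NumericVector gamma, NumericVector beta, double eps) {
  const int cpg = C / groups;
  NumericVector y(no_init(x.size())), xhat(no_init(x.size()));
  std::vector<double> sum((size_t)N * groups, 0.0),
      sum2((size_t)N * groups, 0.0);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    const int g = c / cpg;
    for (int n = 0; n < N; ++n) {
      const double *col = px + ((R_xlen_t)c * N + n) * HW;
      double s = 0, s2 = 0;
      for (int i = 0; i < HW; ++i) { const double v = col[i]; s += v; s2 += v * v; }
      sum[(size_t)g * N + n] += s;
      sum2[(size_t)g * N + n] += s2;
    }
  }
  const double m = (double)HW * cpg;
  NumericMatrix mu(N, groups), isd(N, groups);
  for (int g = 0; g < groups; ++g) {
    for (int n = 0; n < N; ++n) {
      const double mn = sum[(size_t)g * N + n] / m;
      double var = sum2[(size_t)g * N + n] / m - mn * mn;
      if (var < 0) var = 0;
      mu(n, g) = mn;
      isd(n, g) = 1.0 / std::sqrt(var + eps);
    }
  }
  double *py = y.begin(), *ph = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const int g = c / cpg;
    const double ga = gamma[c], be = beta[c];
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = ((R_xlen_t)c * N + n) * HW;
      const double mn = mu(n, g), is = isd(n, g);
      const double *col = px + off;
      double *yc = py + off, *hc = ph + off;
      for (int i = 0; i < HW; ++i) {
        const double h = (col[i] - mn) * is;
        hc[i] = h;
        yc[i] = ga * h + be;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv_sd"] = isd);
}

// [[Rcpp::export(name = ".gn_bwd_cpp")]]
List gn_bwd_cpp(NumericVector dy, NumericVector xhat, NumericMatrix isd,
                int HW, int N, int C, int groups, NumericVector gamma) {
  const int cpg = C / groups;
  NumericVector gx(no_init(dy.size()));
  NumericVector gg(C), gb(C);
  std::vector<double> md((size_t)N * groups, 0.0),
      mdx((size_t)N * groups, 0.0);
  const double *pdy = dy.begin(), *ph = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const int g = c / cpg;
    const double ga = gamma[c];
    double sgg = 0, sgb = 0;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = ((R_xlen_t)c * N + n) * HW;
      const double *dc = pdy + off, *hc = ph + off;
      double sd = 0, sdx = 0;
      for (int i = 0; i < HW; ++i) {
        const double d = dc[i];
        sgg += d * hc[i];
        sgb += d;
        const double dh = d * ga;
        sd += dh;
        sdx += dh * hc[i];
      }
      md[(size_t)g * N + n] += sd;
      mdx[(size_t)g * N + n] += sdx;
    }
    gg[c] = sgg;
    gb[c] = sgb;
  }
  const double m = (double)HW * cpg;
  double *pgx = gx.begin();
  for (int c = 0; c < C; ++c) {
    const int g = c / cpg;
    const double ga = gamma[c];
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = ((R_xlen_t)c * N + n) * HW;
      const double *dc = pdy + off, *hc = ph + off;
      double *gc = pgx + off;
      const double is = isd(n, g);
      const double mdv = md[(size_t)g * N + n] / m;
      const double mdxv = mdx[(size_t)g * N + n] / m;
      for (int i = 0; i < HW; ++i) {
        gc[i] = (dc[i] * ga - mdv - hc[i] * mdxv) * is;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}
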