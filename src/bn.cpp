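// Batch-normalisation kernels: fused column-wise scaling passes that avoid
// the large rep()/sweep() temporaries a pure-R implementation needs.

#include <Rcpp.h>
using namespace Rcpp;

// column means and biased column variances of an m x C matrix view
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x, R_xlen_t m, int C) {
  NumericVector mu(C), v(C);
  const double* p = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* col = p + m * c;
    double s = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    double mean = s / m;
    mu[c] = mean;
    double var = s2 / m - mean * mean;
    v[c] = var > 0 ? var : 0.0;
  }
  return List::create(_["mu"] = mu, _["v"] = v);
}

// y[, c] = x[, c] * a[c] + b[c]
// [[Rcpp::export]]
NumericVector cpp_scale_cols(NumericVector x, R_xlen_t m, int C,
                             NumericVector a, NumericVector b) {
  NumericVector y(no_init(x.size()));
  const double* p = x.begin();
  double* q = y.begin();
  for (int c = 0; c < C; ++c) {
    const double ac = a[c], bc = b[c];
    const double* s = p + m * c;
    double* d = q + m * c;
    for (R_xlen_t i = 0; i < m; ++i) d[i] = s[i] * ac + bc;
  }
  return y;
}

// backward pass given dy, cached xhat, gamma and inv = 1/sqrt(var + eps):
// dx = inv * gamma * (dy - dbeta/m - xhat * dgamma/m)
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dy, NumericVector xhat, NumericVector gamma,
                NumericVector inv, R_xlen_t m, int C) {
  NumericVector dgamma(C), dbeta(C);
  NumericVector dx(no_init(dy.size()));
  const double* pdy = dy.begin();
  const double* px = xhat.begin();
  double* pdx = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double* dcol = pdy + m * c;
    const double* xcol = px + m * c;
    double sg = 0.0, sb = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) {
      sg += dcol[i] * xcol[i];
      sb += dcol[i];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double a = inv[c] * gamma[c];
    const double mb = sb / m, mg = sg / m;
    double* dst = pdx + m * c;
    for (R_xlen_t i = 0; i < m; ++i) {
      dst[i] = a * (dcol[i] - mb - xcol[i] * mg);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
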