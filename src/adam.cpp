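// In-place optimizer arithmetic. Callers guarantee sole ownership of the
// arrays they pass (the training loop duplicates network parameters up
// front and snapshots them by copy), so no cloning happens here.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x += y
// [[Rcpp::export]]
void axpy_inplace_cpp(NumericVector x, NumericVector y) {
  const R_xlen_t n = x.size();
  if (y.size() != n) stop("length mismatch in gradient accumulation");
  double* xp = REAL(x);
  const double* yp = REAL(y);
  for (R_xlen_t i = 0; i < n; ++i) xp[i] += yp[i];
}

// bias-corrected Adam update of w, m, v in place
// [[Rcpp::export]]
void adam_update_inplace_cpp(NumericVector w, NumericVector m, NumericVector v,
                             NumericVector g, double lr, double beta1,
                             double beta2, double eps, double t) {
  const R_xlen_t n = w.size();
  if (m.size() != n || v.size() != n || g.size() != n) {
    stop("length mismatch in Adam update");
  }
  double* wp = REAL(w);
  double* mp = REAL(m);
  double* vp = REAL(v);
  const double* gp = REAL(g);
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1.0 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1.0 - beta2) * gp[i] * gp[i];
    wp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
  }
}
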