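#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fused in-place Adam update for one parameter tensor.  The caller owns the
// buffers (no other R references), so in-place mutation is safe and avoids
// ~10 full-tensor temporaries per step.
// [[Rcpp::export]]
void adam_update_cpp(NumericVector W, NumericVector g, NumericVector m,
                     NumericVector v, double lr, double b1, double b2,
                     double corr1, double corr2, double eps) {
  const R_xlen_t n = W.size();
  double *w = REAL(W), *gr = REAL(g), *mm = REAL(m), *vv = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    mm[i] = b1 * mm[i] + (1 - b1) * gr[i];
    vv[i] = b2 * vv[i] + (1 - b2) * gr[i] * gr[i];
    w[i] -= lr * (mm[i] / corr1) / (std::sqrt(vv[i] / corr2) + eps);
  }
}

// In-place bias addition + activation on a freshly computed pre-activation
// matrix Z (n x k, column-major).  act: 0 linear, 1 relu, 2 sigmoid.
// [[Rcpp::export]]
void bias_act_cpp(NumericMatrix Z, NumericVector b, int act) {
  const R_xlen_t n = Z.nrow(), k = Z.ncol();
  double *z = REAL(Z);
  for (R_xlen_t j = 0; j < k; ++j) {
    const double bj = b[j];
    double *col = z + j * n;
    for (R_xlen_t i = 0; i < n; ++i) {
      double val = col[i] + bj;
      if (act == 1) val = val > 0 ? val : 0;
      else if (act == 2) val = 1.0 / (1.0 + std::exp(-val));
      col[i] = val;
    }
  }
}
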