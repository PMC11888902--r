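#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update on flattened parameter/moment vectors.
// p, m, v are mutated; the caller owns them exclusively.
// [[Rcpp::export]]
void adam_update_inplace(NumericVector p, NumericVector m, NumericVector v,
                         NumericVector g, double lr, double beta1,
                         double beta2, double eps, int t) {
  const R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam_update_inplace: length mismatch");
  const double bc1 = 1.0 - std::pow(beta1, (double)t);
  const double bc2 = 1.0 - std::pow(beta2, (double)t);
  const double lr_t = lr * std::sqrt(bc2) / bc1;
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = beta1 * m[i] + (1.0 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    p[i] -= lr_t * m[i] / (std::sqrt(v[i]) + eps * std::sqrt(bc2));
  }
}
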