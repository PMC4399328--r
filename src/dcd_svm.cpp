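#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVM:
//   min_a 1/2 a^T Q a - e^T a,  0 <= a_i <= C,  Q_ij = y_i y_j K_ij,
// with K the (bias-augmented) Gram matrix of the training rows. The
// coordinate sweep is cyclic, so the solution is fully deterministic given
// (K, y). Suited to the small-n / large-p regime here (n ~ 70 rows), where
// one fit costs O(iterations * n^2) independent of the voxel count.
//
// [[Rcpp::export]]
NumericVector dcd_svm_alpha(const NumericMatrix& K, const IntegerVector& y,
                            double C, int max_iter, double tol) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("dcd_svm_alpha: K must be square and match length(y)");
  NumericVector alpha(n);
  std::vector<double> u(n, 0.0);  // u_j = sum_i alpha_i y_i K_ij
  for (int iter = 0; iter < max_iter; ++iter) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      const double G = y[i] * u[i] - 1.0;
      double pg = G;
      if (alpha[i] <= 0.0)
        pg = G < 0.0 ? G : 0.0;
      else if (alpha[i] >= C)
        pg = G > 0.0 ? G : 0.0;
      if (std::fabs(pg) > max_viol) max_viol = std::fabs(pg);
      if (std::fabs(pg) > 1e-14) {
        const double qii = K(i, i);
        if (qii <= 0.0) continue;
        const double a_old = alpha[i];
        double a_new = a_old - G / qii;
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        if (a_new != a_old) {
          alpha[i] = a_new;
          const double d = (a_new - a_old) * y[i];
          for (int j = 0; j < n; ++j) u[j] += d * K(i, j);
        }
      }
    }
    if (max_viol < tol) break;
  }
  return alpha;
}
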