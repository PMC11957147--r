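#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Log-domain scaling iterations for entropically regularized unbalanced
// linear optimal transport:
//   min_T <C, T> + rho1 KL(T1 | p1) + rho2 KL(T'1 | p2) + eps KL(T | p1 x p2)
// Dual potentials f, g are iterated with the softmin updates
//   f_i <- -(rho1/(rho1+eps)) * eps * LSE_j[ (g_j - C_ij)/eps + log p2_j ]
// (and symmetrically for g). The plan is T_ij = exp((f_i + g_j - C_ij)/eps)
// * p1_i * p2_j. All work happens in the log domain, so small eps does not
// overflow the scaling factors.
// [[Rcpp::export]]
List sinkhorn_unbalanced_cpp(NumericMatrix C,
                             NumericVector logp1, NumericVector logp2,
                             double eps, double rho1, double rho2,
                             NumericVector f0, NumericVector g0,
                             double tol, int max_iter) {
  const int n1 = C.nrow(), n2 = C.ncol();
  std::vector<double> f(f0.begin(), f0.end());
  std::vector<double> g(g0.begin(), g0.end());
  const double c1 = rho1 / (rho1 + eps);
  const double c2 = rho2 / (rho2 + eps);
  std::vector<double> tmp(std::max(n1, n2));
  double err = R_PosInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    err = 0.0;
    for (int i = 0; i < n1; ++i) {
      double mx = -INFINITY;
      for (int j = 0; j < n2; ++j) {
        double v = (g[j] - C(i, j)) / eps + logp2[j];
        tmp[j] = v;
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int j = 0; j < n2; ++j) s += std::exp(tmp[j] - mx);
      double fn = -c1 * eps * (mx + std::log(s));
      err = std::max(err, std::fabs(fn - f[i]));
      f[i] = fn;
    }
    for (int j = 0; j < n2; ++j) {
      double mx = -INFINITY;
      for (int i = 0; i < n1; ++i) {
        double v = (f[i] - C(i, j)) / eps + logp1[i];
        tmp[i] = v;
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int i = 0; i < n1; ++i) s += std::exp(tmp[i] - mx);
      double gn = -c2 * eps * (mx + std::log(s));
      err = std::max(err, std::fabs(gn - g[j]));
      g[j] = gn;
    }
    if (err / eps < tol) { ++it; break; }
  }
  NumericMatrix T(n1, n2);
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      T(i, j) = std::exp((f[i] + g[j] - C(i, j)) / eps + logp1[i] + logp2[j]);
    }
  }
  return List::create(_["T"] = T,
                      _["f"] = NumericVector(f.begin(), f.end()),
                      _["g"] = NumericVector(g.begin(), g.end()),
                      _["iterations"] = it,
                      _["err"] = err / eps);
}
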