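#include <Rcpp.h>
using namespace Rcpp;

// EM for a univariate two-component Gaussian mixture.
// z holds the initial responsibilities of component 2; components are
// returned unlabeled (relabeling happens in R). Variances are floored at
// floor_var to keep the likelihood bounded.
// [[Rcpp::export(name = ".em_gmm2_cpp")]]
List em_gmm2_cpp(NumericVector v, NumericVector z, double floor_var,
                 int max_iter, double tol) {
  const int n = v.size();
  const double log2pi = std::log(2.0 * M_PI);
  double ll_old = R_NegInf, ll = R_NegInf;
  double mu1 = 0, mu2 = 0, s21 = 1, s22 = 1, pi2 = 0.5;
  bool converged = false;
  NumericVector zz = clone(z);

  for (int it = 0; it < max_iter; ++it) {
    // M step
    double w2 = 0, sum1 = 0, sum2 = 0;
    for (int i = 0; i < n; ++i) { w2 += zz[i]; sum2 += zz[i] * v[i]; }
    double w1 = n - w2;
    if (w2 < 1e-10 || w1 < 1e-10) { // collapsed start: median split
      NumericVector sv = clone(v).sort();
      double med = (n % 2) ? sv[n / 2] : 0.5 * (sv[n / 2 - 1] + sv[n / 2]);
      w2 = 0; sum2 = 0;
      for (int i = 0; i < n; ++i) {
        zz[i] = v[i] > med ? 1.0 : 0.0;
        w2 += zz[i]; sum2 += zz[i] * v[i];
      }
      w1 = n - w2;
      if (w1 < 1e-10 || w2 < 1e-10) break;
    }
    for (int i = 0; i < n; ++i) sum1 += (1.0 - zz[i]) * v[i];
    mu1 = sum1 / w1; mu2 = sum2 / w2;
    double q1 = 0, q2 = 0;
    for (int i = 0; i < n; ++i) {
      q1 += (1.0 - zz[i]) * (v[i] - mu1) * (v[i] - mu1);
      q2 += zz[i] * (v[i] - mu2) * (v[i] - mu2);
    }
    s21 = std::max(q1 / w1, floor_var);
    s22 = std::max(q2 / w2, floor_var);
    pi2 = w2 / n;

    // E step, log space
    const double lp1 = std::log1p(-pi2) - 0.5 * (std::log(s21) + log2pi);
    const double lp2 = std::log(pi2) - 0.5 * (std::log(s22) + log2pi);
    ll = 0;
    for (int i = 0; i < n; ++i) {
      double l1 = lp1 - (v[i] - mu1) * (v[i] - mu1) / (2.0 * s21);
      double l2 = lp2 - (v[i] - mu2) * (v[i] - mu2) / (2.0 * s22);
      double m = l1 > l2 ? l1 : l2;
      double lse = m + std::log(std::exp(l1 - m) + std::exp(l2 - m));
      zz[i] = std::exp(l2 - lse);
      ll += lse;
    }
    if (R_finite(ll) && it > 0 && ll - ll_old < tol) {
      converged = true;
      ll_old = ll;
      break;
    }
    ll_old = ll;
  }
  return List::create(_["mu"] = NumericVector::create(mu1, mu2),
                      _["s2"] = NumericVector::create(s21, s22),
                      _["pi2"] = pi2, _["loglik"] = ll_old,
                      _["post"] = zz, _["converged"] = converged);
}
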