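#include <Rcpp.h>
using namespace Rcpp;

static inline double invlogit(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

//' Marginal log-likelihood of detection series under the auto-logistic model
//'
//' One row per site-by-species series; latent occupancy is marginalized by
//' the forward algorithm with per-step rescaling. Emission within a year is
//' the ordered Bernoulli product p^y (1-p)^(n-y) for an occupied site and the
//' indicator of zero detections for an empty one; years with zero visits are
//' uninformative.
//'
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_series_loglik(IntegerMatrix ydet, IntegerMatrix nvis,
                                IntegerVector group,
                                NumericVector alpha, NumericVector delta,
                                NumericVector psi1,
                                NumericMatrix lp, NumericMatrix eta) {
  const int S = ydet.nrow(), T = ydet.ncol();
  NumericVector out(S);
  for (int s = 0; s < S; ++s) {
    const int g = group[s] - 1;
    double ll = 0.0;
    // year 1
    double pr1 = invlogit(psi1[g]);
    double e1, e0;
    {
      const int n = nvis(s, 0), y = ydet(s, 0);
      if (n > 0) {
        const double p = invlogit(lp(g, 0));
        e1 = std::exp(y * std::log(p) + (n - y) * std::log1p(-p));
        e0 = (y == 0) ? 1.0 : 0.0;
      } else {
        e1 = 1.0; e0 = 1.0;
      }
    }
    double f1 = pr1 * e1, f0 = (1.0 - pr1) * e0;
    for (int t = 1; t < T; ++t) {
      const double c = f1 + f0;
      ll += std::log(c);
      f1 /= c; f0 /= c;
      const double p11 = invlogit(alpha[g] + delta[g] + eta(s, t));
      const double p01 = invlogit(alpha[g] + eta(s, t));
      const double g1 = f1 * p11 + f0 * p01;
      const double g0 = f1 * (1.0 - p11) + f0 * (1.0 - p01);
      const int n = nvis(s, t), y = ydet(s, t);
      if (n > 0) {
        const double p = invlogit(lp(g, t));
        e1 = std::exp(y * std::log(p) + (n - y) * std::log1p(-p));
        e0 = (y == 0) ? 1.0 : 0.0;
      } else {
        e1 = 1.0; e0 = 1.0;
      }
      f1 = g1 * e1; f0 = g0 * e0;
    }
    out[s] = ll + std::log(f1 + f0);
  }
  return out;
}
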