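#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Node-wise spike-and-slab Gibbs sampler for Bayesian graphical regression.
//
// Per node i (response y = column i of the standardized slice Z):
//   y = sum_{k != i} gamma_ik beta_ik z_k + eps,   eps ~ N(0, sigma2 I)
//   gamma_ik ~ Bernoulli(piIncl)
//   beta_ik | gamma_ik = 1 ~ N(0, tau2 * sigma2)
//   sigma2 ~ Inverse-Gamma(a0, b0)
//
// All sufficient statistics live in the Gram matrix Z'Z, so one coordinate
// update is O(p) regardless of n.  Uses R's RNG: results are reproducible
// under set.seed() on the calling side.

// [[Rcpp::export(name = ".gibbs_network_fit")]]
List gibbs_network_fit(NumericMatrix Z, int iterations, int burnin,
                       double piIncl, double tau2, double a0, double b0) {
  const int n = Z.nrow(), p = Z.ncol();
  if (iterations <= burnin)
    stop("iterations must exceed burnin");

  // Gram matrix
  NumericMatrix G(p, p);
  for (int a = 0; a < p; ++a)
    for (int b = a; b < p; ++b) {
      double s = 0.0;
      for (int r = 0; r < n; ++r) s += Z(r, a) * Z(r, b);
      G(a, b) = s;
      G(b, a) = s;
    }

  NumericMatrix ppi(p, p), coefMean(p, p), coefCond(p, p);
  NumericVector sigma2Mean(p);
  const int kept = iterations - burnin;
  const double logPrior = std::log(piIncl) - std::log1p(-piIncl);

  std::vector<double> beta(p), s_incl(p);
  std::vector<int> gamma(p), pred(p), inclCount(p);
  std::vector<double> betaSum(p), betaCondSum(p);

  for (int i = 0; i < p; ++i) {
    int m = 0;
    for (int k = 0; k < p; ++k) if (k != i) pred[m++] = k;
    const double yy = G(i, i);

    double sigma2 = 1.0, sigma2Acc = 0.0;
    for (int k = 0; k < m; ++k) {
      beta[k] = 0.0; gamma[k] = 0; inclCount[k] = 0;
      betaSum[k] = 0.0; betaCondSum[k] = 0.0;
    }

    for (int it = 0; it < iterations; ++it) {
      for (int k = 0; k < m; ++k) {
        const int kk = pred[k];
        const double v = G(kk, kk);
        double s = G(kk, i);
        for (int j = 0; j < m; ++j)
          if (j != k && gamma[j]) s -= G(kk, pred[j]) * beta[j];
        const double denom = 1.0 + tau2 * v;
        const double logOdds = logPrior - 0.5 * std::log(denom)
          + tau2 * s * s / (2.0 * sigma2 * denom);
        double p1;
        if (logOdds > 35.0) p1 = 1.0;
        else if (logOdds < -35.0) p1 = 0.0;
        else p1 = 1.0 / (1.0 + std::exp(-logOdds));
        if (unif_rand() < p1) {
          gamma[k] = 1;
          const double postPrec = v + 1.0 / tau2;
          beta[k] = s / postPrec + std::sqrt(sigma2 / postPrec) * norm_rand();
        } else {
          gamma[k] = 0;
          beta[k] = 0.0;
        }
      }
      // sigma2 | rest
      double rss = yy, quad = 0.0;
      int mact = 0;
      for (int k = 0; k < m; ++k) if (gamma[k]) {
        rss -= 2.0 * beta[k] * G(pred[k], i);
        quad += beta[k] * beta[k];
        ++mact;
      }
      for (int k = 0; k < m; ++k) if (gamma[k])
        for (int j = 0; j < m; ++j) if (gamma[j])
          rss += beta[k] * beta[j] * G(pred[k], pred[j]);
      if (rss < 1e-12) rss = 1e-12;
      const double shape = a0 + 0.5 * (n + mact);
      const double rate = b0 + 0.5 * (rss + quad / tau2);
      sigma2 = rate / R::rgamma(shape, 1.0);

      if (it >= burnin) {
        for (int k = 0; k < m; ++k) {
          inclCount[k] += gamma[k];
          betaSum[k] += beta[k];
          if (gamma[k]) betaCondSum[k] += beta[k];
        }
        sigma2Acc += sigma2;
      }
    }

    for (int k = 0; k < m; ++k) {
      const int kk = pred[k];
      ppi(i, kk) = (double) inclCount[k] / kept;
      coefMean(i, kk) = betaSum[k] / kept;
      coefCond(i, kk) = inclCount[k] > 0 ? betaCondSum[k] / inclCount[k] : 0.0;
    }
    sigma2Mean[i] = sigma2Acc / kept;
  }

  return List::create(_["ppi"] = ppi,
                      _["coef"] = coefMean,
                      _["coefCond"] = coefCond,
                      _["sigma2"] = sigma2Mean);
}
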