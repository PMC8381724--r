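#include <Rcpp.h>
using namespace Rcpp;

// Inverse-Gaussian sampler (Michael, Schucany & Haas transformation).
static double rinvgauss1(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) * sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-10;
  double z = R::unif_rand();
  if (z <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static double rscinvchisq(double df, double scale) {
  // scaled-inverse-chi-square: df*scale / chisq(df)
  return df * scale / R::rchisq(df);
}

// Gibbs samplers for whole-genome marker-effect regressions.
//
// model: 0 = BayesA (scaled-t via per-marker variances),
//        1 = BayesC-pi (spike-and-slab, common slab variance, pi ~ U(0,1)),
//        2 = Bayesian LASSO (Park & Casella hierarchy).
//
// y must be complete; X column-centred. Uses R's RNG, so set.seed() in R
// gives bit-identical chains.
// [[Rcpp::export]]
List bayes_marker_gibbs(NumericVector y, NumericMatrix X, int model,
                        int niter, int burnin, int thin,
                        double df0, double S0b, double dfe0, double S0e,
                        double lambda2, double lshape0, double lrate0) {
  const int n = y.size(), m = X.ncol();
  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }

  double mu = mean(y);
  std::vector<double> b(m, 0.0), sb(m, S0b), tau2(m, 1.0);
  std::vector<int> del(m, 1);
  double s2e = S0e > 0 ? S0e : 1.0;
  double s2b = S0b;        // common slab variance (BayesC-pi)
  double pi0 = 0.5;        // proportion of ZERO-effect markers
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  // accumulators
  std::vector<double> bSum(m, 0.0), inclSum(m, 0.0);
  double muSum = 0, s2eSum = 0, s2bSum = 0, piSum = 0, lamSum = 0;
  int nSaved = 0;
  int nStore = (niter - burnin + thin - 1) / thin;
  NumericMatrix varChain(std::max(nStore, 1), 2); // s2b-like, s2e

  for (int it = 0; it < niter; ++it) {
    // intercept
    double rbar = 0.0;
    for (int i = 0; i < n; ++i) rbar += r[i] + mu;
    rbar /= n;
    double muNew = R::rnorm(rbar, sqrt(s2e / n));
    for (int i = 0; i < n; ++i) r[i] += mu - muNew;
    mu = muNew;

    int nIncl = 0;
    double sumB2incl = 0.0, sumB2tau = 0.0, sumTau2 = 0.0;
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0.0) { b[j] = 0.0; continue; }
      double bOld = b[j];
      // z = x_j' r  with marker j removed from the residual
      double z = 0.0;
      for (int i = 0; i < n; ++i) z += X(i, j) * r[i];
      z += xtx[j] * bOld;

      if (model == 0) {            // BayesA
        double C = xtx[j] + s2e / sb[j];
        double bNew = R::rnorm(z / C, sqrt(s2e / C));
        for (int i = 0; i < n; ++i) r[i] += X(i, j) * (bOld - bNew);
        b[j] = bNew;
        sb[j] = rscinvchisq(df0 + 1.0, (df0 * S0b + bNew * bNew) / (df0 + 1.0));
      } else if (model == 1) {     // BayesC-pi
        double v0 = s2e * xtx[j];
        double v1 = s2e * xtx[j] + s2b * xtx[j] * xtx[j];
        double logBF = 0.5 * (log(v0) - log(v1)) +
          0.5 * z * z * (1.0 / v0 - 1.0 / v1);
        double logit = log((1.0 - pi0) / pi0) + logBF;
        double p1 = 1.0 / (1.0 + exp(-logit));
        double bNew = 0.0;
        if (R::unif_rand() < p1) {
          double C = xtx[j] + s2e / s2b;
          bNew = R::rnorm(z / C, sqrt(s2e / C));
          ++nIncl;
          sumB2incl += bNew * bNew;
          del[j] = 1;
        } else del[j] = 0;
        for (int i = 0; i < n; ++i) r[i] += X(i, j) * (bOld - bNew);
        b[j] = bNew;
      } else {                     // Bayesian LASSO
        double C = xtx[j] + 1.0 / tau2[j];
        double bNew = R::rnorm(z / C, sqrt(s2e / C));
        for (int i = 0; i < n; ++i) r[i] += X(i, j) * (bOld - bNew);
        b[j] = bNew;
        double b2 = bNew * bNew;
        if (b2 < 1e-12) b2 = 1e-12;
        double itau2 = rinvgauss1(sqrt(lambda2 * s2e / b2), lambda2);
        tau2[j] = 1.0 / itau2;
        sumB2tau += b2 * itau2;
        sumTau2 += tau2[j];
      }
    }

    if (model == 1) {
      // slab variance and pi (pi is the zero-effect proportion)
      double dfb = df0 + nIncl;
      s2b = rscinvchisq(dfb, (df0 * S0b + sumB2incl) / dfb);
      pi0 = R::rbeta(m - nIncl + 1.0, nIncl + 1.0);
      if (pi0 < 1e-6) pi0 = 1e-6;
      if (pi0 > 1.0 - 1e-6) pi0 = 1.0 - 1e-6;
    }
    if (model == 2)
      lambda2 = R::rgamma(lshape0 + m, 1.0 / (lrate0 + sumTau2 / 2.0));

    // residual variance
    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    if (model == 2) {
      double dfe = dfe0 + n + m;
      s2e = rscinvchisq(dfe, (dfe0 * S0e + rss + sumB2tau) / dfe);
    } else {
      double dfe = dfe0 + n;
      s2e = rscinvchisq(dfe, (dfe0 * S0e + rss) / dfe);
    }

    if (it >= burnin && (it - burnin) % thin == 0) {
      for (int j = 0; j < m; ++j) {
        bSum[j] += b[j];
        if (model == 1) inclSum[j] += del[j];
      }
      muSum += mu; s2eSum += s2e; piSum += pi0;
      lamSum += sqrt(lambda2);
      double vb = 0.0;
      if (model == 0) { for (int j = 0; j < m; ++j) vb += sb[j]; vb /= m; }
      else if (model == 1) vb = s2b;
      else vb = lambda2;
      varChain(nSaved, 0) = vb;
      varChain(nSaved, 1) = s2e;
      ++nSaved;
    }
  }

  NumericVector bMean(m), inclMean(m);
  for (int j = 0; j < m; ++j) {
    bMean[j] = bSum[j] / nSaved;
    inclMean[j] = inclSum[j] / nSaved;
  }
  return List::create(
    _["b"] = bMean, _["mu"] = muSum / nSaved,
    _["sigma2e"] = s2eSum / nSaved, _["pi"] = piSum / nSaved,
    _["lambda"] = lamSum / nSaved, _["inclusion"] = inclMean,
    _["varChain"] = varChain, _["nSaved"] = nSaved);
}
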