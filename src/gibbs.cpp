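// Single-site Gibbs sampler for whole-genome regression.
//
// Model: y = W b + Z alpha + e,  e ~ N(0, I sigma2e), flat prior on b.
// Marker-effect priors (the "Bayesian alphabet"):
//   BayesRR : alpha_j ~ N(0, s2a),          s2a common, scaled-inv-chi2 prior
//   BayesA  : alpha_j ~ N(0, s2a_j),        per-marker scaled-inv-chi2
//   BayesB  : spike at 0 w.p. pi, slab N(0, s2a_j) per-marker variance
//   BayesC  : spike at 0 w.p. pi, slab N(0, s2a)   common variance
//   BayesL  : alpha_j ~ N(0, tau2_j*sigma2e), tau2_j ~ Exp(lambda2/2)
//             (double-exponential marginal), lambda2 ~ Gamma(shape, rate)
//
// Residual updates keep e = y - W b - Z alpha current so each marker
// update costs O(n). All randomness goes through R's RNG so chains are
// reproducible with set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

enum ModelCode { RR = 0, A = 1, B = 2, C = 3, L = 4 };

static double rinvgauss(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  double u = unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// scaled-inverse-chi-square draw: (df * scale) / chisq(df)
static double rscinvchisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".gibbsWgr")]]
List gibbsWgr(const arma::vec& y, const arma::mat& Z, const arma::mat& W,
              int modelCode, int niter, int burnin, int thin, double pi0,
              double dfResid, double scaleResid, double dfMarker,
              double scaleMarker, double lambda2Shape, double lambda2Rate,
              bool samplePi) {
  const int n = y.n_elem, m = Z.n_cols, q = W.n_cols;
  const ModelCode model = static_cast<ModelCode>(modelCode);

  arma::vec zz(m), ww(q);
  for (int j = 0; j < m; ++j) zz[j] = arma::dot(Z.col(j), Z.col(j));
  for (int k = 0; k < q; ++k) ww[k] = arma::dot(W.col(k), W.col(k));

  arma::vec b(q, arma::fill::zeros);
  b[0] = arma::mean(y);  // first column is the intercept
  arma::vec alpha(m, arma::fill::zeros);
  arma::vec delta(m, arma::fill::ones);  // inclusion indicators (B/C)
  arma::vec s2aj(m);
  double s2a = scaleMarker;  // common slab variance (RR/C)
  s2aj.fill(scaleMarker);
  arma::vec tau2(m, arma::fill::ones);  // BayesL local scales
  double lambda2 =
      (lambda2Shape > 1.0) ? (lambda2Shape - 1.0) / lambda2Rate
                           : lambda2Shape / lambda2Rate;
  double sigma2e = scaleResid;
  double pi = pi0;

  arma::vec e = y - W * b;

  const int nsave = (niter - burnin) / thin;
  arma::vec alphaMean(m, arma::fill::zeros), deltaMean(m, arma::fill::zeros);
  arma::vec bMean(q, arma::fill::zeros), gMean(n, arma::fill::zeros);
  arma::vec varGDraws(nsave), veDraws(nsave), piDraws(nsave);
  int isave = 0;

  for (int it = 1; it <= niter; ++it) {
    // fixed effects, flat prior
    for (int k = 0; k < q; ++k) {
      double rhs = arma::dot(W.col(k), e) + ww[k] * b[k];
      double bnew = rhs / ww[k] + std::sqrt(sigma2e / ww[k]) * norm_rand();
      e += W.col(k) * (b[k] - bnew);
      b[k] = bnew;
    }

    int mIncl = 0;
    double sumIncl2 = 0.0;  // sum alpha^2 over included markers (C)
    for (int j = 0; j < m; ++j) {
      const double* zj = Z.colptr(j);
      double rhs = alpha[j] * zz[j];
      for (int i = 0; i < n; ++i) rhs += zj[i] * e[i];
      double aold = alpha[j], anew = 0.0;

      switch (model) {
        case RR: {
          double cjj = zz[j] + sigma2e / s2a;
          anew = rhs / cjj + std::sqrt(sigma2e / cjj) * norm_rand();
          break;
        }
        case A: {
          double cjj = zz[j] + sigma2e / s2aj[j];
          anew = rhs / cjj + std::sqrt(sigma2e / cjj) * norm_rand();
          s2aj[j] = rscinvchisq(dfMarker + 1.0,
                                (anew * anew + dfMarker * scaleMarker) /
                                    (dfMarker + 1.0));
          break;
        }
        case B:
        case C: {
          double slab = (model == B) ? s2aj[j] : s2a;
          double v0 = zz[j] * sigma2e;
          double v1 = zz[j] * zz[j] * slab + v0;
          // log posterior odds of inclusion given rhs ~ N(0, v) mixtures
          double logOdds = std::log((1.0 - pi) / pi) +
                           0.5 * (std::log(v0) - std::log(v1)) +
                           0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
          double pIncl = 1.0 / (1.0 + std::exp(-logOdds));
          if (unif_rand() < pIncl) {
            delta[j] = 1.0;
            double cjj = zz[j] + sigma2e / slab;
            anew = rhs / cjj + std::sqrt(sigma2e / cjj) * norm_rand();
            ++mIncl;
            sumIncl2 += anew * anew;
          } else {
            delta[j] = 0.0;
            anew = 0.0;
          }
          if (model == B) {
            double a2 = anew * anew;
            s2aj[j] = (delta[j] > 0.5)
                          ? rscinvchisq(dfMarker + 1.0,
                                        (a2 + dfMarker * scaleMarker) /
                                            (dfMarker + 1.0))
                          : rscinvchisq(dfMarker, scaleMarker);
          }
          break;
        }
        case L: {
          double cjj = zz[j] + 1.0 / tau2[j];
          anew = rhs / cjj + std::sqrt(sigma2e / cjj) * norm_rand();
          double a2 = anew * anew;
          if (a2 < 1e-12) a2 = 1e-12;
          double invTau =
              rinvgauss(std::sqrt(lambda2 * sigma2e / a2), lambda2);
          tau2[j] = 1.0 / invTau;
          break;
        }
      }

      if (anew != aold) {
        double diff = aold - anew;
        for (int i = 0; i < n; ++i) e[i] += zj[i] * diff;
        alpha[j] = anew;
      }
    }

    // marker-variance / shrinkage hyperparameters
    if (model == RR) {
      double ss = arma::dot(alpha, alpha);
      s2a = rscinvchisq(dfMarker + m,
                        (ss + dfMarker * scaleMarker) / (dfMarker + m));
    } else if (model == C) {
      s2a = rscinvchisq(dfMarker + mIncl,
                        (sumIncl2 + dfMarker * scaleMarker) /
                            (dfMarker + mIncl));
    } else if (model == L) {
      lambda2 = R::rgamma(lambda2Shape + m,
                          1.0 / (lambda2Rate + 0.5 * arma::accu(tau2)));
    }
    if ((model == B || model == C) && samplePi) {
      // pi ~ Beta(m - mIncl + 1, mIncl + 1) (uniform prior)
      double a1 = R::rgamma(m - mIncl + 1.0, 1.0);
      double a2 = R::rgamma(mIncl + 1.0, 1.0);
      pi = a1 / (a1 + a2);
      if (pi >= 1.0 - 1e-10) pi = 1.0 - 1e-10;
      if (pi <= 1e-10) pi = 1e-10;
    }

    // residual variance (BayesL scales marker effects by sigma2e jointly)
    double sse = arma::dot(e, e);
    if (model == L) {
      double sa = 0.0;
      for (int j = 0; j < m; ++j) sa += alpha[j] * alpha[j] / tau2[j];
      sigma2e = (sse + sa + dfResid * scaleResid) /
                R::rchisq(n + m + dfResid);
    } else {
      sigma2e = (sse + dfResid * scaleResid) / R::rchisq(n + dfResid);
    }

    if (it > burnin && ((it - burnin) % thin == 0) && isave < nsave) {
      arma::vec g = y - W * b - e;  // = Z alpha
      alphaMean += alpha;
      deltaMean += delta;
      bMean += b;
      gMean += g;
      varGDraws[isave] = arma::var(g);
      veDraws[isave] = sigma2e;
      piDraws[isave] = pi;
      ++isave;
    }
  }

  alphaMean /= nsave;
  deltaMean /= nsave;
  bMean /= nsave;
  gMean /= nsave;

  return List::create(
      Named("alpha") = alphaMean, Named("delta") = deltaMean,
      Named("b") = bMean, Named("g") = gMean,
      Named("varGDraws") = varGDraws, Named("veDraws") = veDraws,
      Named("piDraws") = piDraws, Named("nSaved") = isave);
}
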