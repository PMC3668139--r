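#include <Rcpp.h>
using namespace Rcpp;

// Per-SNP logistic IRLS for the intercept + additive-dosage model.
// g: n x m dosage matrix (NA allowed; individuals with a missing dosage
// are dropped for that SNP only), y: binary response.
// Returns the two-sided Wald p-value of the dosage coefficient per SNP
// and a status flag: 0 ok, 1 monomorphic/degenerate, 2 separation,
// 3 non-convergence.
// [[Rcpp::export(name = ".scan_logistic_cpp")]]
List scan_logistic_cpp(NumericMatrix g, NumericVector y,
                       int maxit = 50, double tol = 1e-8) {
  const int n = g.nrow(), m = g.ncol();
  NumericVector p(m, NA_REAL), beta(m, NA_REAL), se(m, NA_REAL);
  IntegerVector flag(m, 0);

  for (int j = 0; j < m; ++j) {
    // complete-data subsample for this SNP
    double gmin = R_PosInf, gmax = R_NegInf, ybar = 0.0;
    int nn = 0;
    for (int i = 0; i < n; ++i) {
      double gij = g(i, j);
      if (NumericVector::is_na(gij)) continue;
      if (gij < gmin) gmin = gij;
      if (gij > gmax) gmax = gij;
      ybar += y[i];
      ++nn;
    }
    if (nn < 2 || gmin == gmax) { flag[j] = 1; continue; }
    ybar /= nn;
    if (ybar <= 0.0 || ybar >= 1.0) { flag[j] = 1; continue; }

    double b0 = std::log(ybar / (1.0 - ybar)), b1 = 0.0;
    double S0 = 0, S1 = 0, S2 = 0, det = 0;
    bool converged = false, degenerate = false;
    for (int it = 0; it < maxit; ++it) {
      S0 = S1 = S2 = 0;
      double T0 = 0, T1 = 0;
      for (int i = 0; i < n; ++i) {
        double gij = g(i, j);
        if (NumericVector::is_na(gij)) continue;
        double eta = b0 + b1 * gij;
        double mu = 1.0 / (1.0 + std::exp(-eta));
        double w = mu * (1.0 - mu);
        double wz = w * eta + (y[i] - mu);
        S0 += w; S1 += w * gij; S2 += w * gij * gij;
        T0 += wz; T1 += wz * gij;
      }
      det = S0 * S2 - S1 * S1;
      if (!(det > 1e-12 * (S0 * S2 + 1e-300))) { degenerate = true; break; }
      double nb1 = (S0 * T1 - S1 * T0) / det;
      double nb0 = (S2 * T0 - S1 * T1) / det;
      double delta = std::max(std::fabs(nb1 - b1), std::fabs(nb0 - b0));
      b0 = nb0; b1 = nb1;
      if (delta < tol) { converged = true; break; }
    }
    // in-loop degeneracy on a polymorphic SNP means the weights collapsed
    // (fitted probabilities at 0/1): separation, not monomorphism
    if (degenerate) { flag[j] = 2; continue; }
    if (std::fabs(b1) > 15.0) { flag[j] = 2; continue; }
    if (!converged) { flag[j] = 3; continue; }
    double sej = std::sqrt(S0 / det);
    double z = std::fabs(b1) / sej;
    beta[j] = b1; se[j] = sej;
    p[j] = 2.0 * R::pnorm(z, 0.0, 1.0, 0, 0);
    if (p[j] <= 0.0) p[j] = 5e-324;
    if (p[j] > 1.0) p[j] = 1.0;
  }
  return List::create(_["p"] = p, _["beta"] = beta, _["se"] = se,
                      _["flag"] = flag);
}
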