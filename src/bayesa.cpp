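#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for Bayes A marker regression:
//   y = X b + W beta + e,  b flat,
//   beta_j ~ N(0, s2_j),  s2_j ~ scaled-inv-chi2(df, S),
//   e ~ N(0, se2 I),      se2 ~ scaled-inv-chi2(df_e, S_e).
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List bayes_a_gibbs(const NumericVector& y, const NumericMatrix& X,
                   const NumericMatrix& W, int n_iter, int burn_in,
                   double df_hyper, double scale_hyper,
                   double df_e, double scale_e, int thin) {
  const int n = y.size(), p = W.ncol(), q = X.ncol();
  std::vector<double> b(q, 0.0), beta(p, 0.0), s2(p, scale_hyper);
  double se2 = scale_e > 0 ? scale_e : 1.0;
  std::vector<double> e(y.begin(), y.end());

  std::vector<double> xx(q), ww(p);
  for (int j = 0; j < q; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xx[j] = s;
  }
  for (int j = 0; j < p; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    ww[j] = s;
  }

  std::vector<double> b_sum(q, 0.0), beta_sum(p, 0.0);
  int n_kept = 0;
  int n_thin = (n_iter - burn_in) / thin;
  NumericMatrix chain(std::max(n_thin, 0), 2);  // se2, mean marker variance

  for (int it = 0; it < n_iter; ++it) {
    // fixed effects, flat prior
    for (int j = 0; j < q; ++j) {
      if (xx[j] <= 0) continue;
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xx[j] * b[j];
      double bn = rhs / xx[j] + R::rnorm(0.0, std::sqrt(se2 / xx[j]));
      double d = b[j] - bn;
      for (int i = 0; i < n; ++i) e[i] += d * X(i, j);
      b[j] = bn;
    }
    // marker effects and their variances
    double s2_mean = 0;
    for (int j = 0; j < p; ++j) {
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += W(i, j) * e[i];
      rhs += ww[j] * beta[j];
      double C = ww[j] + se2 / std::max(s2[j], 1e-300);
      double mean = rhs / C;
      double bn = mean + R::rnorm(0.0, std::sqrt(se2 / C));
      if (!R_finite(bn))
        stop("divergent chain at iteration %d (marker %d)", it + 1, j + 1);
      double d = beta[j] - bn;
      if (d != 0) for (int i = 0; i < n; ++i) e[i] += d * W(i, j);
      beta[j] = bn;
      s2[j] = (df_hyper * scale_hyper + bn * bn) / R::rchisq(df_hyper + 1.0);
      s2_mean += s2[j];
    }
    s2_mean /= p;
    // residual variance
    double sse = 0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    se2 = (sse + df_e * scale_e) / R::rchisq((double)n + df_e);
    if (!R_finite(se2) || se2 <= 0)
      stop("divergent chain at iteration %d (residual variance)", it + 1);

    if (it >= burn_in) {
      for (int j = 0; j < q; ++j) b_sum[j] += b[j];
      for (int j = 0; j < p; ++j) beta_sum[j] += beta[j];
      ++n_kept;
      int k = it - burn_in;
      if (thin > 0 && k % thin == 0 && k / thin < chain.nrow()) {
        chain(k / thin, 0) = se2;
        chain(k / thin, 1) = s2_mean;
      }
    }
  }
  NumericVector bm(q), betam(p);
  for (int j = 0; j < q; ++j) bm[j] = b_sum[j] / n_kept;
  for (int j = 0; j < p; ++j) betam[j] = beta_sum[j] / n_kept;
  colnames(chain) = CharacterVector::create("se2", "mean_marker_var");
  return List::create(_["b"] = bm, _["beta"] = betam, _["chain"] = chain,
                      _["n_kept"] = n_kept);
}
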