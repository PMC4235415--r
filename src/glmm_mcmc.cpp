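#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli-logit mixed model sampler.
//
// Fixed effects and independent random effects u are updated by Gaussian
// random-walk Metropolis against the Bernoulli-logit likelihood plus their
// normal priors; the genetic precision tau.g has a conjugate Gamma update
// given u. u components are visited family block by family block; within a
// block updates are componentwise, and changing u[t] in family f perturbs
// the linear predictor only on the rows of that family (eta_j += G(j,t)*d).
// Proposal scales adapt toward a 20-50% acceptance rate during burn-in and
// are frozen afterwards. Uses R's RNG, so seeding via set.seed() in R makes
// chains bit-reproducible.

static inline double stable_log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return std::log1p(std::exp(x));
}

// beta is proposed jointly: beta' = beta + s_b * Lprop z with z ~ N(0, I)
// and Lprop the (lower) Cholesky factor of a proposal covariance taken from
// the logistic MLE information matrix. Correlated designs (e.g. intercept +
// age) make componentwise beta walks mix far too slowly; a joint correlated
// proposal restores O(1) mixing while remaining plain random-walk Metropolis.
// [[Rcpp::export(name = ".glmm_chain")]]
List glmm_chain(IntegerVector y, NumericMatrix X, NumericMatrix G,
                IntegerVector offsets, NumericVector beta0,
                NumericMatrix Lprop, double tau_g0, double prior_beta_mean,
                double prior_beta_prec, double tau_shape, double tau_rate,
                int n_iter, int burn_in, int thin,
                double scale_beta0, double scale_u0) {
  const int n = y.size();
  const int p = X.ncol();
  const int nfam = offsets.size() - 1;
  const int N = n;

  NumericVector beta = clone(beta0);
  NumericVector u(N, 0.0);
  double tau_g = tau_g0;

  // family index of each row/column
  IntegerVector fam_of(n);
  for (int f = 0; f < nfam; ++f)
    for (int j = offsets[f] - 1; j < offsets[f + 1] - 1; ++j) fam_of[j] = f;

  // eta = xb + gu is maintained in two parts so the u scale move can
  // rescale the polygenic contribution alone.
  NumericVector xb(n), gu(n, 0.0), eta(n);
  for (int j = 0; j < n; ++j) {
    double e = 0.0;
    for (int k = 0; k < p; ++k) e += X(j, k) * beta[k];
    xb[j] = e;
    eta[j] = e;
  }

  double s_beta = scale_beta0, s_scale = 0.3;
  NumericVector s_u(N, scale_u0);
  int acc_beta = 0, try_beta = 0, acc_scale = 0, try_scale = 0;
  IntegerVector acc_u(N, 0), try_u(N, 0);
  const int adapt_every = 50;
  NumericVector z(p), db(p), deta(n);

  const int n_kept = (n_iter - burn_in + thin - 1) / thin;
  NumericMatrix draws(n_kept, p + 2);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // fixed effects: joint correlated RW Metropolis
    {
      for (int k = 0; k < p; ++k) z[k] = R::norm_rand();
      for (int k = 0; k < p; ++k) {
        double v = 0.0;
        for (int l = 0; l <= k; ++l) v += Lprop(k, l) * z[l];
        db[k] = s_beta * v;
      }
      double dll = 0.0;
      for (int j = 0; j < n; ++j) {
        double de = 0.0;
        for (int k = 0; k < p; ++k) de += X(j, k) * db[k];
        deta[j] = de;
        double e0 = eta[j], e1 = e0 + de;
        dll += y[j] * de - stable_log1pexp(e1) + stable_log1pexp(e0);
      }
      for (int k = 0; k < p; ++k) {
        double b0 = beta[k] - prior_beta_mean, b1 = b0 + db[k];
        dll += -0.5 * prior_beta_prec * (b1 * b1 - b0 * b0);
      }
      ++try_beta;
      if (std::log(R::unif_rand()) < dll) {
        for (int k = 0; k < p; ++k) beta[k] += db[k];
        for (int j = 0; j < n; ++j) { xb[j] += deta[j]; eta[j] += deta[j]; }
        ++acc_beta;
      }
    }
    // random effects: componentwise within each family block
    for (int t = 0; t < N; ++t) {
      int f = fam_of[t];
      int lo = offsets[f] - 1, hi = offsets[f + 1] - 1;
      double d = s_u[t] * R::norm_rand();
      double dll = 0.0;
      for (int j = lo; j < hi; ++j) {
        double g = G(j, t);
        if (g == 0.0) continue;
        double e0 = eta[j], e1 = e0 + g * d;
        dll += y[j] * (e1 - e0) - stable_log1pexp(e1) + stable_log1pexp(e0);
      }
      double u1 = u[t] + d;
      dll += -0.5 * tau_g * (u1 * u1 - u[t] * u[t]);
      ++try_u[t];
      if (std::log(R::unif_rand()) < dll) {
        for (int j = lo; j < hi; ++j) {
          gu[j] += G(j, t) * d;
          eta[j] = xb[j] + gu[j];
        }
        u[t] = u1;
        ++acc_u[t];
      }
    }
    // joint scale move u' = c u, c = exp(delta): targets the slow
    // "funnel" direction coupling the magnitude of u with tau.g.
    {
      double ss0 = 0.0;
      for (int t = 0; t < N; ++t) ss0 += u[t] * u[t];
      double lc = s_scale * R::norm_rand();
      double c = std::exp(lc);
      double dll = N * lc - 0.5 * tau_g * (c * c - 1.0) * ss0;
      for (int j = 0; j < n; ++j) {
        double e1 = xb[j] + c * gu[j];
        dll += y[j] * (e1 - eta[j]) - stable_log1pexp(e1)
             + stable_log1pexp(eta[j]);
      }
      ++try_scale;
      if (std::log(R::unif_rand()) < dll) {
        for (int t = 0; t < N; ++t) u[t] *= c;
        for (int j = 0; j < n; ++j) { gu[j] *= c; eta[j] = xb[j] + gu[j]; }
        ++acc_scale;
      }
    }
    // tau.g | u : conjugate Gamma
    double ss = 0.0;
    for (int t = 0; t < N; ++t) ss += u[t] * u[t];
    tau_g = R::rgamma(tau_shape + 0.5 * N, 1.0 / (tau_rate + 0.5 * ss));

    // adapt proposal scales during burn-in only
    if (it <= burn_in && it % adapt_every == 0) {
      {
        double r = try_beta ? (double)acc_beta / try_beta : 0.0;
        if (r < 0.20) s_beta *= 0.7; else if (r > 0.50) s_beta *= 1.4;
        acc_beta = try_beta = 0;
        double rs = try_scale ? (double)acc_scale / try_scale : 0.0;
        if (rs < 0.20) s_scale *= 0.7; else if (rs > 0.50) s_scale *= 1.4;
        acc_scale = try_scale = 0;
      }
      for (int t = 0; t < N; ++t) {
        double r = try_u[t] ? (double)acc_u[t] / try_u[t] : 0.0;
        if (r < 0.20) s_u[t] *= 0.7; else if (r > 0.50) s_u[t] *= 1.4;
        acc_u[t] = try_u[t] = 0;
      }
    }

    if (it > burn_in && (it - burn_in - 1) % thin == 0) {
      for (int k = 0; k < p; ++k) draws(kept, k) = beta[k];
      draws(kept, p) = tau_g;
      draws(kept, p + 1) = 1.0 / tau_g;
      ++kept;
    }
  }

  double acc_b = try_beta ? (double)acc_beta / try_beta : 0.0;
  double acc_uu = 0.0;
  for (int t = 0; t < N; ++t)
    acc_uu += try_u[t] ? (double)acc_u[t] / try_u[t] : 0.0;

  return List::create(_["draws"] = draws,
                      _["accept_beta"] = acc_b,
                      _["accept_u"] = acc_uu / N,
                      _["scale_beta"] = s_beta,
                      _["scale_u"] = s_u);
}
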