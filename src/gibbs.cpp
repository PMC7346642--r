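// Grouped spike-and-slab Gaussian-mixture Gibbs sampler.
//
// Model: y = C gamma + sum_g X_g beta_g + e,  e ~ N(0, sigma_e^2 I).
// Each marker effect beta_{gj} has prior
//   P(beta = 0) = pi_{g0};  P(component k) = pi_{gk}, beta ~ N(0, v_{gk}),
// with v_{gk} = c_{gk} * sigma_g^2 (relative scale, BayesR convention) or
// v_{gk} = c_{gk} (absolute scale). pi_g ~ Dirichlet(alpha_g);
// sigma_g^2 and sigma_e^2 have scaled inverse-chi-square conditionals.
// Uses R's RNG throughout so set.seed() gives bit-reproducible chains.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static double rinvchisq(double nu, double s2) {
  return nu * s2 / R::rchisq(nu);
}

static double dot(const double* a, const double* b, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += a[i] * b[i];
  return s;
}

static double sample_var(const std::vector<double>& x) {
  int n = (int)x.size();
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += x[i];
  m /= n;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += (x[i] - m) * (x[i] - m);
  return s / (n - 1);
}

static double sample_cov(const std::vector<double>& x, const std::vector<double>& y) {
  int n = (int)x.size();
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += (x[i] - mx) * (y[i] - my);
  return s / (n - 1);
}

// [[Rcpp::export]]
List gibbs_mixture(NumericVector y, NumericMatrix C, List Xg,
                   List comp_var, List dirichlet, LogicalVector relative_scale,
                   int n_iter, int burn_in, int thin,
                   NumericVector fix_sigma_g, double fix_sigma_e,
                   List fix_pi, double nu0, double s02) {
  const int n = y.size();
  const int G = Xg.size();
  const int P = C.ncol();

  std::vector<NumericMatrix> X(G);
  std::vector<int> mg(G), K(G);
  int M = 0;
  for (int g = 0; g < G; ++g) {
    X[g] = as<NumericMatrix>(Xg[g]);
    mg[g] = X[g].ncol();
    K[g] = as<NumericVector>(comp_var[g]).size();
    M += mg[g];
  }

  // flattened marker index -> (group, column)
  std::vector<int> idx_g(M), idx_j(M);
  {
    int t = 0;
    for (int g = 0; g < G; ++g)
      for (int j = 0; j < mg[g]; ++j) { idx_g[t] = g; idx_j[t] = j; ++t; }
  }

  double var_y = 0.0;
  {
    std::vector<double> yy(y.begin(), y.end());
    var_y = sample_var(yy);
  }

  // state
  std::vector<double> r(y.begin(), y.end());          // residual
  std::vector<double> gamma(P, 0.0);
  std::vector<std::vector<double>> beta(G);
  std::vector<std::vector<int>> comp(G);               // 0 = spike, 1..K
  std::vector<std::vector<std::vector<double>>> u(G);  // per group/component fitted value
  std::vector<std::vector<double>> xtx(G);
  std::vector<double> sigma_g(G), pi_flat;
  std::vector<std::vector<double>> pi(G);
  for (int g = 0; g < G; ++g) {
    beta[g].assign(mg[g], 0.0);
    comp[g].assign(mg[g], 0);
    u[g].assign(K[g], std::vector<double>(n, 0.0));
    xtx[g].assign(mg[g], 0.0);
    for (int j = 0; j < mg[g]; ++j)
      xtx[g][j] = dot(&X[g](0, j), &X[g](0, j), n);
    sigma_g[g] = R_IsNA(fix_sigma_g[g]) ? 0.5 * var_y / G : fix_sigma_g[g];
    if (Rf_isNull(fix_pi[g])) {
      pi[g].assign(K[g] + 1, 1.0 / (K[g] + 1));
    } else {
      NumericVector fp = as<NumericVector>(fix_pi[g]);
      pi[g].assign(fp.begin(), fp.end());
    }
  }
  double sigma_e = R_IsNA(fix_sigma_e) ? 0.5 * var_y : fix_sigma_e;

  std::vector<double> cpc(P, 0.0);
  for (int p = 0; p < P; ++p) cpc[p] = dot(&C(0, p), &C(0, p), n);

  // accumulators / stores
  const int n_keep = (n_iter - burn_in + thin - 1) / thin > 0 ?
                     (n_iter - burn_in) / thin : 0;
  int kept = 0;
  std::vector<std::vector<double>> incl(G), bsum(G), bsq(G);
  for (int g = 0; g < G; ++g) {
    incl[g].assign(mg[g], 0.0);
    bsum[g].assign(mg[g], 0.0);
    bsq[g].assign(mg[g], 0.0);
  }
  NumericMatrix share_draws(n_keep, G);
  int KC = 0;
  for (int g = 0; g < G; ++g) KC += K[g];
  NumericMatrix comp_share_draws(n_keep, KC);
  NumericMatrix sigma_g_draws(n_keep, G);
  NumericVector sigma_e_draws(n_keep);
  int PI = 0;
  for (int g = 0; g < G; ++g) PI += K[g] + 1;
  NumericMatrix pi_draws(n_keep, PI);
  std::vector<double> fitted_sum(n, 0.0);

  std::vector<int> perm(M);
  for (int t = 0; t < M; ++t) perm[t] = t;
  std::vector<double> logw;
  std::vector<double> utot(n);

  for (int iter = 0; iter < n_iter; ++iter) {
    // (1) fixed effects, flat prior, coefficient-wise Gibbs
    for (int p = 0; p < P; ++p) {
      const double* cp = &C(0, p);
      double g_old = gamma[p];
      double rhs = dot(cp, r.data(), n) + g_old * cpc[p];
      double mean = rhs / cpc[p];
      double g_new = mean + ::sqrt(sigma_e / cpc[p]) * norm_rand();
      double d = g_old - g_new;
      for (int i = 0; i < n; ++i) r[i] += cp[i] * d;
      gamma[p] = g_new;
    }

    // (2) markers in re-randomised order (Fisher-Yates on R's RNG)
    for (int t = M - 1; t > 0; --t) {
      int s = (int)(unif_rand() * (t + 1));
      if (s > t) s = t;
      std::swap(perm[t], perm[s]);
    }
    for (int t = 0; t < M; ++t) {
      int g = idx_g[perm[t]], j = idx_j[perm[t]];
      const double* x = &X[g](0, j);
      double b_old = beta[g][j];
      int k_old = comp[g][j];
      double xx = xtx[g][j];
      double rhs = dot(x, r.data(), n) + b_old * xx;

      logw.assign(K[g] + 1, 0.0);
      logw[0] = ::log(pi[g][0]);
      const NumericVector cv = as<NumericVector>(comp_var[g]);
      for (int k = 1; k <= K[g]; ++k) {
        double v = relative_scale[g] ? cv[k - 1] * sigma_g[g] : cv[k - 1];
        double a = sigma_e + v * xx;
        logw[k] = ::log(pi[g][k]) - 0.5 * ::log1p(v * xx / sigma_e)
                  + 0.5 * rhs * rhs * v / (sigma_e * a);
      }
      double mx = logw[0];
      for (int k = 1; k <= K[g]; ++k) if (logw[k] > mx) mx = logw[k];
      double tot = 0.0;
      for (int k = 0; k <= K[g]; ++k) { logw[k] = ::exp(logw[k] - mx); tot += logw[k]; }
      double udraw = unif_rand() * tot, acc = 0.0;
      int k_new = K[g];
      for (int k = 0; k <= K[g]; ++k) {
        acc += logw[k];
        if (udraw <= acc) { k_new = k; break; }
      }

      double b_new = 0.0;
      if (k_new > 0) {
        double v = relative_scale[g] ? cv[k_new - 1] * sigma_g[g] : cv[k_new - 1];
        double post_prec = xx + sigma_e / v;
        b_new = rhs / post_prec + ::sqrt(sigma_e / post_prec) * norm_rand();
      }
      if (b_old != b_new || k_old != k_new) {
        double d = b_old - b_new;
        if (b_old != 0.0 || b_new != 0.0)
          for (int i = 0; i < n; ++i) r[i] += x[i] * d;
        if (k_old == k_new && k_old > 0) {
          std::vector<double>& uu = u[g][k_old - 1];
          for (int i = 0; i < n; ++i) uu[i] -= x[i] * d;
        } else {
          if (k_old > 0 && b_old != 0.0) {
            std::vector<double>& uo = u[g][k_old - 1];
            for (int i = 0; i < n; ++i) uo[i] -= x[i] * b_old;
          }
          if (k_new > 0 && b_new != 0.0) {
            std::vector<double>& un = u[g][k_new - 1];
            for (int i = 0; i < n; ++i) un[i] += x[i] * b_new;
          }
        }
      }
      beta[g][j] = b_new;
      comp[g][j] = k_new;
    }

    // (3) mixture proportions
    for (int g = 0; g < G; ++g) {
      if (!Rf_isNull(fix_pi[g])) continue;
      NumericVector al = as<NumericVector>(dirichlet[g]);
      std::vector<int> counts(K[g] + 1, 0);
      for (int j = 0; j < mg[g]; ++j) counts[comp[g][j]]++;
      double s = 0.0;
      for (int k = 0; k <= K[g]; ++k) {
        pi[g][k] = R::rgamma(counts[k] + al[k], 1.0);
        s += pi[g][k];
      }
      for (int k = 0; k <= K[g]; ++k) pi[g][k] /= s;
    }

    // (4) group variance hyperparameters
    for (int g = 0; g < G; ++g) {
      if (!R_IsNA(fix_sigma_g[g]) || !relative_scale[g]) continue;
      const NumericVector cv = as<NumericVector>(comp_var[g]);
      double ss = 0.0;
      int m_in = 0;
      for (int j = 0; j < mg[g]; ++j) {
        if (comp[g][j] > 0) {
          ss += beta[g][j] * beta[g][j] / cv[comp[g][j] - 1];
          ++m_in;
        }
      }
      double nu = nu0 + m_in;
      sigma_g[g] = rinvchisq(nu, (ss + nu0 * s02) / nu);
    }

    // (5) residual variance
    if (R_IsNA(fix_sigma_e)) {
      double ss = dot(r.data(), r.data(), n);
      double nu = nu0 + n;
      sigma_e = rinvchisq(nu, (ss + nu0 * s02) / nu);
    }

    // (6) record
    if (iter >= burn_in && (iter - burn_in) % thin == 0 && kept < n_keep) {
      int kc = 0, pc = 0;
      for (int g = 0; g < G; ++g) {
        std::fill(utot.begin(), utot.end(), 0.0);
        for (int k = 0; k < K[g]; ++k)
          for (int i = 0; i < n; ++i) utot[i] += u[g][k][i];
        share_draws(kept, g) = sample_var(utot) / var_y;
        for (int k = 0; k < K[g]; ++k)
          comp_share_draws(kept, kc++) = sample_cov(u[g][k], utot) / var_y;
        sigma_g_draws(kept, g) = sigma_g[g];
        for (int k = 0; k <= K[g]; ++k) pi_draws(kept, pc++) = pi[g][k];
        for (int j = 0; j < mg[g]; ++j) {
          if (comp[g][j] > 0) incl[g][j] += 1.0;
          bsum[g][j] += beta[g][j];
          bsq[g][j] += beta[g][j] * beta[g][j];
        }
      }
      sigma_e_draws[kept] = sigma_e;
      for (int i = 0; i < n; ++i) fitted_sum[i] += y[i] - r[i];
      ++kept;
    }
  }

  List marker(G);
  for (int g = 0; g < G; ++g) {
    NumericVector pip(mg[g]), bm(mg[g]), bs(mg[g]);
    for (int j = 0; j < mg[g]; ++j) {
      pip[j] = incl[g][j] / kept;
      bm[j] = bsum[g][j] / kept;
      double v = bsq[g][j] / kept - bm[j] * bm[j];
      bs[j] = v > 0 ? ::sqrt(v) : 0.0;
    }
    marker[g] = List::create(_["pip"] = pip, _["beta_mean"] = bm,
                             _["beta_sd"] = bs);
  }
  NumericVector fitted(n);
  for (int i = 0; i < n; ++i) fitted[i] = fitted_sum[i] / kept;

  return List::create(
    _["marker"] = marker,
    _["share_draws"] = share_draws,
    _["comp_share_draws"] = comp_share_draws,
    _["sigma_g_draws"] = sigma_g_draws,
    _["sigma_e_draws"] = sigma_e_draws,
    _["pi_draws"] = pi_draws,
    _["fitted"] = fitted,
    _["n_retained"] = kept,
    _["var_y"] = var_y);
}
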