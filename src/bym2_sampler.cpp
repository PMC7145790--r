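// Metropolis-within-Gibbs sampler for the BYM2 convolution model
//
//   O_i ~ Poisson(E_i * exp(a + X_i beta + b_i))
//   b_i = sigma * (sqrt(phi) u_i + sqrt(1-phi) v_i)      (non-island areas)
//   b_i = sigma * v_i                                    (island areas)
//   u   ~ scaled ICAR (precision s_c * Q_c per component, sum-to-zero)
//   v   ~ N(0, I)
//
// Single-site adaptive random-walk updates for u and v, adaptive scalar
// random walks for a, beta_j, log(sigma), logit(phi), plus a scaling move
// (sigma, u, v) -> (c*sigma, u/c, v/c) that leaves the likelihood invariant
// and decorrelates sigma from the latent fields. Structured effects are
// recentred to their per-component mean each sweep (sum-to-zero on the fly).
// Uses R's RNG throughout, so results are reproducible from set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double rw_adapt(double log_s, double p_acc, double target,
                              double gamma) {
  log_s += gamma * (p_acc - target);
  if (log_s < -9.0) log_s = -9.0;
  if (log_s > 4.0) log_s = 4.0;
  return log_s;
}

// [[Rcpp::export(name = ".bym2_mcmc")]]
List bym2_mcmc(NumericVector O, NumericVector logE, NumericMatrix X,
               IntegerVector adj, IntegerVector adj_ptr,
               NumericVector prior_prec,   // s_c * d_i, 0 for islands
               IntegerVector comp_id,      // 0-based, -1 for islands
               LogicalVector island,
               NumericVector comp_scaling, // s_c per non-island component
               int n_comp_spatial, int n_u_eff,
               double beta_sd, double sigma_rate,
               bool fix_sigma, double sigma_fixed,
               bool fix_phi, double phi_fixed,
               int n_iter, int n_warmup,
               double a0, NumericVector beta0, double sigma0, double phi0,
               double lik_scale) {
  const int n = O.size();
  const int p = X.ncol();
  const double target = 0.44;

  double a = a0;
  std::vector<double> beta(p);
  for (int j = 0; j < p; ++j) beta[j] = beta0[j];
  double sigma = fix_sigma ? sigma_fixed : sigma0;
  double phi = fix_phi ? phi_fixed : phi0;
  std::vector<double> u(n, 0.0), v(n, 0.0);

  // linear predictor pieces
  std::vector<double> lp_fix(n), w(n), eta(n), mu(n);
  double sumO = 0.0;
  for (int i = 0; i < n; ++i) sumO += O[i];

  auto weff = [&](int i) {
    return island[i] ? v[i]
                     : std::sqrt(phi) * u[i] + std::sqrt(1.0 - phi) * v[i];
  };
  auto refresh = [&]() {
    for (int i = 0; i < n; ++i) {
      double xb = 0.0;
      for (int j = 0; j < p; ++j) xb += X(i, j) * beta[j];
      lp_fix[i] = logE[i] + xb;
      w[i] = weff(i);
      eta[i] = lp_fix[i] + a + sigma * w[i];
      mu[i] = std::exp(eta[i]);
    }
  };
  refresh();

  // adaptive proposal scales (log)
  double ls_a = std::log(0.1), ls_sig = std::log(0.3), ls_phi = std::log(0.5),
         ls_resc = std::log(0.2);
  std::vector<double> ls_beta(p, std::log(0.1));
  std::vector<double> ls_u(n, std::log(0.5)), ls_v(n, std::log(0.5));

  const int n_keep = n_iter - n_warmup;
  NumericVector out_a(n_keep), out_sigma(n_keep), out_phi(n_keep);
  NumericMatrix out_beta(n_keep, p), out_b(n_keep, n), out_u(n_keep, n);

  for (int it = 1; it <= n_iter; ++it) {
    const bool adapting = it <= n_warmup;
    const double gamma = adapting ? 1.0 / std::sqrt((double)it) : 0.0;

    double sumMu = 0.0;
    for (int i = 0; i < n; ++i) sumMu += mu[i];

    // ---- intercept: eta shifts uniformly, so delta-loglik is closed form
    {
      double delta = std::exp(ls_a) * norm_rand();
      double dll = lik_scale * (delta * sumO - (std::expm1(delta)) * sumMu);
      double ap = a + delta;
      dll += -0.5 * (ap * ap - a * a) / (beta_sd * beta_sd);
      double p_acc = dll >= 0 ? 1.0 : std::exp(dll);
      if (unif_rand() < p_acc) {
        a = ap;
        for (int i = 0; i < n; ++i) { eta[i] += delta; mu[i] = std::exp(eta[i]); }
        sumMu = 0.0; for (int i = 0; i < n; ++i) sumMu += mu[i];
      }
      if (adapting) ls_a = rw_adapt(ls_a, p_acc, target, gamma);
    }

    // ---- regression coefficients
    for (int j = 0; j < p; ++j) {
      double delta = std::exp(ls_beta[j]) * norm_rand();
      double dll = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = delta * X(i, j);
        dll += O[i] * d - mu[i] * std::expm1(d);
      }
      dll *= lik_scale;
      double bp = beta[j] + delta;
      dll += -0.5 * (bp * bp - beta[j] * beta[j]) / (beta_sd * beta_sd);
      double p_acc = dll >= 0 ? 1.0 : std::exp(dll);
      if (unif_rand() < p_acc) {
        beta[j] = bp;
        for (int i = 0; i < n; ++i) {
          double d = delta * X(i, j);
          lp_fix[i] += d; eta[i] += d; mu[i] = std::exp(eta[i]);
        }
      }
      if (adapting) ls_beta[j] = rw_adapt(ls_beta[j], p_acc, target, gamma);
    }

    // ---- structured field, single-site
    double sqf = std::sqrt(phi);
    for (int i = 0; i < n; ++i) {
      if (island[i]) continue;
      int k0 = adj_ptr[i], k1 = adj_ptr[i + 1];
      double msum = 0.0;
      for (int k = k0; k < k1; ++k) msum += u[adj[k]];
      double m = msum / (k1 - k0);
      double prec = prior_prec[i];
      double du = std::exp(ls_u[i]) * norm_rand();
      double up = u[i] + du;
      double db = sigma * sqf * du;
      double dll = lik_scale * (O[i] * db - mu[i] * std::expm1(db));
      dll += -0.5 * prec * ((up - m) * (up - m) - (u[i] - m) * (u[i] - m));
      double p_acc = dll >= 0 ? 1.0 : std::exp(dll);
      if (unif_rand() < p_acc) {
        u[i] = up; w[i] += sqf * du; eta[i] += db; mu[i] = std::exp(eta[i]);
      }
      if (adapting) ls_u[i] = rw_adapt(ls_u[i], p_acc, target, gamma);
    }

    // ---- recentre u within each component (sum-to-zero on the fly)
    if (n_comp_spatial > 0) {
      std::vector<double> csum(n_comp_spatial, 0.0);
      std::vector<int> cn(n_comp_spatial, 0);
      for (int i = 0; i < n; ++i) {
        if (island[i]) continue;
        csum[comp_id[i]] += u[i]; cn[comp_id[i]] += 1;
      }
      for (int i = 0; i < n; ++i) {
        if (island[i]) continue;
        double shift = csum[comp_id[i]] / cn[comp_id[i]];
        u[i] -= shift;
        double db = -sigma * sqf * shift;
        w[i] -= sqf * shift; eta[i] += db; mu[i] = std::exp(eta[i]);
      }
    }

    // ---- unstructured field, single-site
    double sqg = std::sqrt(1.0 - phi);
    for (int i = 0; i < n; ++i) {
      double coef = island[i] ? sigma : sigma * sqg;
      double dv = std::exp(ls_v[i]) * norm_rand();
      double vp = v[i] + dv;
      double db = coef * dv;
      double dll = lik_scale * (O[i] * db - mu[i] * std::expm1(db));
      dll += -0.5 * (vp * vp - v[i] * v[i]);
      double p_acc = dll >= 0 ? 1.0 : std::exp(dll);
      if (unif_rand() < p_acc) {
        v[i] = vp;
        w[i] += island[i] ? dv : sqg * dv;
        eta[i] += db; mu[i] = std::exp(eta[i]);
      }
      if (adapting) ls_v[i] = rw_adapt(ls_v[i], p_acc, target, gamma);
    }

    // ---- sigma: random walk on log scale (exact prior draw if no data)
    if (!fix_sigma) {
      if (lik_scale == 0.0) {
        sigma = exp_rand() / sigma_rate;
        refresh();
      } else {
        double dls = std::exp(ls_sig) * norm_rand();
        double sp = sigma * std::exp(dls);
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          double db = (sp - sigma) * w[i];
          dll += O[i] * db - mu[i] * std::expm1(db);
        }
        dll *= lik_scale;
        dll += -sigma_rate * (sp - sigma) + dls;   // Exp prior + log-Jacobian
        double p_acc = dll >= 0 ? 1.0 : std::exp(dll);
        if (unif_rand() < p_acc) {
          for (int i = 0; i < n; ++i) {
            eta[i] += (sp - sigma) * w[i]; mu[i] = std::exp(eta[i]);
          }
          sigma = sp;
        }
        if (adapting) ls_sig = rw_adapt(ls_sig, p_acc, target, gamma);
      }
    }

    // ---- phi: random walk on logit scale, uniform prior
    if (!fix_phi) {
      if (lik_scale == 0.0) {
        phi = unif_rand();
        refresh();
      } else {
        double lphi = std::log(phi / (1.0 - phi));
        double lp = lphi + std::exp(ls_phi) * norm_rand();
        double pp = 1.0 / (1.0 + std::exp(-lp));
        double sqfp = std::sqrt(pp), sqgp = std::sqrt(1.0 - pp);
        double dll = 0.0;
        std::vector<double> dbv(n);
        for (int i = 0; i < n; ++i) {
          double wp = island[i] ? v[i] : sqfp * u[i] + sqgp * v[i];
          dbv[i] = sigma * (wp - w[i]);
          dll += O[i] * dbv[i] - mu[i] * std::expm1(dbv[i]);
        }
        dll *= lik_scale;
        dll += std::log(pp * (1.0 - pp)) - std::log(phi * (1.0 - phi));
        double p_acc = dll >= 0 ? 1.0 : std::exp(dll);
        if (unif_rand() < p_acc) {
          phi = pp;
          for (int i = 0; i < n; ++i) {
            if (!island[i]) w[i] = sqfp * u[i] + sqgp * v[i];
            eta[i] += dbv[i]; mu[i] = std::exp(eta[i]);
          }
        }
        if (adapting) ls_phi = rw_adapt(ls_phi, p_acc, target, gamma);
      }
    }

    // ---- likelihood-invariant rescaling (sigma, u, v) -> (c sigma, u/c, v/c)
    if (!fix_sigma && lik_scale > 0.0) {
      double d = std::exp(ls_resc) * norm_rand();
      double c = std::exp(d);
      double quadU = 0.0, quadV = 0.0;
      for (int i = 0; i < n; ++i) {
        quadV += v[i] * v[i];
        if (island[i]) continue;
        int k0 = adj_ptr[i], k1 = adj_ptr[i + 1];
        double s_c = comp_scaling[comp_id[i]];
        for (int k = k0; k < k1; ++k) {
          double diff = u[i] - u[adj[k]];
          quadU += 0.5 * s_c * diff * diff;   // each edge visited twice
        }
      }
      double ic2 = 1.0 / (c * c);
      double dlp = -0.5 * (ic2 - 1.0) * (quadU + quadV)        // field priors
                   - sigma_rate * sigma * (c - 1.0) + d        // Exp prior + d(log sigma)
                   - (n_u_eff + n) * d;                        // Jacobian of u,v
      double p_acc = dlp >= 0 ? 1.0 : std::exp(dlp);
      if (unif_rand() < p_acc) {
        sigma *= c;
        for (int i = 0; i < n; ++i) { u[i] /= c; v[i] /= c; }
        // eta, mu, w*sigma invariant; w itself changes
        for (int i = 0; i < n; ++i) w[i] /= c;
      }
      if (adapting) ls_resc = rw_adapt(ls_resc, p_acc, target, gamma);
    }

    // ---- store
    if (it > n_warmup) {
      int r = it - n_warmup - 1;
      out_a[r] = a; out_sigma[r] = sigma; out_phi[r] = phi;
      for (int j = 0; j < p; ++j) out_beta(r, j) = beta[j];
      for (int i = 0; i < n; ++i) {
        out_b(r, i) = sigma * w[i];
        out_u(r, i) = u[i];
      }
    }
  }

  return List::create(_["a"] = out_a, _["beta"] = out_beta,
                      _["sigma"] = out_sigma, _["phi"] = out_phi,
                      _["b"] = out_b, _["u"] = out_u);
}
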