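// Metropolis-within-Gibbs sampler for the spatially regularized
// two-compartment T2 model.
//
// Model, per in-mask voxel v with signal y_v (n_echo echoes):
//   y_v ~ Normal(bi_signal(theta_v), sigma^2 I)
//   theta_v = (s0, f, t2s, t2l) parameterized on the unconstrained scale
//   eta_v = (log s0, logit f, log t2s, log(t2l - t2s))
// Spatial prior (per channel p, intrinsic first-order Gaussian Markov
// random field over the mask-interior neighbour graph):
//   eta_{v,p} | neighbours ~ Normal(mean of neighbours, tau_p^2 / n_nbr)
// Each channel additionally carries a weakly informative Gaussian anchor
// prior eta_{v,p} ~ Normal(mu_p, omega_p^2). Without it the posterior is
// improper: as log(t2l - t2s) -> -inf or logit(f) -> +/-inf the likelihood
// tends to the mono-exponential limit, a positive constant, so a flat prior
// puts infinite mass in the compartment-merging cone and the chain drifts
// into it indefinitely. The anchor is broad enough to be negligible for
// identifiable voxels.
//
// The noise variance carries a Jeffreys prior p(sigma^2) ~ 1/sigma^2 with a
// conjugate inverse-gamma Gibbs update. The spatial precisions tau_p^2 are
// either fixed (empirical-Bayes mode, default upstream) or given Jeffreys
// priors with inverse-gamma Gibbs updates (tau_gibbs = true); the joint
// hierarchical chain can funnel into over-smoothing, which is why the fixed
// mode exists.
//
// Single-site random-walk updates are interleaved with one global-shift
// Metropolis move per channel and sweep (all voxels shifted together). The
// intrinsic GMRF prior is invariant under such shifts, so the collective
// likelihood and the anchor decide; this mixes the channel's global level,
// the slowest mode of a single-site sampler on a strongly coupled field.
//
// Proposal scales adapt toward ~30% acceptance during burn-in only and are
// frozen afterwards, preserving detailed balance for the retained draws.
// Uses R's RNG, so results are reproducible under set.seed().
//
// Matrix layout: voxels are COLUMNS (column-major contiguity), i.e.
// Y is n_echo x n_vox, eta is 4 x n_vox.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline void eta_to_theta(const double *eta, double *theta) {
  theta[0] = std::exp(eta[0]);            // s0
  theta[1] = inv_logit(eta[1]);           // f
  theta[2] = std::exp(eta[2]);            // t2s
  theta[3] = theta[2] + std::exp(eta[3]); // t2l
}

static inline double voxel_rss(const double *y, const double *te, int n_echo,
                               const double *theta, double *model_out) {
  double rss = 0.0;
  for (int k = 0; k < n_echo; ++k) {
    double m = theta[0] * (theta[1] * std::exp(-te[k] / theta[2]) +
                           (1.0 - theta[1]) * std::exp(-te[k] / theta[3]));
    if (model_out) model_out[k] = m;
    double r = y[k] - m;
    rss += r * r;
  }
  return rss;
}

// [[Rcpp::export(name = ".bayes_mcmc")]]
List bayes_mcmc(NumericMatrix Y,          // n_echo x n_vox signals
                NumericVector te,         // echo times (ms)
                NumericMatrix eta_init,   // 4 x n_vox initial values
                IntegerVector nbr_idx,    // 0-based CSR neighbour indices
                IntegerVector nbr_start,  // length n_vox + 1
                int n_iter, int n_burn,
                bool spatial,
                bool tau_gibbs,
                NumericVector tau2_init,
                NumericVector anchor_mu,     // length 4
                NumericVector anchor_omega2, // length 4
                double init_scale,
                double sigma_init,
                bool track_map) {
  const int n_vox = Y.ncol();
  const int n_echo = Y.nrow();
  const int P = 4;
  const double target_acc = 0.3;
  const int adapt_every = 50;

  NumericMatrix eta(clone(eta_init));        // P x n_vox
  NumericMatrix model(n_echo, n_vox);
  NumericVector rss(n_vox);
  double theta[4];
  for (int v = 0; v < n_vox; ++v) {
    eta_to_theta(&eta(0, v), theta);
    rss[v] = voxel_rss(&Y(0, v), te.begin(), n_echo, theta, &model(0, v));
  }

  double sigma2 = sigma_init * sigma_init;
  std::vector<double> tau2(tau2_init.begin(), tau2_init.end());

  NumericMatrix scale(P, n_vox);
  std::fill(scale.begin(), scale.end(), init_scale);
  IntegerMatrix acc_win(P, n_vox);   // window acceptance counts (adaptation)
  IntegerMatrix acc_tot(P, n_vox);   // post-burn-in acceptance counts

  // post-burn-in accumulators: transformed scale, natural scale, split halves
  NumericMatrix eta_sum(P, n_vox), eta_sq(P, n_vox);
  NumericMatrix th_sum(P, n_vox), th_sq(P, n_vox);
  NumericMatrix h1_sum(P, n_vox), h1_sq(P, n_vox);
  NumericMatrix h2_sum(P, n_vox), h2_sq(P, n_vox);
  double sigma2_sum = 0.0;
  std::vector<double> tau2_sum(P, 0.0);

  NumericMatrix eta_map(P, n_vox);
  double best_lp = R_NegInf;

  // thinned draws for quantile-based estimators and diagnostics
  int thin = (n_iter - n_burn) / 200; if (thin < 1) thin = 1;
  int n_thin = (n_iter - n_burn) / thin;
  NumericVector draws((R_xlen_t)n_thin * n_vox * P);
  int thin_count = 0;

  std::vector<double> gscale(P, 0.02);   // global-shift proposal scales
  std::vector<int> gacc(P, 0);

  const int n_keep = n_iter - n_burn;
  const int half = n_keep / 2;
  const double n_obs = (double)n_vox * n_echo;
  std::vector<double> prop_model(n_echo);
  double eta_prop[4];

  RNGScope rng;

  for (int it = 0; it < n_iter; ++it) {
    const bool kept = it >= n_burn;

    for (int v = 0; v < n_vox; ++v) {
      const double *yv = &Y(0, v);
      for (int p = 0; p < P; ++p) {
        double cur = eta(p, v);
        double prop = cur + scale(p, v) * norm_rand();

        for (int q = 0; q < P; ++q) eta_prop[q] = eta(q, v);
        eta_prop[p] = prop;
        eta_to_theta(eta_prop, theta);
        double rss_prop = voxel_rss(yv, te.begin(), n_echo, theta,
                                    prop_model.data());

        double dlog = -(rss_prop - rss[v]) / (2.0 * sigma2);
        {
          double a1 = prop - anchor_mu[p], a0 = cur - anchor_mu[p];
          dlog += -(a1 * a1 - a0 * a0) / (2.0 * anchor_omega2[p]);
        }
        if (spatial) {
          int s = nbr_start[v], e = nbr_start[v + 1];
          int nn = e - s;
          if (nn > 0) {
            double m = 0.0;
            for (int j = s; j < e; ++j) m += eta(p, nbr_idx[j]);
            m /= nn;
            double d1 = prop - m, d0 = cur - m;
            dlog += -(double)nn / (2.0 * tau2[p]) * (d1 * d1 - d0 * d0);
          }
        }
        if (dlog >= 0.0 || unif_rand() < std::exp(dlog)) {
          eta(p, v) = prop;
          rss[v] = rss_prop;
          std::copy(prop_model.begin(), prop_model.end(), &model(0, v));
          acc_win(p, v) += 1;
          if (kept) acc_tot(p, v) += 1;
        }
      }
    }

    // global-shift move per channel: eta(p, .) += delta
    for (int p = 0; p < P; ++p) {
      double delta = gscale[p] * norm_rand();
      double dlog = 0.0, srss_new = 0.0, srss_old = 0.0;
      // anchor term: sum over voxels of the quadratic change
      double sdev = 0.0;
      for (int v = 0; v < n_vox; ++v) sdev += eta(p, v) - anchor_mu[p];
      dlog += -(2.0 * delta * sdev + n_vox * delta * delta) /
              (2.0 * anchor_omega2[p]);
      for (int v = 0; v < n_vox; ++v) {
        for (int q = 0; q < P; ++q) eta_prop[q] = eta(q, v);
        eta_prop[p] += delta;
        eta_to_theta(eta_prop, theta);
        srss_new += voxel_rss(&Y(0, v), te.begin(), n_echo, theta, nullptr);
        srss_old += rss[v];
      }
      dlog += -(srss_new - srss_old) / (2.0 * sigma2);
      if (dlog >= 0.0 || unif_rand() < std::exp(dlog)) {
        for (int v = 0; v < n_vox; ++v) {
          eta(p, v) += delta;
          eta_to_theta(&eta(0, v), theta);
          rss[v] = voxel_rss(&Y(0, v), te.begin(), n_echo, theta, &model(0, v));
        }
        gacc[p] += 1;
      }
    }

    // Gibbs update of the noise variance: InvGamma(N/2, RSS/2)
    double rss_tot = 0.0;
    for (int v = 0; v < n_vox; ++v) rss_tot += rss[v];
    sigma2 = (rss_tot / 2.0 + 1e-12) / R::rgamma(n_obs / 2.0, 1.0);
    if (sigma2 < 1e-12) sigma2 = 1e-12;

    // Gibbs update of the spatial precision per channel:
    // InvGamma((n_vox - 1)/2, SS_p/2) over unique graph edges.
    // Skipped when the spatial precision is fixed (empirical-Bayes mode).
    if (spatial && tau_gibbs) {
      for (int p = 0; p < P; ++p) {
        double ss = 0.0;
        for (int v = 0; v < n_vox; ++v) {
          for (int j = nbr_start[v]; j < nbr_start[v + 1]; ++j) {
            int w = nbr_idx[j];
            if (w > v) {
              double d = eta(p, v) - eta(p, w);
              ss += d * d;
            }
          }
        }
        double shape = (n_vox - 1) / 2.0;
        if (shape < 0.5) shape = 0.5;
        tau2[p] = (ss / 2.0 + 1e-10) / R::rgamma(shape, 1.0);
        if (tau2[p] < 1e-10) tau2[p] = 1e-10;
      }
    }

    // proposal adaptation, burn-in only
    if (!kept && (it + 1) % adapt_every == 0) {
      for (int p = 0; p < P; ++p) {
        double rate = (double)gacc[p] / adapt_every;
        double s = gscale[p] * std::exp(rate - target_acc);
        if (s < 1e-5) s = 1e-5;
        if (s > 1.0) s = 1.0;
        gscale[p] = s;
        gacc[p] = 0;
      }
      for (int v = 0; v < n_vox; ++v) {
        for (int p = 0; p < P; ++p) {
          double rate = (double)acc_win(p, v) / adapt_every;
          double s = scale(p, v) * std::exp(rate - target_acc);
          if (s < 1e-4) s = 1e-4;
          if (s > 5.0) s = 5.0;
          scale(p, v) = s;
          acc_win(p, v) = 0;
        }
      }
    }

    if (kept) {
      const int kept_it = it - n_burn;
      for (int v = 0; v < n_vox; ++v) {
        eta_to_theta(&eta(0, v), theta);
        for (int p = 0; p < P; ++p) {
          double e = eta(p, v), t = theta[p];
          eta_sum(p, v) += e; eta_sq(p, v) += e * e;
          th_sum(p, v) += t; th_sq(p, v) += t * t;
          if (kept_it < half) { h1_sum(p, v) += e; h1_sq(p, v) += e * e; }
          else if (kept_it < 2 * half) { h2_sum(p, v) += e; h2_sq(p, v) += e * e; }
        }
      }
      sigma2_sum += sigma2;
      for (int p = 0; p < P; ++p) tau2_sum[p] += tau2[p];

      if (kept_it % thin == 0 && thin_count < n_thin) {
        double *d = &draws[(R_xlen_t)thin_count * n_vox * P];
        std::copy(eta.begin(), eta.end(), d);
        thin_count++;
      }

      if (track_map) {
        double lp = -n_obs / 2.0 * std::log(sigma2) - rss_tot / (2.0 * sigma2);
        if (lp > best_lp) {
          best_lp = lp;
          std::copy(eta.begin(), eta.end(), eta_map.begin());
        }
      }
    }
  }

  // summaries, returned voxel-per-row (n_vox x P)
  NumericMatrix eta_mean(n_vox, P), eta_sd(n_vox, P);
  NumericMatrix th_mean(n_vox, P), th_sd(n_vox, P);
  NumericMatrix accept(n_vox, P), rhat(n_vox, P);
  NumericMatrix eta_map_out(n_vox, P);
  for (int v = 0; v < n_vox; ++v) {
    for (int p = 0; p < P; ++p) {
      double m = eta_sum(p, v) / n_keep;
      eta_mean(v, p) = m;
      double var = eta_sq(p, v) / n_keep - m * m;
      eta_sd(v, p) = var > 0 ? std::sqrt(var * n_keep / (n_keep - 1.0)) : 0.0;
      double tm = th_sum(p, v) / n_keep;
      th_mean(v, p) = tm;
      double tvar = th_sq(p, v) / n_keep - tm * tm;
      th_sd(v, p) = tvar > 0 ? std::sqrt(tvar * n_keep / (n_keep - 1.0)) : 0.0;
      accept(v, p) = (double)acc_tot(p, v) / n_keep;
      eta_map_out(v, p) = eta_map(p, v);

      // split-chain convergence statistic over the two halves
      double m1 = h1_sum(p, v) / half, m2 = h2_sum(p, v) / half;
      double v1 = h1_sq(p, v) / half - m1 * m1;
      double v2 = h2_sq(p, v) / half - m2 * m2;
      if (v1 < 0) v1 = 0;
      if (v2 < 0) v2 = 0;
      double W = (v1 + v2) / 2.0;
      double mbar = (m1 + m2) / 2.0;
      double B = half * ((m1 - mbar) * (m1 - mbar) + (m2 - mbar) * (m2 - mbar));
      if (W < 1e-300) { rhat(v, p) = 1.0; }
      else {
        double vplus = (half - 1.0) / half * W + B / half;
        rhat(v, p) = std::sqrt(vplus / W);
      }
    }
  }

  return List::create(
    _["eta_mean"] = eta_mean, _["eta_sd"] = eta_sd,
    _["theta_mean"] = th_mean, _["theta_sd"] = th_sd,
    _["accept"] = accept, _["rhat"] = rhat,
    _["eta_map"] = eta_map_out,
    _["draws"] = draws, _["n_thin"] = thin_count,
    _["sigma2_mean"] = sigma2_sum / n_keep,
    _["tau2_mean"] = NumericVector(tau2_sum.begin(), tau2_sum.end()) /
                     (double)n_keep,
    _["n_keep"] = n_keep);
}
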