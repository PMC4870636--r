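#include <Rcpp.h>
#include <numeric>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for Poisson log-linear disease-mapping
// models with CAR random effects. Structures:
//   0 = IND    exchangeable effects theta ~ N(0, sigma2)
//   1 = IAR    intrinsic autoregressive phi (sum-to-zero)
//   2 = BYM    convolution phi (IAR) + theta (IND)
//   3 = LER    Leroux phi with mixing rho in [0,1] (sum-to-zero)
// Likelihood: y_k ~ Poisson(exp(offset_k + x_k' beta + phi_k + theta_k)).
// Uses R's RNG throughout, so set.seed() gives identical chains.

static inline double pois_delta(double y, double eta_old, double eta_new) {
  // change in Poisson log-likelihood for one observation
  return y * (eta_new - eta_old) - (std::exp(eta_new) - std::exp(eta_old));
}

// [[Rcpp::export]]
List car_mcmc_cpp(NumericVector y, NumericMatrix X, NumericVector offset,
                  List nb, NumericVector dvec, int structure,
                  double v_beta, double tau_a, double tau_b,
                  double sig_a, double sig_b, NumericVector lambda,
                  NumericVector beta_init,
                  int n_burn, int n_save, int thin,
                  bool fix_rho, double rho_init,
                  bool fix_tau2, double tau2_init,
                  bool fix_sigma2, double sigma2_init) {
  const int n = y.size(), p = X.ncol();
  const bool has_phi = structure >= 1;           // IAR, BYM, LER
  const bool has_theta = (structure == 0 || structure == 2);
  const bool has_rho = (structure == 3);

  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> phi(n, 0.0), theta(n, 0.0), eta(n);
  double tau2 = fix_tau2 ? tau2_init : 0.1;
  double sigma2 = fix_sigma2 ? sigma2_init : 0.1;
  double rho;
  if (structure == 1) rho = 1.0;                 // intrinsic limit
  else if (structure == 3) rho = fix_rho ? rho_init : 0.5;
  else rho = 0.0;

  for (int k = 0; k < n; ++k) {
    double xb = 0.0;
    for (int j = 0; j < p; ++j) xb += X(k, j) * beta[j];
    eta[k] = offset[k] + xb;
  }

  // proposal scales with burn-in adaptation
  std::vector<double> s_beta(p, 0.1);
  double s_phi = 0.1, s_theta = 0.1, s_rho = 0.05;
  std::vector<int> acc_beta(p, 0), att_beta(p, 0);
  int acc_phi = 0, att_phi = 0, acc_theta = 0, att_theta = 0;
  int acc_rho = 0, att_rho = 0;
  // post-burn-in totals for reporting
  std::vector<long> Acc_beta(p, 0), Att_beta(p, 0);
  long Acc_phi = 0, Att_phi = 0, Acc_theta = 0, Att_theta = 0,
       Acc_rho = 0, Att_rho = 0;

  // precompute neighbour index arrays
  std::vector<std::vector<int>> nbr(n);
  for (int k = 0; k < n; ++k) {
    IntegerVector v = nb[k];
    nbr[k].assign(v.begin(), v.end());
  }

  NumericMatrix beta_out(n_save, p), fitted_out(n_save, n);
  NumericVector tau2_out(n_save), sigma2_out(n_save), rho_out(n_save),
      dev_out(n_save);
  std::vector<double> eta_mean(n, 0.0), phi_mean(n, 0.0), theta_mean(n, 0.0);

  double lgy = 0.0;                              // sum lgamma(y + 1)
  for (int k = 0; k < n; ++k) lgy += R::lgammafn(y[k] + 1.0);

  RNGScope scope;
  const int n_iter = n_burn + n_save * thin;
  int saved = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool burn = iter <= n_burn;

    // --- beta: componentwise random-walk Metropolis
    for (int j = 0; j < p; ++j) {
      const double bnew = beta[j] + s_beta[j] * norm_rand();
      const double db = bnew - beta[j];
      double dll = 0.0;
      for (int k = 0; k < n; ++k) {
        const double en = eta[k] + X(k, j) * db;
        dll += pois_delta(y[k], eta[k], en);
      }
      dll += -(bnew * bnew - beta[j] * beta[j]) / (2.0 * v_beta);
      ++att_beta[j]; if (!burn) ++Att_beta[j];
      if (std::isfinite(dll) && std::log(unif_rand()) < dll) {
        for (int k = 0; k < n; ++k) eta[k] += X(k, j) * db;
        beta[j] = bnew;
        ++acc_beta[j]; if (!burn) ++Acc_beta[j];
      }
    }

    // --- phi: single-site Metropolis with CAR full-conditional prior
    if (has_phi) {
      for (int k = 0; k < n; ++k) {
        double nbsum = 0.0;
        for (int j : nbr[k]) nbsum += phi[j];
        double cprec, cmean;
        if (structure == 3) {
          const double denom = rho * dvec[k] + 1.0 - rho;
          cprec = denom / tau2;
          cmean = rho * nbsum / denom;
        } else {                                  // IAR / BYM
          cprec = dvec[k] / tau2;
          cmean = nbsum / dvec[k];
        }
        const double pnew = phi[k] + s_phi * norm_rand();
        const double enew = eta[k] + (pnew - phi[k]);
        double dll = pois_delta(y[k], eta[k], enew);
        dll += -0.5 * cprec * ((pnew - cmean) * (pnew - cmean) -
                               (phi[k] - cmean) * (phi[k] - cmean));
        ++att_phi; if (!burn) ++Att_phi;
        if (std::isfinite(dll) && std::log(unif_rand()) < dll) {
          eta[k] = enew; phi[k] = pnew;
          ++acc_phi; if (!burn) ++Acc_phi;
        }
      }
      // sum-to-zero recentring of the structured effects
      double m = 0.0;
      for (int k = 0; k < n; ++k) m += phi[k];
      m /= n;
      for (int k = 0; k < n; ++k) { phi[k] -= m; eta[k] -= m; }
    }

    // --- theta: single-site Metropolis, exchangeable N(0, sigma2) prior
    if (has_theta) {
      for (int k = 0; k < n; ++k) {
        const double tnew = theta[k] + s_theta * norm_rand();
        const double enew = eta[k] + (tnew - theta[k]);
        double dll = pois_delta(y[k], eta[k], enew);
        dll += -(tnew * tnew - theta[k] * theta[k]) / (2.0 * sigma2);
        ++att_theta; if (!burn) ++Att_theta;
        if (std::isfinite(dll) && std::log(unif_rand()) < dll) {
          eta[k] = enew; theta[k] = tnew;
          ++acc_theta; if (!burn) ++Acc_theta;
        }
      }
    }

    // --- variance components: conjugate inverse-gamma Gibbs draws
    double quad_sp = 0.0, quad_id = 0.0;
    if (has_phi) {
      for (int k = 0; k < n; ++k) {
        quad_id += phi[k] * phi[k];
        for (int j : nbr[k])
          if (j > k) quad_sp += (phi[k] - phi[j]) * (phi[k] - phi[j]);
      }
      if (!fix_tau2) {
        // phi is recentred to sum to zero, so the field has n - 1 free
        // dimensions under every structure
        const double shape = tau_a + (n - 1) / 2.0;
        const double quad = (structure == 3)
            ? rho * quad_sp + (1.0 - rho) * quad_id   // Leroux
            : quad_sp;                                // intrinsic
        tau2 = 1.0 / R::rgamma(shape, 1.0 / (tau_b + quad / 2.0));
      }
    }
    if (has_theta && !fix_sigma2) {
      double ss = 0.0;
      for (int k = 0; k < n; ++k) ss += theta[k] * theta[k];
      sigma2 = 1.0 / R::rgamma(sig_a + n / 2.0, 1.0 / (sig_b + ss / 2.0));
    }

    // --- rho: random-walk Metropolis with reflection, exact log-det via
    //     the precomputed eigenvalues of (D - W)
    if (has_rho && !fix_rho) {
      double rnew = rho + s_rho * norm_rand();
      while (rnew < 0.0 || rnew > 1.0) {
        if (rnew < 0.0) rnew = -rnew;
        if (rnew > 1.0) rnew = 2.0 - rnew;
      }
      double dll = 0.0;
      for (int k = 0; k < n; ++k) {
        const double a = rnew * lambda[k] + 1.0 - rnew;
        const double b = rho * lambda[k] + 1.0 - rho;
        dll += 0.5 * (std::log(a) - std::log(b));
      }
      dll += -(rnew - rho) * (quad_sp - quad_id) / (2.0 * tau2);
      ++att_rho; if (!burn) ++Att_rho;
      if (std::isfinite(dll) && std::log(unif_rand()) < dll) {
        rho = rnew;
        ++acc_rho; if (!burn) ++Acc_rho;
      }
    }

    // --- adapt proposal scales during burn-in only (target band 0.2-0.6
    //     componentwise, 0.2-0.5 for the single-site sweeps)
    if (burn && iter % 100 == 0) {
      for (int j = 0; j < p; ++j) {
        const double r = att_beta[j] ? (double)acc_beta[j] / att_beta[j] : 0.0;
        if (r < 0.2) s_beta[j] *= 0.7; else if (r > 0.6) s_beta[j] *= 1.4;
        acc_beta[j] = att_beta[j] = 0;
      }
      if (att_phi) {
        const double r = (double)acc_phi / att_phi;
        if (r < 0.2) s_phi *= 0.7; else if (r > 0.6) s_phi *= 1.4;
        acc_phi = att_phi = 0;
      }
      if (att_theta) {
        const double r = (double)acc_theta / att_theta;
        if (r < 0.2) s_theta *= 0.7; else if (r > 0.6) s_theta *= 1.4;
        acc_theta = att_theta = 0;
      }
      if (att_rho) {
        const double r = (double)acc_rho / att_rho;
        if (r < 0.2) s_rho *= 0.7; else if (r > 0.6) s_rho *= 1.4;
        acc_rho = att_rho = 0;
      }
    }

    // --- store retained draws
    if (!burn && (iter - n_burn) % thin == 0) {
      for (int j = 0; j < p; ++j) beta_out(saved, j) = beta[j];
      tau2_out[saved] = tau2;
      sigma2_out[saved] = sigma2;
      rho_out[saved] = rho;
      double dev = 0.0;
      for (int k = 0; k < n; ++k) {
        const double mu = std::exp(eta[k]);
        fitted_out(saved, k) = mu;
        dev += y[k] * eta[k] - mu;
        eta_mean[k] += eta[k];
        phi_mean[k] += phi[k];
        theta_mean[k] += theta[k];
      }
      dev_out[saved] = -2.0 * (dev - lgy);
      ++saved;
    }
  }

  for (int k = 0; k < n; ++k) {
    eta_mean[k] /= n_save; phi_mean[k] /= n_save; theta_mean[k] /= n_save;
  }

  NumericVector acc_rates = NumericVector::create(
      _["beta"] = Att_beta[0] ? (double)std::accumulate(Acc_beta.begin(),
          Acc_beta.end(), 0L) / std::accumulate(Att_beta.begin(),
          Att_beta.end(), 0L) : NA_REAL,
      _["phi"] = Att_phi ? (double)Acc_phi / Att_phi : NA_REAL,
      _["theta"] = Att_theta ? (double)Acc_theta / Att_theta : NA_REAL,
      _["rho"] = Att_rho ? (double)Acc_rho / Att_rho : NA_REAL);

  return List::create(
      _["beta"] = beta_out, _["tau2"] = tau2_out, _["sigma2"] = sigma2_out,
      _["rho"] = rho_out, _["deviance"] = dev_out,
      _["fitted_samples"] = fitted_out,
      _["eta_mean"] = NumericVector(eta_mean.begin(), eta_mean.end()),
      _["phi_mean"] = NumericVector(phi_mean.begin(), phi_mean.end()),
      _["theta_mean"] = NumericVector(theta_mean.begin(), theta_mean.end()),
      _["acceptance"] = acc_rates);
}

// Permutation reference distribution for Moran's I: returns the raw
// cross-product sum_i sum_j w_ij z_i z_j (= 2 * sum over undirected
// edges) for nperm random permutations of z. Scaling to I happens in R.
// [[Rcpp::export]]
NumericVector moran_perm_cpp(NumericVector z, IntegerVector ei,
                             IntegerVector ej, int nperm) {
  const int n = z.size(), m = ei.size();
  std::vector<double> zp(z.begin(), z.end());
  NumericVector out(nperm);
  RNGScope scope;
  for (int b = 0; b < nperm; ++b) {
    // Fisher-Yates shuffle with R's RNG
    for (int i = n - 1; i > 0; --i) {
      const int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(zp[i], zp[j]);
    }
    double s = 0.0;
    for (int e = 0; e < m; ++e) s += zp[ei[e]] * zp[ej[e]];
    out[b] = 2.0 * s;
  }
  return out;
}
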