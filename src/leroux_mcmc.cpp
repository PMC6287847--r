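#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs kernel for the Poisson log-linear model with
// Leroux CAR random effects:
//   y_i ~ Poisson(E_i * exp(x_i' beta + phi_i))
//   phi ~ N(0, tau2 * Q(rho, W)^{-1}),  Q = rho (D - W) + (1 - rho) I
//   beta_j ~ N(0, beta_var), rho ~ U(0,1), tau2 ~ IG(a, b)
//
// Sweep: (i) random-walk block update of beta; (ii) per-area random-walk
// updates of phi using the Poisson likelihood and the Leroux full
// conditional; phi re-centred to mean zero with the mean transferred to the
// intercept (the two are confounded); (iii) conjugate Gibbs draw of tau2;
// (iv) logit-scale random walk for rho with the Jacobian and the exact
// log-determinant  log|Q(rho)| = sum_k log(rho * lambda_k + 1 - rho)
// from the precomputed eigenvalues lambda of D - W.
//
// The adjacency is passed in compressed sparse row form (0-based). Uses R's
// RNG, so runs are reproducible via set.seed() on the R side.

static inline double quad_form(double rho, double qdw, double qss) {
  // phi' Q phi = rho * phi'(D-W)phi + (1-rho) * phi'phi
  return rho * qdw + (1.0 - rho) * qss;
}

static double logdet_Q(double rho, const NumericVector& lambda) {
  double s = 0.0;
  for (int k = 0; k < lambda.size(); ++k)
    s += std::log(rho * lambda[k] + 1.0 - rho);
  return s;
}

// [[Rcpp::export]]
List leroux_mcmc(const NumericVector y, const NumericMatrix X,
                 const NumericVector logE,
                 const IntegerVector adj, const NumericVector adjw,
                 const IntegerVector rowstart, const NumericVector d,
                 const NumericVector lambda,
                 const NumericVector beta_init,
                 const NumericVector beta_prop_sd,
                 const double beta_var,
                 const double tau2_shape, const double tau2_scale,
                 const int n_iter, const int n_burnin, const int thin,
                 double scale_beta, double scale_phi, double scale_rho,
                 const bool adapt,
                 const double rho_init, const double tau2_init,
                 const bool fix_rho) {
  const int n = y.size(), p = X.ncol();
  RNGScope scope;

  NumericVector beta = clone(beta_init);
  NumericVector phi(n, 0.0);
  double rho = rho_init, tau2 = tau2_init;

  // cached linear predictor pieces: eta_i = logE_i + lp_i + phi_i
  NumericVector lp(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * beta[j];
    lp[i] = s;
  }

  const int n_keep = (n_iter - n_burnin) / thin;
  NumericMatrix beta_s(n_keep, p), phi_s(n_keep, n);
  NumericVector rho_s(n_keep), tau2_s(n_keep);

  // acceptance bookkeeping: window counts for adaptation, post-burn-in totals
  int acc_beta_w = 0, acc_rho_w = 0; long acc_phi_w = 0;
  long acc_beta_post = 0, acc_rho_post = 0, acc_phi_post = 0;
  long n_beta_post = 0, n_rho_post = 0, n_phi_post = 0;
  const int batch = 100;

  NumericVector beta_p(p), lp_p(n);
  int keep = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // --- (i) beta block random walk -----------------------------------
    for (int j = 0; j < p; ++j)
      beta_p[j] = beta[j] + scale_beta * beta_prop_sd[j] * R::norm_rand();
    double ld = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += X(i, j) * beta_p[j];
      lp_p[i] = s;
      ld += y[i] * (s - lp[i])
          - std::exp(logE[i] + phi[i]) * (std::exp(s) - std::exp(lp[i]));
    }
    if (R_finite(beta_var)) {
      double pr = 0.0;
      for (int j = 0; j < p; ++j) pr += beta_p[j] * beta_p[j] - beta[j] * beta[j];
      ld -= pr / (2.0 * beta_var);
    }
    if (std::log(R::unif_rand()) < ld) {
      beta = clone(beta_p);
      lp = clone(lp_p);
      ++acc_beta_w;
      if (it > n_burnin) ++acc_beta_post;
    }
    if (it > n_burnin) ++n_beta_post;

    // --- (ii) phi single-site updates ----------------------------------
    for (int i = 0; i < n; ++i) {
      double nbsum = 0.0;
      for (int k = rowstart[i]; k < rowstart[i + 1]; ++k)
        nbsum += adjw[k] * phi[adj[k]];
      const double denom = rho * d[i] + 1.0 - rho;
      const double cmean = rho * nbsum / denom;
      const double cprec = denom / tau2;
      const double phi_n = phi[i] + scale_phi * R::norm_rand();
      const double base = std::exp(logE[i] + lp[i]);
      double ldp = y[i] * (phi_n - phi[i])
                 - base * (std::exp(phi_n) - std::exp(phi[i]))
                 - 0.5 * cprec * ((phi_n - cmean) * (phi_n - cmean)
                                  - (phi[i] - cmean) * (phi[i] - cmean));
      if (std::log(R::unif_rand()) < ldp) {
        phi[i] = phi_n;
        ++acc_phi_w;
        if (it > n_burnin) ++acc_phi_post;
      }
      if (it > n_burnin) ++n_phi_post;
    }
    // re-centre phi; transfer the mean to the intercept so the likelihood
    // is untouched (identifiability constraint)
    double mphi = 0.0;
    for (int i = 0; i < n; ++i) mphi += phi[i];
    mphi /= n;
    for (int i = 0; i < n; ++i) { phi[i] -= mphi; lp[i] += mphi; }
    beta[0] += mphi;

    // --- (iii) tau2 conjugate Gibbs ------------------------------------
    double qdw = 0.0, qss = 0.0;
    for (int i = 0; i < n; ++i) {
      qss += phi[i] * phi[i];
      double nbsum = 0.0;
      for (int k = rowstart[i]; k < rowstart[i + 1]; ++k)
        nbsum += adjw[k] * phi[adj[k]];
      qdw += d[i] * phi[i] * phi[i] - phi[i] * nbsum;
    }
    const double ig_shape = tau2_shape + n / 2.0;
    const double ig_scale = tau2_scale + quad_form(rho, qdw, qss) / 2.0;
    tau2 = 1.0 / R::rgamma(ig_shape, 1.0 / ig_scale);

    // --- (iv) rho logit random walk ------------------------------------
    if (!fix_rho) {
      const double theta = std::log(rho / (1.0 - rho));
      const double theta_n = theta + scale_rho * R::norm_rand();
      const double rho_n = 1.0 / (1.0 + std::exp(-theta_n));
      double ldr = 0.5 * (logdet_Q(rho_n, lambda) - logdet_Q(rho, lambda))
                 - (quad_form(rho_n, qdw, qss) - quad_form(rho, qdw, qss))
                   / (2.0 * tau2)
                 + std::log(rho_n) + std::log(1.0 - rho_n)
                 - std::log(rho) - std::log(1.0 - rho);
      if (std::log(R::unif_rand()) < ldr) {
        rho = rho_n;
        ++acc_rho_w;
        if (it > n_burnin) ++acc_rho_post;
      }
      if (it > n_burnin) ++n_rho_post;
    }

    // --- proposal adaptation (burn-in only) ----------------------------
    if (adapt && it <= n_burnin && it % batch == 0) {
      const double ab = acc_beta_w / (double)batch;
      if (ab > 0.45) scale_beta *= 1.2; else if (ab < 0.25) scale_beta /= 1.2;
      const double ap = acc_phi_w / (double)(batch * n);
      if (ap > 0.55) scale_phi *= 1.2; else if (ap < 0.35) scale_phi /= 1.2;
      if (!fix_rho) {
        const double ar = acc_rho_w / (double)batch;
        if (ar > 0.55) scale_rho *= 1.2; else if (ar < 0.35) scale_rho /= 1.2;
      }
      scale_beta = std::min(std::max(scale_beta, 1e-4), 1e3);
      scale_phi  = std::min(std::max(scale_phi, 1e-4), 1e3);
      scale_rho  = std::min(std::max(scale_rho, 1e-4), 1e3);
      acc_beta_w = 0; acc_phi_w = 0; acc_rho_w = 0;
    }

    // --- retain ---------------------------------------------------------
    if (it > n_burnin && (it - n_burnin) % thin == 0 && keep < n_keep) {
      for (int j = 0; j < p; ++j) beta_s(keep, j) = beta[j];
      for (int i = 0; i < n; ++i) phi_s(keep, i) = phi[i];
      rho_s[keep] = rho;
      tau2_s[keep] = tau2;
      ++keep;
    }
  }

  return List::create(
    _["beta"] = beta_s, _["phi"] = phi_s,
    _["rho"] = rho_s, _["tau2"] = tau2_s,
    _["accept"] = NumericVector::create(
      _["beta"] = n_beta_post ? acc_beta_post / (double)n_beta_post : NA_REAL,
      _["phi"]  = n_phi_post ? acc_phi_post / (double)n_phi_post : NA_REAL,
      _["rho"]  = n_rho_post ? acc_rho_post / (double)n_rho_post : NA_REAL),
    _["scales"] = NumericVector::create(
      _["beta"] = scale_beta, _["phi"] = scale_phi, _["rho"] = scale_rho));
}
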