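// Gibbs samplers for the kernel mixed model and (multilayer) BayesB.
// Both use R's RNG (seed handled on the R side), so runs are exactly
// reproducible given a seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// scaled-inverse-chi-square draw, "sum" parametrisation:
// x = (Ssum + SS) / chisq(df + n); prior mode Ssum/(df+2), mean Ssum/(df-2).
static inline double draw_scinv(double df, double Ssum) {
  return Ssum / R::rchisq(df);
}

// Kernel mixed model: y = X b + sum_k U_k alpha_k + e,
// alpha_ki ~ N(0, d_ki sigma2_k), e ~ N(0, I sigma2_e), flat prior on b.
// U_k, d_k are the eigenvectors/values of kernel K_k, so u_k = U_k alpha_k
// has covariance K_k sigma2_k and the alpha full conditional is diagonal.
// [[Rcpp::export]]
List kernel_mcmc_cpp(const arma::vec& y,
                     const arma::mat& X,
                     const List& Ulist,
                     const List& dlist,
                     const arma::vec& df_u,
                     const arma::vec& Su,
                     double df_e,
                     double Se,
                     const arma::vec& sigma2_u_init,
                     const LogicalVector& fix_u,
                     double sigma2_e_init,
                     bool fix_e,
                     int burnin,
                     int ndraws,
                     int thin,
                     bool store_effects) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int K = Ulist.size();
  const double dtol = 1e-10;

  std::vector<arma::mat> U(K);
  std::vector<arma::vec> d(K);
  for (int k = 0; k < K; ++k) {
    U[k] = as<arma::mat>(Ulist[k]);
    d[k] = as<arma::vec>(dlist[k]);
  }

  // Cholesky of X'X for the flat-prior fixed-effect block draw
  arma::mat XtX = X.t() * X;
  arma::mat Rchol = arma::chol(XtX);  // upper triangular

  arma::vec b(p, arma::fill::zeros);
  std::vector<arma::vec> alpha(K), u(K);
  arma::vec sigma2_u(K);
  for (int k = 0; k < K; ++k) {
    alpha[k] = arma::vec(n, arma::fill::zeros);
    u[k] = arma::vec(n, arma::fill::zeros);
    sigma2_u(k) = sigma2_u_init(k);
  }
  double sigma2_e = sigma2_e_init;

  const int niter = burnin + ndraws;
  const int nstored = ndraws / thin;
  arma::mat chain_var(nstored, K + 1, arma::fill::zeros);
  arma::mat chain_b(nstored, p, arma::fill::zeros);
  std::vector<arma::mat> chain_u(K);
  if (store_effects)
    for (int k = 0; k < K; ++k) chain_u[k] = arma::mat(nstored, n, arma::fill::zeros);

  arma::vec b_mean(p, arma::fill::zeros);
  std::vector<arma::vec> u_mean(K, arma::vec(n, arma::fill::zeros));
  arma::vec s2u_mean(K, arma::fill::zeros);
  double s2e_mean = 0.0;
  int nkept = 0, istore = 0;

  arma::vec usum(n, arma::fill::zeros);  // sum of all u_k

  for (int it = 0; it < niter; ++it) {
    // --- fixed effects (flat prior): b ~ N((X'X)^-1 X'r, sigma2_e (X'X)^-1)
    arma::vec rb = y - usum;
    arma::vec bhat = arma::solve(XtX, X.t() * rb, arma::solve_opts::likely_sympd);
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z(j) = R::norm_rand();
    b = bhat + std::sqrt(sigma2_e) * arma::solve(arma::trimatu(Rchol), z);
    arma::vec xb = X * b;

    // --- kernel random effects
    for (int k = 0; k < K; ++k) {
      arma::vec rk = y - xb - (usum - u[k]);
      arma::vec v = U[k].t() * rk;
      arma::vec& a = alpha[k];
      const arma::vec& dk = d[k];
      for (int i = 0; i < n; ++i) {
        if (dk(i) > dtol) {
          double prec = 1.0 / sigma2_e + 1.0 / (dk(i) * sigma2_u(k));
          double mu = (v(i) / sigma2_e) / prec;
          a(i) = mu + R::norm_rand() / std::sqrt(prec);
        } else {
          a(i) = 0.0;
        }
      }
      arma::vec unew = U[k] * a;
      usum += unew - u[k];
      u[k] = unew;

      if (!fix_u[k]) {
        double SS = 0.0; int npos = 0;
        for (int i = 0; i < n; ++i)
          if (dk(i) > dtol) { SS += a(i) * a(i) / dk(i); ++npos; }
        sigma2_u(k) = draw_scinv(df_u(k) + npos, Su(k) + SS);
      }
    }

    // --- residual variance
    if (!fix_e) {
      arma::vec r = y - xb - usum;
      sigma2_e = draw_scinv(df_e + n, Se + arma::dot(r, r));
    }

    // --- accumulate
    if (it >= burnin) {
      ++nkept;
      b_mean += b;
      for (int k = 0; k < K; ++k) { u_mean[k] += u[k]; s2u_mean(k) += sigma2_u(k); }
      s2e_mean += sigma2_e;
      if ((it - burnin) % thin == 0 && istore < nstored) {
        for (int k = 0; k < K; ++k) chain_var(istore, k) = sigma2_u(k);
        chain_var(istore, K) = sigma2_e;
        chain_b.row(istore) = b.t();
        if (store_effects)
          for (int k = 0; k < K; ++k) chain_u[k].row(istore) = u[k].t();
        ++istore;
      }
    }
  }

  b_mean /= nkept;
  s2u_mean /= nkept;
  s2e_mean /= nkept;
  List u_mean_out(K), chain_u_out(K);
  for (int k = 0; k < K; ++k) {
    u_mean[k] /= nkept;
    u_mean_out[k] = u_mean[k];
    if (store_effects) chain_u_out[k] = chain_u[k];
  }

  return List::create(
    _["b_mean"] = b_mean,
    _["u_mean"] = u_mean_out,
    _["sigma2_u_mean"] = s2u_mean,
    _["sigma2_e_mean"] = s2e_mean,
    _["chain_var"] = chain_var,
    _["chain_b"] = chain_b,
    _["chain_u"] = store_effects ? chain_u_out : List(0),
    _["n_kept"] = nkept);
}

// (Multilayer) BayesB: y = X b + sum_l W_l a_l + e, with per-effect
// point-mass + scaled-t mixture prior on each layer (t implemented
// hierarchically: a_i | s2_i ~ N(0, s2_i), s2_i ~ scInvChi2(df, S)),
// layer-specific inclusion probability pi with optional Beta update.
// Fixed effects get a Gaussian prior with large variance.
// [[Rcpp::export]]
List bayesb_mcmc_cpp(const arma::vec& y,
                     const arma::mat& X,
                     const List& Wlist,
                     const arma::vec& df_a,
                     const arma::vec& Sa,
                     const arma::vec& pi_init,
                     const LogicalVector& pi_update,
                     const arma::vec& beta_shape1,
                     const arma::vec& beta_shape2,
                     double df_e,
                     double Se,
                     double sigma2_e_init,
                     bool fix_e,
                     double var_b,
                     int burnin,
                     int ndraws,
                     int thin) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int L = Wlist.size();
  const double ctol = 1e-12;

  std::vector<arma::mat> W(L);
  std::vector<arma::vec> cW(L), a(L), s2(L);
  std::vector<arma::ivec> delta(L);
  arma::vec pi(L);
  std::vector<int> m(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(Wlist[l]);
    m[l] = W[l].n_cols;
    cW[l] = arma::sum(arma::square(W[l]), 0).t();
    a[l] = arma::vec(m[l], arma::fill::zeros);
    delta[l] = arma::ivec(m[l], arma::fill::zeros);
    s2[l] = arma::vec(m[l]);
    double prior_mean = Sa(l) / std::max(df_a(l) - 2.0, 0.5);
    s2[l].fill(prior_mean);
    pi(l) = pi_init(l);
  }
  arma::vec cX = arma::sum(arma::square(X), 0).t();
  arma::vec b(p, arma::fill::zeros);
  double sigma2_e = sigma2_e_init;

  arma::vec r = y;  // residual given all-zero state

  const int niter = burnin + ndraws;
  const int nstored = ndraws / thin;
  arma::mat chain_misc(nstored, L + 1, arma::fill::zeros);  // pi_l ..., sigma2_e

  arma::vec b_mean(p, arma::fill::zeros);
  std::vector<arma::vec> a_mean(L), pip(L);
  for (int l = 0; l < L; ++l) {
    a_mean[l] = arma::vec(m[l], arma::fill::zeros);
    pip[l] = arma::vec(m[l], arma::fill::zeros);
  }
  arma::vec pi_mean(L, arma::fill::zeros);
  double s2e_mean = 0.0;
  int nkept = 0, istore = 0;

  for (int it = 0; it < niter; ++it) {
    // --- fixed effects, one at a time, Gaussian prior N(0, var_b)
    for (int j = 0; j < p; ++j) {
      if (cX(j) < ctol) { b(j) = 0.0; continue; }
      double rhs = arma::dot(X.col(j), r) + cX(j) * b(j);
      double prec = cX(j) / sigma2_e + 1.0 / var_b;
      double mu = (rhs / sigma2_e) / prec;
      double bnew = mu + R::norm_rand() / std::sqrt(prec);
      r -= X.col(j) * (bnew - b(j));
      b(j) = bnew;
    }

    // --- layer effects
    for (int l = 0; l < L; ++l) {
      int m_in = 0;
      bool always_in = (pi(l) >= 1.0 - 1e-12);  // pi == 1: no exclusion step
      for (int i = 0; i < m[l]; ++i) {
        double cii = cW[l](i);
        if (cii < ctol) { a[l](i) = 0.0; delta[l](i) = 0; continue; }
        double aold = a[l](i);
        double rhs = arma::dot(W[l].col(i), r) + cii * aold;
        double s2i = s2[l](i);
        int dnew;
        if (always_in) {
          dnew = 1;
        } else {
          double v1 = cii * s2i + sigma2_e;
          double logBF = 0.5 * (std::log(sigma2_e) - std::log(v1)) +
            0.5 * rhs * rhs * s2i / (sigma2_e * v1);
          double logodds = std::log(pi(l) / (1.0 - pi(l))) + logBF;
          double pin = 1.0 / (1.0 + std::exp(-logodds));
          dnew = (R::unif_rand() < pin) ? 1 : 0;
        }
        double anew = 0.0;
        if (dnew == 1) {
          double prec = cii / sigma2_e + 1.0 / s2i;
          double mu = (rhs / sigma2_e) / prec;
          anew = mu + R::norm_rand() / std::sqrt(prec);
          ++m_in;
        }
        if (anew != aold) r -= W[l].col(i) * (anew - aold);
        a[l](i) = anew;
        delta[l](i) = dnew;
        // per-effect variance
        if (dnew == 1)
          s2[l](i) = draw_scinv(df_a(l) + 1.0, Sa(l) + anew * anew);
        else
          s2[l](i) = draw_scinv(df_a(l), Sa(l));
      }
      if (pi_update[l]) {
        int m_eff = 0;
        for (int i = 0; i < m[l]; ++i) if (cW[l](i) >= ctol) ++m_eff;
        pi(l) = R::rbeta(beta_shape1(l) + m_in, beta_shape2(l) + (m_eff - m_in));
        if (pi(l) < 1e-8) pi(l) = 1e-8;
        if (pi(l) > 1.0 - 1e-8) pi(l) = 1.0 - 1e-8;
      }
    }

    // --- residual variance
    if (!fix_e)
      sigma2_e = draw_scinv(df_e + n, Se + arma::dot(r, r));

    // --- accumulate
    if (it >= burnin) {
      ++nkept;
      b_mean += b;
      for (int l = 0; l < L; ++l) {
        a_mean[l] += a[l];
        for (int i = 0; i < m[l]; ++i) pip[l](i) += delta[l](i);
      }
      pi_mean += pi;
      s2e_mean += sigma2_e;
      if ((it - burnin) % thin == 0 && istore < nstored) {
        for (int l = 0; l < L; ++l) chain_misc(istore, l) = pi(l);
        chain_misc(istore, L) = sigma2_e;
        ++istore;
      }
    }
  }

  b_mean /= nkept;
  pi_mean /= nkept;
  s2e_mean /= nkept;
  List a_out(L), pip_out(L);
  for (int l = 0; l < L; ++l) {
    a_mean[l] /= nkept;
    pip[l] /= nkept;
    a_out[l] = a_mean[l];
    pip_out[l] = pip[l];
  }

  return List::create(
    _["b_mean"] = b_mean,
    _["a_mean"] = a_out,
    _["pip"] = pip_out,
    _["pi_mean"] = pi_mean,
    _["sigma2_e_mean"] = s2e_mean,
    _["chain_misc"] = chain_misc,
    _["n_kept"] = nkept);
}
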