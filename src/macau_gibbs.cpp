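// Gibbs sampler for Bayesian matrix factorization with side information
// (Macau-style). Model:
//   y_ij | u_i, v_j, tau ~ N(u_i' v_j, 1/tau)            (observed entries)
//   u_i ~ N(mu_u + beta_d' x_i, Lambda_u^-1)             (drug rows)
//   v_j ~ N(mu_v + beta_c' x_j, Lambda_v^-1)             (cell columns)
//   (mu, Lambda) ~ Normal-Wishart(mu0 = 0, b0, W0 = I, nu0 = L)
//   beta ~ MatrixNormal(0, (lambda_beta)^-1 I_F, Lambda^-1)
//   tau ~ Gamma(a0_tau, b0_tau)  (optional; may be held fixed)
//   lambda_beta ~ Gamma(a0_lb, b0_lb) (optional; fixed by default)
// All randomness comes from R's RNG so set.seed() upstream gives full
// determinism. Link matrices are sampled by exact multivariate-normal
// conditionals (feature dimensions here are small; no conjugate-gradient
// noise-injection sampler).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat r_randn(int r, int c) {
  mat out(r, c);
  for (uword j = 0; j < out.n_cols; ++j)
    for (uword i = 0; i < out.n_rows; ++i)
      out(i, j) = R::norm_rand();
  return out;
}

static vec r_randn_vec(int n) {
  vec out(n);
  for (int i = 0; i < n; ++i) out(i) = R::norm_rand();
  return out;
}

// Wishart(W, nu) via Bartlett decomposition; W is the scale matrix.
static mat r_wishart(const mat& W, double nu) {
  const uword p = W.n_rows;
  mat A(p, p, fill::zeros);
  for (uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - (double)i));
    for (uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat Lw = chol(W, "lower");
  mat LA = Lw * A;
  return LA * LA.t();
}

// x ~ N(Q^{-1} b, Q^{-1}) given precision Q and linear term b.
static vec r_mvn_prec(const mat& Q, const vec& b) {
  mat R = chol(Q);                   // upper: Q = R'R
  vec mu = solve(trimatu(R), solve(trimatl(R.t()), b));
  return mu + solve(trimatu(R), r_randn_vec(b.n_elem));
}

struct NWState {
  vec mu;
  mat Lambda;
};

// Sample (mu, Lambda) from the Normal-Wishart posterior given residual rows R.
static NWState sample_normal_wishart(const mat& Rres, double b0, double nu0) {
  const double n = (double)Rres.n_rows;
  const uword L = Rres.n_cols;
  vec rbar = mean(Rres, 0).t();
  mat C = Rres.each_row() - rbar.t();
  mat S = C.t() * C;
  double bN = b0 + n;
  double nuN = nu0 + n;
  vec muN = (n * rbar) / bN;        // prior mean mu0 = 0
  mat W0inv = eye(L, L);
  mat WNinv = W0inv + S + (b0 * n / bN) * (rbar * rbar.t());
  mat WN = inv_sympd(symmatu(WNinv));
  NWState st;
  st.Lambda = r_wishart(symmatu(WN), nuN);
  mat Q = bN * st.Lambda;
  st.mu = r_mvn_prec(symmatu(Q), Q * muN);
  return st;
}

// beta | U, mu, Lambda, lambda ~ MN(M, K^{-1}, Lambda^{-1}),
// K = X'X + lambda I, M = K^{-1} X'(U - 1 mu').
static mat sample_link(const mat& X, const mat& U, const vec& mu,
                       const mat& Lambda, double lambda) {
  const uword F = X.n_cols, L = U.n_cols;
  mat K = X.t() * X + lambda * eye(F, F);
  mat UK = chol(symmatu(K));         // upper
  mat M = solve(trimatu(UK), solve(trimatl(UK.t()), X.t() * (U.each_row() - mu.t())));
  mat UL = chol(symmatu(Lambda));    // upper
  mat Z = r_randn(F, L);
  // row cov K^{-1}: A = UK^{-1}; col cov Lambda^{-1}: C = UL^{-T}, C'C = Lambda^{-1}
  return M + solve(trimatu(UK), Z) * inv(trimatu(UL)).t();
}

// Sample the latent rows of one side given the other side's latents.
static void sample_latents(mat& U, const mat& V, const mat& y, bool transpose_y,
                           const std::vector<uvec>& obs,
                           const std::vector<vec>& yobs,
                           const mat& prior_mean, const mat& Lambda, double tau) {
  const uword n = U.n_rows;
  const uword L = U.n_cols;
  (void)y; (void)transpose_y;
  for (uword i = 0; i < n; ++i) {
    const uvec& oi = obs[i];
    mat Q = Lambda;
    vec b = Lambda * prior_mean.row(i).t();
    if (oi.n_elem > 0) {
      mat Vs = V.rows(oi);
      Q += tau * (Vs.t() * Vs);
      b += tau * (Vs.t() * yobs[i]);
    }
    U.row(i) = r_mvn_prec(symmatu(Q), b).t();
    if ((uword)0 == i % 64) Rcpp::checkUserInterrupt();
    (void)L;
  }
}

// [[Rcpp::export]]
Rcpp::List macau_gibbs_cpp(const arma::mat& y,
                           const arma::mat& xd, const arma::mat& xc,
                           int L, int n_burnin, int n_samples,
                           bool sample_tau, double tau_init,
                           double lambda_beta, bool sample_lambda_beta,
                           bool sample_hyper,
                           const arma::vec& mu_u_fixed,
                           const arma::vec& mu_v_fixed,
                           double prec_fixed,
                           bool keep_samples) {
  const uword n1 = y.n_rows, n2 = y.n_cols;
  const uword Fd = xd.n_cols, Fc = xc.n_cols;
  const double b0 = 2.0, nu0 = (double)L;
  const double a0_tau = 0.5, b0_tau = 0.5;
  const double a0_lb = 1.0, b0_lb = 1.0;

  // Observed-entry index structures per row and per column.
  std::vector<uvec> obs_r(n1), obs_c(n2);
  std::vector<vec> y_r(n1), y_c(n2);
  uword n_obs = 0;
  {
    std::vector<std::vector<uword>> ir(n1), ic(n2);
    for (uword j = 0; j < n2; ++j)
      for (uword i = 0; i < n1; ++i)
        if (std::isfinite(y(i, j))) { ir[i].push_back(j); ic[j].push_back(i); ++n_obs; }
    for (uword i = 0; i < n1; ++i) {
      obs_r[i] = conv_to<uvec>::from(ir[i]);
      y_r[i] = conv_to<vec>::from(std::vector<double>());
      vec tmp(obs_r[i].n_elem);
      for (uword k = 0; k < obs_r[i].n_elem; ++k) tmp(k) = y(i, obs_r[i](k));
      y_r[i] = tmp;
    }
    for (uword j = 0; j < n2; ++j) {
      obs_c[j] = conv_to<uvec>::from(ic[j]);
      vec tmp(obs_c[j].n_elem);
      for (uword k = 0; k < obs_c[j].n_elem; ++k) tmp(k) = y(obs_c[j](k), j);
      y_c[j] = tmp;
    }
  }

  // State; latents start at their prior means plus small jitter.
  mat U = 0.1 * r_randn(n1, L), V = 0.1 * r_randn(n2, L);
  if (!sample_hyper) {
    U.each_row() += mu_u_fixed.t();
    V.each_row() += mu_v_fixed.t();
  }
  mat beta_d(std::max<uword>(Fd, 1), L, fill::zeros);
  mat beta_c(std::max<uword>(Fc, 1), L, fill::zeros);
  vec mu_u = sample_hyper ? vec(L, fill::zeros) : mu_u_fixed;
  vec mu_v = sample_hyper ? vec(L, fill::zeros) : mu_v_fixed;
  mat Lambda_u = (sample_hyper ? 1.0 : prec_fixed) * eye(L, L);
  mat Lambda_v = Lambda_u;
  double tau = tau_init;
  double lambda_d = lambda_beta, lambda_c = lambda_beta;

  // Accumulators.
  mat U_mean(n1, L, fill::zeros), V_mean(n2, L, fill::zeros);
  mat bd_mean(std::max<uword>(Fd, 1), L, fill::zeros);
  mat bc_mean(std::max<uword>(Fc, 1), L, fill::zeros);
  mat inter_mean(std::max<uword>(Fd, 1), std::max<uword>(Fc, 1), fill::zeros);
  mat yhat_mean(n1, n2, fill::zeros);
  vec rmse_trace(n_samples, fill::zeros);
  vec tau_trace(n_samples, fill::zeros);
  cube U_samp, bc_samp;
  mat mu_v_samp;
  if (keep_samples) {
    U_samp.set_size(n1, L, n_samples);
    bc_samp.set_size(std::max<uword>(Fc, 1), L, n_samples);
    mu_v_samp.set_size(L, n_samples);
  }

  const int n_iter = n_burnin + n_samples;
  for (int it = 0; it < n_iter; ++it) {
    // ---- drug side ----
    if (sample_hyper) {
      mat Rres = (Fd > 0) ? mat(U - xd * beta_d) : U;
      NWState st = sample_normal_wishart(Rres, b0, nu0);
      mu_u = st.mu; Lambda_u = st.Lambda;
    }
    if (Fd > 0) {
      beta_d = sample_link(xd, U, mu_u, Lambda_u, lambda_d);
      if (sample_lambda_beta) {
        double shp = a0_lb + 0.5 * (double)(Fd * L);
        double rate = b0_lb + 0.5 * trace(beta_d * Lambda_u * beta_d.t());
        lambda_d = R::rgamma(shp, 1.0 / rate);
      }
    }
    mat pm_u = repmat(mu_u.t(), n1, 1);
    if (Fd > 0) pm_u += xd * beta_d;
    sample_latents(U, V, y, false, obs_r, y_r, pm_u, Lambda_u, tau);

    // ---- cell side ----
    if (sample_hyper) {
      mat Rres = (Fc > 0) ? mat(V - xc * beta_c) : V;
      NWState st = sample_normal_wishart(Rres, b0, nu0);
      mu_v = st.mu; Lambda_v = st.Lambda;
    }
    if (Fc > 0) {
      beta_c = sample_link(xc, V, mu_v, Lambda_v, lambda_c);
      if (sample_lambda_beta) {
        double shp = a0_lb + 0.5 * (double)(Fc * L);
        double rate = b0_lb + 0.5 * trace(beta_c * Lambda_v * beta_c.t());
        lambda_c = R::rgamma(shp, 1.0 / rate);
      }
    }
    mat pm_v = repmat(mu_v.t(), n2, 1);
    if (Fc > 0) pm_v += xc * beta_c;
    sample_latents(V, U, y, true, obs_c, y_c, pm_v, Lambda_v, tau);

    // ---- noise precision ----
    double sse = 0.0;
    for (uword i = 0; i < n1; ++i) {
      if (obs_r[i].n_elem == 0) continue;
      vec pred = V.rows(obs_r[i]) * U.row(i).t();
      vec res = y_r[i] - pred;
      sse += dot(res, res);
    }
    if (!std::isfinite(sse))
      Rcpp::stop("divergent chain: non-finite training residual at iteration %d", it + 1);
    if (sample_tau)
      tau = R::rgamma(a0_tau + 0.5 * (double)n_obs, 1.0 / (b0_tau + 0.5 * sse));

    if (it >= n_burnin) {
      const int s = it - n_burnin;
      U_mean += U; V_mean += V;
      yhat_mean += U * V.t();
      rmse_trace(s) = std::sqrt(sse / (double)n_obs);
      tau_trace(s) = tau;
      if (Fd > 0) bd_mean += beta_d;
      if (Fc > 0) bc_mean += beta_c;
      if (Fd > 0 && Fc > 0) inter_mean += beta_d * beta_c.t();
      if (keep_samples) {
        U_samp.slice(s) = U;
        bc_samp.slice(s) = beta_c;
        mu_v_samp.col(s) = mu_v;
      }
    }
  }

  const double ns = (double)n_samples;
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("U_mean") = U_mean / ns,
      Rcpp::Named("V_mean") = V_mean / ns,
      Rcpp::Named("beta_d_mean") = bd_mean / ns,
      Rcpp::Named("beta_c_mean") = bc_mean / ns,
      Rcpp::Named("interaction_mean") = inter_mean / ns,
      Rcpp::Named("yhat_mean") = yhat_mean / ns,
      Rcpp::Named("rmse_trace") = rmse_trace,
      Rcpp::Named("tau_trace") = tau_trace,
      Rcpp::Named("n_obs") = (double)n_obs);
  if (keep_samples) {
    out["U_samples"] = U_samp;
    out["beta_c_samples"] = bc_samp;
    out["mu_v_samples"] = mu_v_samp;
  }
  return out;
}
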