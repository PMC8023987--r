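// Marginal likelihood of a finite mixture of linear mixed models
// (growth mixture model) on the transformed outcome scale.
//
// Patient i, class g:  y_i | g  ~  N( X_i beta_g + W_i gamma ,
//                                     Z_i D Z_i' + sigma^2 I )
// Marginal loglik:  l = sum_i log sum_g pi_g f_ig.
//
// Unconstrained parameter packing (shared with the R side, see
// pack_gmm_params):
//   theta      (G-1)           multinomial-logit class intercepts, class G ref
//   beta       G blocks of p_fix, class-major
//   gamma      p_cov           common covariate effects
//   cholD      q(q+1)/2        lower-triangular Cholesky of D, column-wise,
//                              diagonal entries on the log scale
//   log_sigma  1

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

struct Pars {
  vec logpi;     // G
  mat beta;      // p_fix x G
  vec gamma;     // p_cov
  mat L;         // q x q lower Cholesky of D
  double sigma2;
};

// Cholesky with escalating diagonal jitter; false only if hopeless.
static bool safe_chol(mat& L, mat V) {
  if (chol(L, V, "lower")) return true;
  double base = std::max(V.diag().max(), 1.0);
  for (double j = 1e-8; j <= 1e-2; j *= 100) {
    mat Vj = V;
    Vj.diag() += j * base;
    if (chol(L, Vj, "lower")) return true;
  }
  return false;
}

static Pars unpack(const vec& par, int G, int p_fix, int p_cov, int q) {
  Pars p;
  int pos = 0;
  vec theta(G, fill::zeros);
  for (int g = 0; g < G - 1; g++) theta(g) = par(pos++);
  vec ex = exp(theta - theta.max());
  p.logpi = log(ex / accu(ex));
  p.beta.set_size(p_fix, G);
  for (int g = 0; g < G; g++)
    for (int j = 0; j < p_fix; j++) p.beta(j, g) = par(pos++);
  p.gamma.set_size(p_cov);
  for (int j = 0; j < p_cov; j++) p.gamma(j) = par(pos++);
  p.L.zeros(q, q);
  for (int c = 0; c < q; c++)
    for (int r = c; r < q; r++) {
      double v = par(pos++);
      p.L(r, c) = (r == c) ? std::exp(v) : v;
    }
  p.sigma2 = std::exp(2.0 * par(pos++));
  return p;
}

// Per-patient, per-class Gaussian log density matrix (n x G).
// [[Rcpp::export]]
arma::mat gmm_logf_cpp(const arma::vec& par, const arma::vec& y,
                       const arma::ivec& offsets, const arma::mat& X,
                       const arma::mat& W, const arma::mat& Z, int G) {
  const int n = offsets.n_elem - 1;
  const int p_fix = X.n_cols, p_cov = W.n_cols, q = Z.n_cols;
  mat logf(n, G);
  if (!par.is_finite()) { logf.fill(-datum::inf); return logf; }
  Pars p = unpack(par, G, p_fix, p_cov, q);
  mat D = p.L * p.L.t();
  if (!std::isfinite(p.sigma2) || !D.is_finite()) {
    logf.fill(-datum::inf);
    return logf;
  }
  for (int i = 0; i < n; i++) {
    const int a = offsets(i), b = offsets(i + 1) - 1;
    const int ni = b - a + 1;
    mat Zi = Z.rows(a, b);
    mat Vi = Zi * D * Zi.t();
    Vi.diag() += p.sigma2;
    mat L;
    if (!safe_chol(L, Vi)) { logf.row(i).fill(-datum::inf); continue; }
    const double logdet = 2.0 * accu(log(L.diag()));
    vec yi = y.subvec(a, b);
    vec wg(ni, fill::zeros);
    if (p_cov > 0) wg = W.rows(a, b) * p.gamma;
    mat Xi = X.rows(a, b);
    for (int g = 0; g < G; g++) {
      vec r = yi - Xi * p.beta.col(g) - wg;
      vec u = solve(trimatl(L), r);
      logf(i, g) = -0.5 * (ni * LOG2PI + logdet + dot(u, u));
    }
  }
  return logf;
}

// Negative marginal log-likelihood (log-sum-exp over classes).
// [[Rcpp::export]]
double gmm_negloglik_cpp(const arma::vec& par, const arma::vec& y,
                         const arma::ivec& offsets, const arma::mat& X,
                         const arma::mat& W, const arma::mat& Z, int G) {
  mat logf = gmm_logf_cpp(par, y, offsets, X, W, Z, G);
  Pars p = unpack(par, G, X.n_cols, W.n_cols, Z.n_cols);
  double ll = 0.0;
  for (uword i = 0; i < logf.n_rows; i++) {
    rowvec a = logf.row(i) + p.logpi.t();
    double m = a.max();
    if (!std::isfinite(m)) return datum::inf;
    ll += m + std::log(accu(exp(a - m)));
  }
  return -ll;
}

// Analytic gradient of the negative log-likelihood.  Uses the mixture
// identity  dl/dpar = sum_i sum_g r_ig d(log pi_g + log f_ig)/dpar  with
// posterior responsibilities r_ig, and  d log f / d(V entries) collected as
// S_i = sum_g r_ig (-V^{-1} + v v')/2 with v = V^{-1} residual.
// [[Rcpp::export]]
arma::vec gmm_negloglik_grad_cpp(const arma::vec& par, const arma::vec& y,
                                 const arma::ivec& offsets, const arma::mat& X,
                                 const arma::mat& W, const arma::mat& Z,
                                 int G) {
  const int n = offsets.n_elem - 1;
  const int p_fix = X.n_cols, p_cov = W.n_cols, q = Z.n_cols;
  if (!par.is_finite()) return vec(par.n_elem, fill::zeros);
  Pars p = unpack(par, G, p_fix, p_cov, q);
  mat D = p.L * p.L.t();
  if (!std::isfinite(p.sigma2) || !D.is_finite())
    return vec(par.n_elem, fill::zeros);
  vec pi = exp(p.logpi);

  vec g_theta(std::max(G - 1, 0), fill::zeros);
  mat g_beta(p_fix, G, fill::zeros);
  vec g_gamma(p_cov, fill::zeros);
  mat A_tot(q, q, fill::zeros);   // sum_i Z_i' S_i Z_i
  double trS_tot = 0.0;

  for (int i = 0; i < n; i++) {
    const int a = offsets(i), b = offsets(i + 1) - 1;
    const int ni = b - a + 1;
    mat Zi = Z.rows(a, b);
    mat Vi = Zi * D * Zi.t();
    Vi.diag() += p.sigma2;
    mat L;
    if (!safe_chol(L, Vi) || L.diag().min() < 1e-10)
      continue;                        // ill-conditioned point: skip patient
    mat Li;
    if (!inv(Li, trimatl(L))) continue;
    mat Vinv = Li.t() * Li;
    const double logdet = 2.0 * accu(log(L.diag()));
    vec yi = y.subvec(a, b);
    vec wg(ni, fill::zeros);
    if (p_cov > 0) wg = W.rows(a, b) * p.gamma;
    mat Xi = X.rows(a, b);

    vec lf(G);
    mat vs(ni, G);            // v_ig = Vinv * residual
    for (int g = 0; g < G; g++) {
      vec r = yi - Xi * p.beta.col(g) - wg;
      vec v = Vinv * r;
      vs.col(g) = v;
      lf(g) = -0.5 * (ni * LOG2PI + logdet + dot(r, v));
    }
    vec lw = lf + p.logpi;
    double m = lw.max();
    vec resp = exp(lw - m);
    resp /= accu(resp);

    for (int g = 0; g < G - 1; g++) g_theta(g) += resp(g) - pi(g);
    mat S(ni, ni, fill::zeros);
    double trVinv = trace(Vinv);
    for (int g = 0; g < G; g++) {
      vec v = vs.col(g);
      g_beta.col(g) += resp(g) * (Xi.t() * v);
      if (p_cov > 0) g_gamma += resp(g) * (W.rows(a, b).t() * v);
      S += resp(g) * 0.5 * (v * v.t());
      trS_tot += resp(g) * 0.5 * (dot(v, v) - trVinv);
    }
    S -= 0.5 * Vinv;   // total responsibility sums to 1
    A_tot += Zi.t() * S * Zi;
  }

  mat gL = 2.0 * A_tot * p.L;
  vec grad(par.n_elem);
  int pos = 0;
  for (int g = 0; g < G - 1; g++) grad(pos++) = -g_theta(g);
  for (int g = 0; g < G; g++)
    for (int j = 0; j < p_fix; j++) grad(pos++) = -g_beta(j, g);
  for (int j = 0; j < p_cov; j++) grad(pos++) = -g_gamma(j);
  for (int c = 0; c < q; c++)
    for (int r = c; r < q; r++)
      grad(pos++) = (r == c) ? -gL(r, c) * p.L(r, c) : -gL(r, c);
  grad(pos++) = -2.0 * p.sigma2 * trS_tot;
  return grad;
}
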