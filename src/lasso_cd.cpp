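// Weighted L1-penalised logistic regression: outer IRLS loop with inner
// cyclic coordinate descent on the working weighted least-squares problem,
// warm-started along a descending lambda grid.  Predictors arrive already
// standardised; the intercept is unpenalised.  Mirrors the objective
//   -(1/W) sum_i w_i [y_i log p_i + (1-y_i) log(1-p_i)] + lambda ||beta||_1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double soft(double x, double lam) {
  // relative tie guard: at lambda_max the score of the entering column
  // equals lambda up to summation-order rounding; treat it as a tie
  const double l = lam * (1.0 + 1e-12);
  if (x > l) return x - lam;
  if (x < -l) return x + lam;
  return 0.0;
}

// [[Rcpp::export]]
Rcpp::List lasso_cd_path_cpp(const arma::mat& Xs, const arma::vec& y,
                             const arma::vec& w, const arma::vec& lambda,
                             double tol, int max_sweeps) {
  const int p = Xs.n_cols;
  const int L = lambda.n_elem;
  const double W = accu(w);
  mat B(p, L, fill::zeros);
  vec b0s(L);
  int n_fit = L;
  vec beta(p, fill::zeros);
  double ybar = dot(w, y) / W;
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  double b0 = std::log(ybar / (1.0 - ybar));
  mat Xs2 = square(Xs);

  auto wdev = [&](const vec& eta) -> double {
    vec pr = clamp(1.0 / (1.0 + exp(-eta)), 1e-10, 1.0 - 1e-10);
    return -2.0 * dot(w, y % log(pr) + (1.0 - y) % log(1.0 - pr)) / W;
  };
  const double null_dev = wdev(vec(y.n_elem, fill::value(b0)));

  for (int l = 0; l < L; l++) {
    const double lam = lambda(l);
    for (int outer = 0; outer < 50; outer++) {
      vec eta = b0 + Xs * beta;
      vec pr = 1.0 / (1.0 + exp(-eta));
      // saturated observations (fitted probability at the clamp) get a
      // floor working weight and zero working residual, so the quadratic
      // approximation stays bounded under quasi-separation
      uvec sat = find(pr < 1e-5 || pr > 1.0 - 1e-5);
      pr = clamp(pr, 1e-5, 1.0 - 1e-5);
      vec pq = pr % (1.0 - pr);
      vec v = w % pq / W;
      vec r = (y - pr) / pq;       // z - eta
      r.elem(sat).zeros();
      vec denom = Xs2.t() * v;
      double sv = accu(v);

      // convergence is monitored on the working objective scale,
      // denom_j * (delta beta_j)^2, which is robust to correlated columns
      auto update_j = [&](int j) -> double {
        const double bj = beta(j);
        const double rho = dot(v % Xs.col(j), r) + denom(j) * bj;
        const double bn = soft(rho, lam) / denom(j);
        if (bn != bj) {
          r -= Xs.col(j) * (bn - bj);
          beta(j) = bn;
          return denom(j) * (bn - bj) * (bn - bj);
        }
        return 0.0;
      };
      auto update_b0 = [&]() -> double {
        const double d0 = dot(v, r) / sv;
        if (d0 != 0.0) { b0 += d0; r -= d0; }
        return sv * d0 * d0;
      };

      // active-set iteration: converge on the current non-zero set
      // (cheap), then one full sweep to admit new coordinates; repeat
      // until the full sweep changes nothing
      int sweeps_used = 0;
      while (sweeps_used < max_sweeps) {
        std::vector<int> active;
        for (int j = 0; j < p; j++) if (beta(j) != 0.0) active.push_back(j);
        while (sweeps_used < max_sweeps) {
          double md_a = update_b0();
          for (int j : active) md_a = std::max(md_a, update_j(j));
          sweeps_used++;
          if (md_a < tol) break;
        }
        double md_f = update_b0();
        for (int j = 0; j < p; j++) md_f = std::max(md_f, update_j(j));
        sweeps_used++;
        if (md_f < tol) break;
      }
      vec eta_new = b0 + Xs * beta;
      if (max(abs(eta_new - eta)) < 1e-9) break;
    }
    B.col(l) = beta;
    b0s(l) = b0;
    // near-saturated fit: smaller penalties only push coefficients toward
    // the separable limit at great cost; freeze the path here (the
    // reference implementation stops its path the same way)
    if (l + 1 < L && wdev(b0 + Xs * beta) < 0.01 * null_dev) {
      for (int l2 = l + 1; l2 < L; l2++) { B.col(l2) = beta; b0s(l2) = b0; }
      n_fit = l + 1;
      break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("beta") = B,
                            Rcpp::Named("b0") = b0s,
                            Rcpp::Named("n_fit") = n_fit);
}
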