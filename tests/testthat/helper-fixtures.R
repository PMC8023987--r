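# Small in-code fixtures shared across tests.

tiny_baseline <- function(ids = c("A1", "B2")) {
  data.frame(patient_id = ids,
             sex = rep(c("F", "M"), length.out = length(ids)),
             ethnicity = "White", diagnosis = "definite_jdm",
             centre = rep(c("A", "Other"), length.out = length(ids)),
             age_at_diagnosis = 7.5, time_to_first_visit = 0.2,
             pga0 = 3, cmas0 = 40, das0 = 3,
             arthritis = 0, abnormal_respiration = 0, calcinosis = 0,
             lipodystrophy = 0, ulceration = 0)
}

tiny_visits <- function(ids = c("A1", "B2")) {
  data.frame(patient_id = rep(ids, each = 3),
             t = rep(c(0.2, 1.0, 2.5), length(ids)),
             pga = c(3, 2, 1.5, 5, 4.5, 4),
             das = c(3, 2, 1, 4, 3, 3),
             gottron = NA_real_, heliotrope = NA_real_,
             vasculitis = NA_real_, erythema = NA_real_)
}

tiny_cohort <- function(ids = c("A1", "B2"))
  cohort(tiny_baseline(ids), tiny_visits(ids))

# A small simulated cohort (fast, deterministic) for model-level tests.
small_sim <- function(n = 120, seed = 42, outcome = "pga") {
  simulate_cohort(default_sim_spec(outcome, n), seed = seed)
}

# Gauss-Hermite log marginal likelihood for the mixture of linear mixed
# models, integrating the bivariate random effect on a tensor grid.
# Independent of the package's Cholesky-based likelihood.
gh_loglik <- function(params, y, X, W, Z, patient, n_nodes = 40) {
  gh <- pracma::gaussHermite(n_nodes)
  # b = sqrt(2) * L %*% u, u ~ product of standard GH nodes
  L <- t(chol(params$D))
  nodes <- as.matrix(expand.grid(gh$x, gh$x))
  wts <- as.vector(outer(gh$w, gh$w)) / pi   # normalising 1/pi for 2D
  b_draws <- sqrt(2) * nodes %*% t(L)        # n_nodes^2 x 2
  pi_g <- params$pi
  G <- length(pi_g)
  ll <- 0
  for (i in unique(patient)) {
    rows <- patient == i
    yi <- y[rows]; Xi <- X[rows, , drop = FALSE]
    Zi <- Z[rows, , drop = FALSE]
    wg <- if (ncol(W)) as.vector(W[rows, , drop = FALSE] %*% params$gamma)
          else rep(0, sum(rows))
    f_i <- 0
    for (g in seq_len(G)) {
      mu <- as.vector(Xi %*% params$beta[g, ]) + wg
      dens_g <- vapply(seq_len(nrow(b_draws)), function(k) {
        m <- mu + as.vector(Zi %*% b_draws[k, ])
        prod(dnorm(yi, m, params$sigma))
      }, numeric(1))
      f_i <- f_i + pi_g[g] * sum(wts * dens_g)
    }
    ll <- ll + log(f_i)
  }
  ll
}
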