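# --- likelihood ------------------------------------------------------------

test_that("marginal likelihood reduces to the normal density in the trivial case", {
  b <- tiny_baseline("A1")
  v <- tiny_visits("A1")[1, ]
  v$pga <- 4
  co <- cohort(b, v)
  sp <- gmm_spec(1, outcome = "pga", time_degree = 1,
                 transform = "identity", random_effects = "intercept",
                 covariates = character(0))
  # G=1, one visit, D=0, sigma=1, mean = y  ->  log phi(0) = -log(2*pi)/2
  params <- list(theta = numeric(0), beta = matrix(c(4, 0), 1),
                 gamma = numeric(0), D = matrix(0, 1, 1), sigma = 1)
  expect_equal(marginal_loglik(params, co, sp), -0.5 * log(2 * pi),
               tolerance = 1e-8)
})

test_that("a degenerate mixture equals the single-class likelihood", {
  co <- truncate_followup(small_sim(40)$cohort, 10)
  p1 <- list(theta = numeric(0),
             beta = matrix(c(1.8, -0.3, 0.03, -0.001), 1), gamma = 0.1,
             D = matrix(c(0.09, 0, 0, 0.001), 2), sigma = 0.3)
  ll1 <- marginal_loglik(p1, co, gmm_spec(1, outcome = "pga"))
  p2 <- list(theta = 40,    # pi = (1, ~4e-18)
             beta = rbind(p1$beta, c(9, 9, 9, 9)), gamma = 0.1,
             D = p1$D, sigma = 0.3)
  ll2 <- marginal_loglik(p2, co, gmm_spec(2, outcome = "pga"))
  expect_equal(ll2, ll1, tolerance = 1e-10)
})

test_that("likelihood matches Gauss-Hermite integration on a small instance", {
  skip_if_not_installed("pracma")
  sim <- small_sim(3, seed = 8)
  co <- truncate_followup(sim$cohort, 10)
  co$visits$pga[is.na(co$visits$pga)] <- 2   # all visits usable
  co <- cohort(co$baseline, co$visits)
  sp <- gmm_spec(2, outcome = "pga")
  d <- trajmix:::gmm_data(co, sp)
  params <- list(theta = log(0.89 / 0.11),
                 beta = rbind(c(1.8, -0.28, 0.026, -0.0007),
                              c(2.2, -0.15, 0.030, -0.0015)),
                 gamma = 0.1,
                 D = matrix(c(0.09, -0.002, -0.002, 0.0009), 2, 2),
                 sigma = 0.28)
  params$pi <- c(0.89, 0.11)
  ll <- marginal_loglik(params, co, sp)
  patient <- rep(seq_along(d$ids), diff(d$offsets))
  ll_gh <- gh_loglik(params, d$y, d$X, d$W, d$Z, patient, n_nodes = 80)
  expect_lt(abs(ll - ll_gh), 1e-6 * abs(ll_gh))
})

test_that("analytic gradient agrees with central differences", {
  co <- truncate_followup(small_sim(30)$cohort, 10)
  sp <- gmm_spec(2, outcome = "pga")
  d <- trajmix:::gmm_data(co, sp)
  params <- list(theta = 1.5,
                 beta = rbind(c(1.7, -0.3, 0.03, -0.001),
                              c(2.1, -0.1, 0.02, -0.001)),
                 gamma = 0.08, D = matrix(c(0.1, -0.01, -0.01, 0.002), 2),
                 sigma = 0.3)
  par <- trajmix:::pack_gmm_params(params, 2, 2)
  g <- as.vector(trajmix:::gmm_negloglik_grad_cpp(par, d$y, d$offsets, d$X, d$W, d$Z, 2L))
  num <- vapply(seq_along(par), function(j) {
    e <- numeric(length(par)); e[j] <- 1e-6
    (trajmix:::gmm_negloglik_cpp(par + e, d$y, d$offsets, d$X, d$W, d$Z, 2L) -
       trajmix:::gmm_negloglik_cpp(par - e, d$y, d$offsets, d$X, d$W, d$Z, 2L)) / 2e-6
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-4)
})

test_that("label permutation leaves the likelihood unchanged", {
  co <- truncate_followup(small_sim(30)$cohort, 10)
  sp <- gmm_spec(2, outcome = "pga")
  params <- list(theta = 1.2,
                 beta = rbind(c(1.8, -0.3, 0.03, -0.001),
                              c(2.2, -0.1, 0.02, -0.001)),
                 gamma = 0.1, D = matrix(c(0.09, 0, 0, 0.001), 2),
                 sigma = 0.3)
  swapped <- params
  swapped$theta <- -1.2
  swapped$beta <- params$beta[2:1, ]
  expect_equal(marginal_loglik(params, co, sp),
               marginal_loglik(swapped, co, sp), tolerance = 1e-10)
})

# --- posteriors, entropy, summaries ----------------------------------------

test_that("posterior probabilities follow Bayes rule", {
  co <- truncate_followup(small_sim(25)$cohort, 10)
  sp <- gmm_spec(2, outcome = "pga")
  base <- list(theta = qlogis(0.7) - qlogis(0.3),
               beta = rbind(c(1.8, -0.3, 0.03, -0.001),
                            c(2.2, -0.1, 0.02, -0.001)),
               gamma = 0.1, D = matrix(c(0.09, 0, 0, 0.001), 2),
               sigma = 0.3)
  base$theta <- log(0.7 / 0.3)
  # identical class parameters: posterior = prior for every patient
  same <- base
  same$beta <- rbind(base$beta[1, ], base$beta[1, ])
  post <- posterior_probs(same, co, sp)
  expect_equal(unname(post[, 1]), rep(0.7, nrow(post)), tolerance = 1e-10)
  # general case vs an independently coded density computation
  post <- posterior_probs(base, co, sp)
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-10)
  d <- trajmix:::gmm_data(co, sp)
  pi_g <- c(0.7, 0.3)
  for (i in c(1, 7, 20)) {
    rows <- (d$offsets[i] + 1):d$offsets[i + 1]
    yi <- d$y[rows]
    f <- vapply(1:2, function(g) {
      mu <- as.vector(d$X[rows, , drop = FALSE] %*% base$beta[g, ]) +
        as.vector(d$W[rows, , drop = FALSE] %*% base$gamma)
      Zi <- d$Z[rows, , drop = FALSE]
      V <- Zi %*% base$D %*% t(Zi) + base$sigma^2 * diag(length(rows))
      exp(-0.5 * (length(yi) * log(2 * pi) + determinant(V)$modulus +
                    t(yi - mu) %*% solve(V) %*% (yi - mu)))
    }, numeric(1))
    expect_equal(unname(post[i, ]), pi_g * f / sum(pi_g * f),
                 tolerance = 1e-8)
  }
})

test_that("posterior with density ratio 3:1 at equal priors gives 0.75/0.25", {
  logf <- matrix(c(log(3), log(1)), 1)
  p <- trajmix:::posterior_from_logf(logf, log(c(0.5, 0.5)))
  expect_equal(as.vector(p), c(0.75, 0.25), tolerance = 1e-12)
})

test_that("relative entropy has the documented extremes and hand value", {
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(entropy(onehot), 1)
  expect_equal(entropy(matrix(1 / 4, 6, 4)), 0, tolerance = 1e-12)
  rows <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  # by hand: H1 = 0.3251, H2 = 0.6730, E = 1 - (H1+H2)/(2 ln 2) = 0.28002
  expect_equal(entropy(rows), 0.28002, tolerance = 1e-4)
  expect_error(entropy(matrix(1, 5, 1)), "single class")
})

test_that("mean posterior by modal class handles empty classes", {
  post <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.3, 0.7))
  expect_equal(mean_posterior_by_class(post), c(0.85, 0.7))
  expect_equal(mean_posterior_by_class(diag(2)), c(1, 1))
  post2 <- rbind(c(0.9, 0.1), c(0.8, 0.2))
  expect_equal(mean_posterior_by_class(post2), c(0.85, NA_real_))
})

# --- fitting ---------------------------------------------------------------

test_that("single-class fit matches an independent linear mixed model", {
  skip_if_not_installed("lme4")
  sim <- small_sim(150, seed = 13)
  co <- truncate_followup(sim$cohort, 10)
  fit <- fit_gmm(co, gmm_spec(1, outcome = "pga"), n_starts = 5, seed = 1)
  v <- co$visits[!is.na(co$visits$pga), ]
  b <- co$baseline[match(v$patient_id, co$baseline$patient_id), ]
  df <- data.frame(y = sqrt(v$pga), t = v$t, id = v$patient_id,
                   centreA = as.numeric(b$centre == "A"))
  or <- lme4::lmer(y ~ t + I(t^2) + I(t^3) + centreA + (1 + t | id), df,
                   REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(or)), tolerance = 1e-6)
  expect_equal(unname(c(fit$params$beta[1, ], fit$params$gamma)),
               unname(lme4::fixef(or)), tolerance = 1e-4)
  expect_equal(unname(fit$params$sigma), stats::sigma(or), tolerance = 1e-4)
  D_or <- as.matrix(Matrix::bdiag(lme4::VarCorr(or)))
  # D entries span orders of magnitude; compare relative to the matrix scale
  expect_lt(max(abs(fit$params$D - D_or)) / norm(D_or, "F"), 1e-3)
})

test_that("iteration cap reports non-convergence without raising", {
  co <- truncate_followup(small_sim(60)$cohort, 10)
  fit <- fit_gmm(co, gmm_spec(2, outcome = "pga"), n_starts = 2, seed = 1,
                 max_iter = 1)
  expect_false(fit$convergence$converged)
  expect_true(is.finite(fit$loglik))
})

test_that("fitted classes are ordered by descending probability and BIC identity holds", {
  co <- truncate_followup(small_sim(120, seed = 3)$cohort, 10)
  fit <- fit_gmm(co, gmm_spec(2, outcome = "pga"), n_starts = 6, seed = 2)
  expect_true(all(diff(fit$params$pi) <= 0))
  expect_equal(fit$bic, -2 * fit$loglik + fit$k * log(fit$n_patients))
  expect_equal(fit$k, 1 + 2 * 4 + 1 + 3 + 1)
  expect_equal(rowSums(fit$posterior), rep(1, fit$n_patients),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$modal_class, unname(max.col(fit$posterior, "first")))
})

test_that("error is raised when patients are fewer than parameters", {
  co <- tiny_cohort()
  expect_error(fit_gmm(co, gmm_spec(2, outcome = "pga")), "fewer patients")
})

# --- predicted trajectories ------------------------------------------------

test_that("predicted curves back-transform the class mean", {
  co <- truncate_followup(small_sim(120, seed = 3)$cohort, 10)
  fit <- fit_gmm(co, gmm_spec(2, outcome = "pga"), n_starts = 6, seed = 2)
  grid <- c(0, 1, 2, 5)
  pred <- predict_trajectory(fit, 1, grid, centre = 0, ci = "delta")
  eta <- as.vector(cbind(1, grid, grid^2, grid^3) %*% fit$params$beta[1, ])
  expect_equal(pred$median, pmax(eta, 0)^2, tolerance = 1e-10)
  expect_false(attr(pred, "extrapolated"))
  expect_true(attr(predict_trajectory(fit, 1, c(5, 12), ci = "delta"),
                   "extrapolated"))
  # identity-transform fit: curve equals X beta exactly
  fit_id <- fit_gmm(co, gmm_spec(1, outcome = "pga", transform = "identity",
                                 covariates = character(0)),
                    n_starts = 3, seed = 1)
  pr <- predict_trajectory(fit_id, 1, grid, ci = "delta")
  expect_equal(pr$median,
               pmax(as.vector(cbind(1, grid, grid^2, grid^3) %*%
                                fit_id$params$beta[1, ]), 0),
               tolerance = 1e-10)
  # bootstrap band contains the point estimate
  pb <- predict_trajectory(fit, 1, grid, ci = "bootstrap", B = 200, seed = 1)
  expect_true(all(pb$lower <= pb$median + 1e-8 & pb$median <= pb$upper + 1e-8))
})
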