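#' Specify a growth mixture model
#'
#' A growth mixture model is a finite mixture of linear mixed models: each
#' latent class g has its own polynomial-in-time mean trajectory for the
#' transformed outcome, patients deviate from their class mean through a
#' random intercept (and optionally slope), and residuals are Gaussian.
#' Baseline covariates listed in `covariates` enter the mean with effects
#' common to all classes (the default, `"centre"`, keeps the recruiting
#' centre in the model so outcome missingness associated with centre is
#' ignorable under MAR).
#'
#' @param n_classes number of latent classes G (>= 1).
#' @param outcome visit column to model, `"pga"` or `"das"`.
#' @param time_degree degree of the time polynomial (1, 2 or 3; default 3).
#' @param transform outcome transform, `"sqrt"` (default) or `"identity"`.
#' @param random_effects `"intercept+slope"` (default) or `"intercept"`.
#' @param covariates character vector of baseline columns with common
#'   effects; `"centre"` expands to an indicator of Centre A. Use
#'   `character(0)` for none.
#' @return An object of class `"gmm_spec"`.
#' @export
gmm_spec <- function(n_classes, outcome = c("pga", "das"), time_degree = 3,
                     transform = c("sqrt", "identity"),
                     random_effects = c("intercept+slope", "intercept"),
                     covariates = "centre") {
  outcome <- match.arg(outcome)
  transform <- match.arg(transform)
  random_effects <- match.arg(random_effects)
  stopifnot(n_classes >= 1, time_degree %in% 1:3)
  structure(list(n_classes = as.integer(n_classes), outcome = outcome,
                 time_degree = as.integer(time_degree), transform = transform,
                 random_effects = random_effects, covariates = covariates),
            class = "gmm_spec")
}

# Assemble the per-patient design for the likelihood: transformed outcome,
# visit offsets, time polynomial X, covariate matrix W, random-effects Z.
# Visits with a missing outcome are dropped (ignorable under MAR given the
# covariates in the mean model); patients left with no usable outcome are
# excluded and counted.
gmm_data <- function(x, spec) {
  stopifnot(inherits(x, "cohort"), inherits(spec, "gmm_spec"))
  v <- x$visits
  ok <- !is.na(v[[spec$outcome]])
  v <- v[ok, , drop = FALSE]
  ids <- unique(v$patient_id)
  n_excluded <- nrow(x$baseline) - length(ids)
  if (!length(ids)) stop("no usable outcome observations")
  v <- v[order(match(v$patient_id, ids), v$t), , drop = FALSE]
  y <- transform_outcome(v[[spec$outcome]], spec$transform)
  counts <- as.integer(table(factor(v$patient_id, levels = ids)))
  offsets <- c(0L, cumsum(counts))
  X <- stats::poly(v$t, degree = spec$time_degree, raw = TRUE, simple = TRUE)
  X <- cbind(1, X)
  colnames(X) <- c("(Intercept)", paste0("t", seq_len(spec$time_degree)))
  W <- matrix(0, nrow(v), 0)
  if (length(spec$covariates)) {
    b <- x$baseline[match(v$patient_id, x$baseline$patient_id), , drop = FALSE]
    cols <- list()
    for (cv in spec$covariates) {
      if (cv == "centre") {
        cols[["centreA"]] <- as.numeric(b$centre == "A")
      } else if (is.numeric(b[[cv]])) {
        cols[[cv]] <- b[[cv]]
      } else {
        mm <- model.matrix(~ f, data.frame(f = factor(b[[cv]])))[, -1,
                                                                 drop = FALSE]
        for (j in seq_len(ncol(mm))) cols[[paste0(cv, colnames(mm)[j])]] <-
            mm[, j]
      }
    }
    W <- do.call(cbind, cols)
    if (anyNA(W)) stop("missing values in GMM covariates: ",
                       paste(spec$covariates, collapse = ", "))
  }
  q <- if (spec$random_effects == "intercept") 1L else 2L
  Z <- cbind(1, if (q == 2) v$t)
  list(y = y, offsets = offsets, X = X, W = W, Z = Z, ids = ids,
       t = v$t, n_excluded = n_excluded, original_y = v[[spec$outcome]])
}

# --- parameter packing (mirrors src/gmm_loglik.cpp) -------------------------

pack_gmm_params <- function(params, G, q) {
  L <- t(chol(params$D + diag(1e-12, q)))
  chol_flat <- numeric(0)
  for (cc in seq_len(q))
    for (rr in cc:q)
      chol_flat <- c(chol_flat,
                     if (rr == cc) log(max(L[rr, cc], 1e-8)) else L[rr, cc])
  c(params$theta, as.vector(t(params$beta)), params$gamma, chol_flat,
    log(params$sigma))
}

unpack_gmm_params <- function(par, G, p_fix, p_cov, q) {
  pos <- 0
  theta <- if (G > 1) par[seq_len(G - 1)] else numeric(0)
  pos <- G - 1
  pi <- exp(c(theta, 0)); pi <- pi / sum(pi)
  beta <- matrix(par[pos + seq_len(G * p_fix)], nrow = G, byrow = TRUE)
  pos <- pos + G * p_fix
  gamma <- if (p_cov > 0) par[pos + seq_len(p_cov)] else numeric(0)
  pos <- pos + p_cov
  L <- matrix(0, q, q)
  for (cc in seq_len(q))
    for (rr in cc:q) {
      pos <- pos + 1
      L[rr, cc] <- if (rr == cc) exp(par[pos]) else par[pos]
    }
  sigma <- exp(par[pos + 1])
  list(theta = theta, pi = pi, beta = beta, gamma = gamma, D = L %*% t(L),
       chol_D = L, sigma = sigma)
}

n_gmm_params <- function(G, p_fix, p_cov, q)
  (G - 1) + G * p_fix + p_cov + q * (q + 1) / 2 + 1

#' Marginal log-likelihood of a growth mixture model
#'
#' Sums, over patients, the log of the class-probability-weighted
#' multivariate normal density of the patient's transformed outcome vector,
#' with covariance `Z D Z' + sigma^2 I` from the random effects and the
#' residual. Computed in the log domain via log-sum-exp; Cholesky failures
#' are retried with a 1e-8 diagonal jitter.
#'
#' @param params parameter list with `theta` (G-1 multinomial-logit class
#'   intercepts), `beta` (G x (degree+1) class trajectory coefficients),
#'   `gamma` (covariate effects), `D` (random-effects covariance), `sigma`
#'   (residual SD).
#' @param x a [cohort()].
#' @param spec a [gmm_spec()].
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(params, x, spec) {
  d <- gmm_data(x, spec)
  G <- spec$n_classes
  q <- ncol(d$Z)
  par <- pack_gmm_params(params, G, q)
  -gmm_negloglik_cpp(par, d$y, d$offsets, d$X, d$W, d$Z, G)
}

#' Posterior class-membership probabilities
#'
#' Bayes rule over the latent class: `p_ig = pi_g f_ig / sum_h pi_h f_ih`
#' with `f_ig` the patient's class-conditional marginal density.
#'
#' @inheritParams marginal_loglik
#' @return `n_patients x G` matrix with rows summing to 1, patient ids as
#'   row names.
#' @export
posterior_probs <- function(params, x, spec) {
  d <- gmm_data(x, spec)
  G <- spec$n_classes
  par <- pack_gmm_params(params, G, ncol(d$Z))
  logf <- gmm_logf_cpp(par, d$y, d$offsets, d$X, d$W, d$Z, G)
  post <- posterior_from_logf(logf, log(unpack_like(params, G)))
  rownames(post) <- d$ids
  post
}

unpack_like <- function(params, G) {
  if (!is.null(params$pi)) return(params$pi)
  pi <- exp(c(params$theta, 0))
  pi / sum(pi)
}

posterior_from_logf <- function(logf, logpi) {
  lw <- sweep(logf, 2, logpi, "+")
  m <- apply(lw, 1, max)
  if (any(!is.finite(m)))
    stop("zero density in every class for patient row(s) ",
         paste(which(!is.finite(m)), collapse = ", "))
  p <- exp(lw - m)
  p / rowSums(p)
}

#' Relative entropy of a posterior classification
#'
#' `E = 1 - sum_i sum_g (-p_ig log p_ig) / (n log G)`: 1 when every patient
#' is assigned to one class with certainty, 0 when the posterior is uniform
#' and carries no information. Degenerate (one-hot) rows contribute 0 to the
#' numerator.
#'
#' @param posterior `n x G` posterior probability matrix, `G >= 2`.
#' @return Entropy in `[0, 1]`.
#' @export
entropy <- function(posterior) {
  posterior <- as.matrix(posterior)
  G <- ncol(posterior)
  if (G < 2) stop("entropy is undefined for a single class")
  pl <- posterior * log(posterior)
  pl[posterior == 0] <- 0
  1 - sum(-pl) / (nrow(posterior) * log(G))
}

#' Mean posterior probability by modal class
#'
#' For each class g, the mean of `p_ig` over patients whose modal class is
#' g — a per-class summary of classification quality (near 1 when members
#' are assigned with confidence). Classes with no members are `NA`.
#'
#' @param posterior posterior probability matrix.
#' @param modal_class integer vector of per-patient modal classes; computed
#'   from `posterior` if omitted.
#' @return Length-G numeric vector.
#' @export
mean_posterior_by_class <- function(posterior, modal_class = NULL) {
  posterior <- as.matrix(posterior)
  if (is.null(modal_class)) modal_class <- max.col(posterior, "first")
  vapply(seq_len(ncol(posterior)), function(g) {
    in_g <- modal_class == g
    if (!any(in_g)) NA_real_ else mean(posterior[in_g, g])
  }, numeric(1))
}

# --- starting values --------------------------------------------------------

# Per-patient OLS (intercept, slope) summaries; patients with one visit get
# slope 0.
patient_ols_summaries <- function(d) {
  n <- length(d$ids)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    rows <- (d$offsets[i] + 1):d$offsets[i + 1]
    ti <- d$t[rows]; yi <- d$y[rows]
    if (length(rows) >= 2 && var(ti) > 0) {
      cf <- coef(lm(yi ~ ti))
      out[i, ] <- cf
    } else out[i, ] <- c(mean(yi), 0)
  }
  out[!is.finite(out)] <- 0
  out
}

single_class_start <- function(d) {
  XW <- cbind(d$X, d$W)
  cf <- qr.coef(qr(XW), d$y)
  cf[is.na(cf)] <- 0
  res <- d$y - XW %*% cf
  s <- max(sd(res), 1e-3)
  p_fix <- ncol(d$X); q <- ncol(d$Z)
  D0 <- diag(q) * c(0.5 * s^2, if (q == 2) 0.01 * s^2)
  list(theta = numeric(0), beta = matrix(cf[seq_len(p_fix)], 1),
       gamma = cf[-seq_len(p_fix)], D = D0, sigma = s * 0.8)
}

# Starts for G >= 2: a k-means start on per-patient (intercept, slope)
# summaries, then perturbations of the single-class fit.
multi_class_starts <- function(d, G, fit1_params, n_starts, seed) {
  set.seed(seed)
  starts <- list()
  p_fix <- ncol(d$X)
  ols <- patient_ols_summaries(d)
  km <- tryCatch(stats::kmeans(scale(ols), centers = G, nstart = 5),
                 error = function(e) NULL)
  base_beta <- fit1_params$beta[1, ]
  if (!is.null(km)) {
    beta <- matrix(rep(base_beta, each = G), G)
    prop <- tabulate(km$cluster, G) / length(km$cluster)
    prop <- pmax(prop, 0.02); prop <- prop / sum(prop)
    for (g in seq_len(G)) {
      in_g <- km$cluster == g
      if (sum(in_g) >= 3) {
        beta[g, 1] <- base_beta[1] + (mean(ols[in_g, 1]) - mean(ols[, 1]))
        if (p_fix >= 2)
          beta[g, 2] <- base_beta[2] + (mean(ols[in_g, 2]) - mean(ols[, 2]))
      }
    }
    starts[[1]] <- list(theta = log(prop[-G] / prop[G]), beta = beta,
                        gamma = fit1_params$gamma, D = fit1_params$D,
                        sigma = fit1_params$sigma)
  }
  while (length(starts) < n_starts) {
    beta <- matrix(rep(base_beta, each = G), G)
    beta[, 1] <- beta[, 1] + rnorm(G, 0, max(0.5 * sd(d$y), 0.1))
    if (p_fix >= 2) beta[, 2] <- beta[, 2] * runif(G, 0.5, 1.5)
    starts[[length(starts) + 1]] <-
      list(theta = rnorm(G - 1, 0, 0.5), beta = beta,
           gamma = fit1_params$gamma, D = fit1_params$D,
           sigma = fit1_params$sigma * runif(1, 0.8, 1.2))
  }
  starts
}

# Reorder classes by descending class probability (canonical labelling).
canonicalize_params <- function(params, G) {
  ord <- order(params$pi, decreasing = TRUE)
  pi <- params$pi[ord]
  list(theta = log(pi[-G] / pi[G]), pi = pi,
       beta = params$beta[ord, , drop = FALSE], gamma = params$gamma,
       D = params$D, chol_D = params$chol_D, sigma = params$sigma, order = ord)
}

#' Fit a growth mixture model by maximum likelihood
#'
#' Maximises the marginal mixture likelihood directly by quasi-Newton (BFGS
#' with the analytic gradient) over the unconstrained parameterisation
#' (multinomial-logit class intercepts, Cholesky factor of the
#' random-effects covariance with log diagonal, log residual SD). Mixture
#' likelihoods are multimodal, so the optimiser is run from `n_starts`
#' initialisations: a k-means start built from per-patient OLS
#' intercept/slope summaries plus random perturbations of a single-class
#' fit. The best converged solution is returned with classes relabelled in
#' order of descending class probability.
#'
#' @param x a [cohort()].
#' @param spec a [gmm_spec()].
#' @param n_starts number of starts for `G >= 2` (default 30).
#' @param seed RNG seed for start generation.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter BFGS iteration cap per start.
#' @return An object of class `"gmm_fit"`: parameter estimates, `loglik`,
#'   `k` (free-parameter count), `bic` (with patients as the sample size),
#'   `entropy`, `posterior`, `modal_class`, `mean_posterior_by_class`,
#'   `convergence` diagnostics, and the asymptotic covariance `vcov` of the
#'   packed parameters for trajectory confidence bands.
#' @export
fit_gmm <- function(x, spec, n_starts = 30, seed = 1L, tol = 1e-10,
                    max_iter = 500L) {
  d <- gmm_data(x, spec)
  G <- spec$n_classes
  q <- ncol(d$Z); p_fix <- ncol(d$X); p_cov <- ncol(d$W)
  n <- length(d$ids)
  k <- n_gmm_params(G, p_fix, p_cov, q)
  if (n <= k) stop("fewer patients (", n, ") than free parameters (", k, ")")

  # clamp so BFGS line searches survive excursions into degenerate regions;
  # far outside the plausible region (|par| > 100 on log/logit scales) the
  # likelihood is replaced by a sloped penalty so the line search backs off
  # without ever evaluating an overflowing covariance
  oob <- function(par) any(!is.finite(par)) || max(abs(par)) > 100
  fn <- function(par) {
    if (oob(par)) return(1e10 + sum(pmax(abs(par) - 100, 0)))
    v <- gmm_negloglik_cpp(par, d$y, d$offsets, d$X, d$W, d$Z, G)
    if (!is.finite(v)) 1e10 else v
  }
  gr <- function(par) {
    if (oob(par)) return(sign(par) * (abs(par) > 100))
    g <- gmm_negloglik_grad_cpp(par, d$y, d$offsets, d$X, d$W, d$Z, G)
    g[!is.finite(g)] <- 0
    pmin(pmax(g, -1e8), 1e8)
  }

  grad_tol <- 1e-3 * n
  run_start <- function(params0) {
    par0 <- pack_gmm_params(params0, G, q)
    if (!is.finite(fn(par0))) return(NULL)
    opt <- tryCatch(
      optim(par0, fn, gr, method = "BFGS",
            control = list(maxit = max_iter, reltol = tol)),
      error = function(e) NULL)
    # BFGS can satisfy its relative-f tolerance with the gradient still
    # large; restarting from the optimum resets the Hessian approximation
    # and polishes the solution.  A start counts as stationary when a
    # restart can no longer improve the objective.
    if (!is.null(opt)) opt$stationary <- FALSE
    for (polish in 1:3) {
      if (is.null(opt) || opt$convergence != 0) break
      if (max(abs(gr(opt$par))) <= grad_tol) { opt$stationary <- TRUE; break }
      nxt <- tryCatch(
        optim(opt$par, fn, gr, method = "BFGS",
              control = list(maxit = max_iter, reltol = tol)),
        error = function(e) NULL)
      if (is.null(nxt) || nxt$value > opt$value - 1e-8) {
        opt$stationary <- TRUE
        break
      }
      nxt$stationary <- polish == 3
      opt <- nxt
    }
    opt
  }

  fit1_params <- single_class_start(d)
  if (G == 1) {
    starts <- list(fit1_params)
    for (j in seq_len(max(n_starts %/% 10, 2))) {
      s <- fit1_params
      s$beta <- s$beta + rnorm(length(s$beta), 0, 0.2)
      s$sigma <- s$sigma * runif(1, 0.7, 1.4)
      starts[[j + 1]] <- s
    }
  } else {
    fn1 <- function(par) {
      if (oob(par)) return(1e10 + sum(pmax(abs(par) - 100, 0)))
      v <- gmm_negloglik_cpp(par, d$y, d$offsets, d$X, d$W, d$Z, 1L)
      if (!is.finite(v)) 1e10 else v
    }
    gr1 <- function(par) {
      if (oob(par)) return(sign(par) * (abs(par) > 100))
      g <- gmm_negloglik_grad_cpp(par, d$y, d$offsets, d$X, d$W, d$Z, 1L)
      g[!is.finite(g)] <- 0
      pmin(pmax(g, -1e8), 1e8)
    }
    opt1 <- tryCatch(
      optim(pack_gmm_params(fit1_params, 1, q), fn1, gr1, method = "BFGS",
            control = list(maxit = max_iter, reltol = tol)),
      error = function(e) NULL)
    p1 <- if (!is.null(opt1))
      unpack_gmm_params(opt1$par, 1, p_fix, p_cov, q) else fit1_params
    starts <- multi_class_starts(d, G, p1, n_starts, seed)
  }

  best <- NULL
  n_conv <- 0L
  best_start <- NA_integer_
  for (s in seq_along(starts)) {
    opt <- run_start(starts[[s]])
    if (is.null(opt) || !is.finite(opt$value)) next
    if (opt$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || opt$value < best$value - 1e-9) {
      best <- opt
      best_start <- s
    }
  }
  if (is.null(best)) stop("likelihood not finite at any start")

  grad_at_opt <- gr(best$par)
  converged <- best$convergence == 0 &&
    (max(abs(grad_at_opt)) < grad_tol || isTRUE(best$stationary))

  params <- unpack_gmm_params(best$par, G, p_fix, p_cov, q)
  params <- canonicalize_params(params, G)
  par_hat <- pack_gmm_params(params, G, q)

  logf <- gmm_logf_cpp(par_hat, d$y, d$offsets, d$X, d$W, d$Z, G)
  post <- posterior_from_logf(logf, log(params$pi))
  rownames(post) <- d$ids
  modal <- max.col(post, "first")
  loglik <- -best$value
  bic <- -2 * loglik + k * log(n)

  vc <- gmm_vcov(par_hat, gr, length(par_hat))

  structure(list(
    spec = spec, params = params[c("theta", "pi", "beta", "gamma", "D",
                                   "sigma")],
    par = par_hat, vcov = vc,
    loglik = loglik, k = k, bic = bic,
    entropy = if (G >= 2) entropy(post) else NA_real_,
    posterior = post, modal_class = modal,
    mean_posterior_by_class = mean_posterior_by_class(post, modal),
    class_proportions = params$pi,
    patient_ids = d$ids, n_patients = n, n_excluded = d$n_excluded,
    design = list(p_fix = p_fix, p_cov = p_cov, q = q,
                  w_names = colnames(d$W)),
    convergence = list(converged = converged, code = best$convergence,
                       n_starts = length(starts), n_converged = n_conv,
                       best_start = best_start,
                       max_abs_grad = max(abs(grad_at_opt)))),
    class = "gmm_fit")
}

# Asymptotic covariance: inverse of the numeric Hessian of the negative
# log-likelihood (central differences on the analytic gradient), with
# eigenvalue flooring if the Hessian is near-singular.
gmm_vcov <- function(par, gr, npar, h = 1e-5) {
  H <- matrix(0, npar, npar)
  for (j in seq_len(npar)) {
    e <- numeric(npar); e[j] <- h
    H[, j] <- (gr(par + e) - gr(par - e)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  ei <- eigen(H, symmetric = TRUE)
  vals <- pmax(ei$values, max(ei$values) * 1e-10 + 1e-12)
  ei$vectors %*% diag(1 / vals, npar) %*% t(ei$vectors)
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> %s, G=%d, degree %d, %s transform\n",
              x$spec$outcome, x$spec$n_classes, x$spec$time_degree,
              x$spec$transform))
  cat(sprintf("  n=%d patients (%d excluded, no usable outcome)\n",
              x$n_patients, x$n_excluded))
  cat(sprintf("  loglik %.2f, k=%d, BIC %.1f, entropy %s, converged %s\n",
              x$loglik, x$k, x$bic,
              ifelse(is.na(x$entropy), "-", sprintf("%.3f", x$entropy)),
              x$convergence$converged))
  cat("  class proportions:",
      paste(sprintf("%.3f", x$params$pi), collapse = " "), "\n")
  invisible(x)
}

#' Predicted class trajectory on the original outcome scale
#'
#' The class-g mean curve on the transformed scale is back-transformed
#' through the monotone outcome transform, giving the predicted median on
#' the original scale. The 95% confidence band is a parametric bootstrap:
#' parameter vectors are drawn from the asymptotic normal distribution of
#' the maximum-likelihood estimate and the curve quantiles taken pointwise
#' (`ci = "delta"` gives the faster delta-method band on the transformed
#' scale instead).
#'
#' @param fit a [fit_gmm()] result.
#' @param class class index g.
#' @param time_grid evaluation times (years since diagnosis).
#' @param centre value of the Centre A indicator (and any other common
#'   covariates) at which to predict; a named vector matching the fit's
#'   covariate columns, or 0 for all-reference.
#' @param ci `"bootstrap"` (default) or `"delta"`.
#' @param B bootstrap draws (default 500).
#' @param horizon times beyond this trigger an extrapolation warning flag.
#' @param seed RNG seed for the bootstrap.
#' @return data frame with `t`, `median`, `lower`, `upper` and attribute
#'   `extrapolated`.
#' @export
predict_trajectory <- function(fit, class, time_grid, centre = 0,
                               ci = c("bootstrap", "delta"), B = 500,
                               horizon = 10, seed = 1L) {
  ci <- match.arg(ci)
  stopifnot(inherits(fit, "gmm_fit"), class >= 1,
            class <= fit$spec$n_classes)
  d <- fit$spec$time_degree
  X <- cbind(1, stats::poly(time_grid, degree = d, raw = TRUE, simple = TRUE))
  wvec <- rep(0, fit$design$p_cov)
  if (length(centre) == fit$design$p_cov) wvec <- as.numeric(centre)
  else if (fit$design$p_cov >= 1 && length(centre) == 1)
    wvec[1] <- as.numeric(centre)

  curve_of <- function(params) {
    eta <- as.vector(X %*% params$beta[class, ]) +
      if (length(params$gamma)) sum(params$gamma * wvec) else 0
    inverse_transform(pmax(eta, 0), fit$spec$transform)
  }
  med <- curve_of(fit$params)

  if (ci == "bootstrap") {
    set.seed(seed)
    L <- t(chol(fit$vcov + diag(1e-12, length(fit$par))))
    draws <- matrix(NA_real_, B, length(time_grid))
    for (b in seq_len(B)) {
      par_b <- fit$par + as.vector(L %*% rnorm(length(fit$par)))
      p_b <- unpack_gmm_params(par_b, fit$spec$n_classes, fit$design$p_fix,
                               fit$design$p_cov, fit$design$q)
      draws[b, ] <- curve_of(p_b)
    }
    lo <- apply(draws, 2, quantile, 0.025)
    hi <- apply(draws, 2, quantile, 0.975)
  } else {
    # delta method on the transformed-scale mean, then back-transform
    idx_beta <- (fit$spec$n_classes - 1) +
      (class - 1) * fit$design$p_fix + seq_len(fit$design$p_fix)
    idx <- c(idx_beta,
             if (fit$design$p_cov)
               (fit$spec$n_classes - 1) +
               fit$spec$n_classes * fit$design$p_fix +
               seq_len(fit$design$p_cov))
    J <- cbind(X, if (fit$design$p_cov) matrix(rep(wvec,
                                                   each = nrow(X)), nrow(X)))
    V <- fit$vcov[idx, idx, drop = FALSE]
    se <- sqrt(pmax(rowSums((J %*% V) * J), 0))
    eta <- as.vector(X %*% fit$params$beta[class, ]) +
      if (length(fit$params$gamma)) sum(fit$params$gamma * wvec) else 0
    lo <- inverse_transform(pmax(eta - 1.96 * se, 0), fit$spec$transform)
    hi <- inverse_transform(pmax(eta + 1.96 * se, 0), fit$spec$transform)
  }
  out <- data.frame(t = time_grid, median = med, lower = lo, upper = hi)
  attr(out, "extrapolated") <- any(time_grid > horizon)
  out
}
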