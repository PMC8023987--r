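#' Logistic GEE for visit-level outcome missingness
#'
#' Models the probability that a visit's outcome (PGA by default) is missing
#' as a function of visit- and patient-level predictors, accounting for the
#' clustering of visits within patients with an exchangeable working
#' correlation and reporting robust (sandwich) standard errors. This is the
#' diagnostic used to decide which covariates drive missingness and hence
#' belong in the trajectory model's mean so the missingness is ignorable
#' under MAR.
#'
#' The estimating equations are solved by Fisher scoring, alternating with
#' the moment estimator of the exchangeable correlation alpha (standardised
#' Pearson residual cross-products with the usual `N_pairs - p` denominator
#' correction), until the relative coefficient change is below `tol`.
#'
#' @param x a [cohort()].
#' @param predictors character vector drawn from `"sex"`,
#'   `"age_at_diagnosis"`, `"t"` (time since diagnosis), `"pga0"` (baseline
#'   PGA), `"centre"`.
#' @param outcome the visit outcome whose missingness is modelled.
#' @param alpha `NULL` to estimate the exchangeable correlation, or a fixed
#'   value (0 reduces the fit to ordinary logistic regression).
#' @param tol convergence tolerance on the relative coefficient change.
#' @param max_iter iteration cap.
#' @return An object of class `"gee_result"`: `coefficients`, `robust_se`,
#'   `naive_se`, `alpha`, `n_clusters`, `z`, `p_value`, `vcov_robust`,
#'   `vcov_naive`, `converged`, `n_dropped` (patients removed for missing
#'   predictors).
#' @export
fit_gee_missingness <- function(x,
                                predictors = c("sex", "age_at_diagnosis",
                                               "t", "pga0", "centre"),
                                outcome = "pga", alpha = NULL,
                                tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(x, "cohort"))
  v <- x$visits
  b <- x$baseline[match(v$patient_id, x$baseline$patient_id), , drop = FALSE]
  resp <- as.numeric(is.na(v[[outcome]]))
  cols <- list("(Intercept)" = rep(1, nrow(v)))
  for (p in predictors) {
    cols[[switch(p, sex = "sexM", centre = "centreA", p)]] <- switch(
      p,
      sex = as.numeric(b$sex == "M"),
      centre = as.numeric(b$centre == "A"),
      t = v$t,
      b[[p]])
  }
  X <- do.call(cbind, cols)
  keep <- complete.cases(X)
  id <- v$patient_id[keep]
  n_dropped <- length(unique(v$patient_id)) - length(unique(id))
  X <- X[keep, , drop = FALSE]
  y <- resp[keep]
  fit <- gee_logit_exchangeable(y, X, id, alpha = alpha, tol = tol,
                                max_iter = max_iter)
  fit$n_dropped <- n_dropped
  fit
}

#' @rdname fit_gee_missingness
#' @param y binary response vector.
#' @param X design matrix (including intercept).
#' @param id cluster identifier (one cluster per patient).
#' @export
gee_logit_exchangeable <- function(y, X, id, alpha = NULL, tol = 1e-8,
                                   max_iter = 100L) {
  X <- as.matrix(X)
  p <- ncol(X)
  cl <- split(seq_along(y), factor(id, levels = unique(id)))
  n_cl <- length(cl)
  max_m <- max(lengths(cl))
  est_alpha <- is.null(alpha)
  a <- if (est_alpha) 0 else alpha

  beta <- tryCatch(coef(glm.fit(X, y, family = binomial())),
                   error = function(e) rep(0, p))
  beta[is.na(beta)] <- 0
  converged <- FALSE

  # R^{-1} for exchangeable R = (1-a)I + aJ has the closed form
  # (I - a/(1+(m-1)a) J) / (1-a).
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    var_mu <- pmax(mu * (1 - mu), 1e-10)
    if (est_alpha) {
      e <- (y - mu) / sqrt(var_mu)
      num <- 0; npair <- 0
      for (rows in cl) {
        m <- length(rows)
        if (m < 2) next
        s <- sum(e[rows])
        num <- num + (s^2 - sum(e[rows]^2)) / 2
        npair <- npair + m * (m - 1) / 2
      }
      a <- if (npair > p) num / (npair - p) else 0
      a <- min(max(a, -1 / max(max_m - 1, 1) + 1e-6), 0.99)
    }
    U <- numeric(p); I <- matrix(0, p, p)
    for (rows in cl) {
      m <- length(rows)
      Xi <- X[rows, , drop = FALSE]
      vi <- var_mu[rows]
      ri <- y[rows] - mu[rows]
      # Di = diag(vi) Xi ; Vi = diag(sqrt(vi)) R diag(sqrt(vi))
      # Di' Vi^{-1} = Xi' diag(sqrt(vi)) R^{-1} diag(1/sqrt(vi))
      sv <- sqrt(vi)
      Binv <- (diag(m) - matrix(a / (1 + (m - 1) * a), m, m)) / (1 - a)
      DtVinv <- t(Xi * sv) %*% Binv %*% diag(1 / sv, m)
      U <- U + DtVinv %*% ri
      I <- I + DtVinv %*% (Xi * vi)
    }
    step <- solve(I, U)
    beta_new <- beta + as.vector(step)
    if (max(abs(beta_new - beta)) / max(max(abs(beta)), 1e-8) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }

  # sandwich covariance A^{-1} B A^{-1}
  eta <- as.vector(X %*% beta); mu <- plogis(eta)
  var_mu <- pmax(mu * (1 - mu), 1e-10)
  A <- matrix(0, p, p); B <- matrix(0, p, p)
  for (rows in cl) {
    m <- length(rows)
    Xi <- X[rows, , drop = FALSE]
    vi <- var_mu[rows]; sv <- sqrt(vi)
    ri <- y[rows] - mu[rows]
    Binv <- (diag(m) - matrix(a / (1 + (m - 1) * a), m, m)) / (1 - a)
    DtVinv <- t(Xi * sv) %*% Binv %*% diag(1 / sv, m)
    A <- A + DtVinv %*% (Xi * vi)
    u <- DtVinv %*% ri
    B <- B + u %*% t(u)
  }
  Ainv <- solve(A)
  vc_rob <- Ainv %*% B %*% t(Ainv)
  vc_rob <- (vc_rob + t(vc_rob)) / 2
  vc_naive <- (Ainv + t(Ainv)) / 2
  se_rob <- sqrt(diag(vc_rob)); se_naive <- sqrt(pmax(diag(vc_naive), 0))
  z <- beta / se_rob
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, robust_se = setNames(se_rob, names(beta)),
                 naive_se = setNames(se_naive, names(beta)),
                 alpha = a, n_clusters = n_cl,
                 z = setNames(z, names(beta)),
                 p_value = setNames(2 * stats::pnorm(-abs(z)), names(beta)),
                 vcov_robust = vc_rob, vcov_naive = vc_naive,
                 converged = converged),
            class = "gee_result")
}

#' @export
print.gee_result <- function(x, ...) {
  cat(sprintf("<gee_result> logistic GEE, exchangeable alpha = %.4f, %d clusters\n",
              x$alpha, x$n_clusters))
  print(data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                   z = x$z, p = signif(x$p_value, 3)))
  invisible(x)
}
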