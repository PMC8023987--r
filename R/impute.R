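#' Multiple imputation of baseline features by chained equations
#'
#' Fills the missing cells of the baseline table m times by iterating
#' variable-by-variable conditional draws: predictive mean matching (k
#' nearest donors) for numeric columns, a logistic draw for binary columns
#' and a multinomial draw for categorical columns. Each of the m completed
#' tables comes from an independent RNG stream derived from `seed`, and
#' observed cells are never altered.
#'
#' @param baseline a baseline data frame (the `baseline` element of a
#'   [cohort()]).
#' @param m number of completed tables (default 10).
#' @param n_iter chained-equation sweeps per table (default 10).
#' @param seed integer seed.
#' @param k_pmm donor pool size for predictive mean matching.
#' @param imputable columns allowed to contain missing values; others must
#'   be complete.
#' @param predictors columns used on the right-hand side of every
#'   conditional model (defaults to demographics plus all imputable
#'   columns).
#' @return An object of class `"imputation_set"`: `tables` (list of m
#'   completed data frames), `mask` (logical matrix of originally missing
#'   cells), `methods`, `m`, `n_iter`, `seed`.
#' @export
impute_baseline <- function(baseline, m = 10, n_iter = 10, seed = 1L,
                            k_pmm = 5,
                            imputable = c("pga0", "cmas0", "das0",
                                          BINARY_FEATURES),
                            predictors = NULL) {
  baseline <- as.data.frame(baseline)
  imputable <- intersect(imputable, names(baseline))
  if (is.null(predictors))
    predictors <- intersect(c("sex", "ethnicity", "diagnosis", "centre",
                              "age_at_diagnosis", "time_to_first_visit",
                              imputable), names(baseline))
  non_imputable <- setdiff(names(baseline), imputable)
  bad <- non_imputable[vapply(baseline[non_imputable], anyNA, logical(1))]
  if (length(bad))
    stop("missing values outside the imputable columns: ",
         paste(bad, collapse = ", "))
  all_missing <- imputable[vapply(baseline[imputable],
                                  function(z) all(is.na(z)), logical(1))]
  if (length(all_missing))
    stop("column(s) 100% missing, cannot impute: ",
         paste(all_missing, collapse = ", "))

  mask <- vapply(baseline, is.na, logical(nrow(baseline)))
  needs <- imputable[colSums(mask[, imputable, drop = FALSE]) > 0]
  # impute in order of increasing missingness
  needs <- needs[order(colSums(mask[, needs, drop = FALSE]))]

  method_of <- function(col) {
    z <- baseline[[col]]
    if (is.numeric(z) && all(z %in% c(0, 1) | is.na(z))) "logreg"
    else if (is.numeric(z)) "pmm"
    else "polyreg"
  }
  methods <- setNames(vapply(needs, method_of, character(1)), needs)

  design_for <- function(df, target) {
    rhs <- setdiff(predictors, target)
    mm <- model.matrix(~ ., data = lapply2_df(df[rhs]))
    mm
  }

  tables <- vector("list", m)
  for (d in seq_len(m)) {
    set.seed(seed + 104729L * d)   # independent stream per imputation
    df <- baseline
    for (col in needs) {           # initialise from observed marginals
      miss <- mask[, col]
      df[[col]][miss] <- sample(baseline[[col]][!miss], sum(miss),
                                replace = TRUE)
    }
    for (iter in seq_len(n_iter)) {
      for (col in needs) {
        miss <- mask[, col]
        X <- design_for(df, col)
        df[[col]][miss] <- draw_conditional(methods[[col]],
                                            y_obs = baseline[[col]][!miss],
                                            X_obs = X[!miss, , drop = FALSE],
                                            X_mis = X[miss, , drop = FALSE],
                                            k = k_pmm)
      }
    }
    tables[[d]] <- df
  }
  structure(list(tables = tables, mask = mask, methods = methods, m = m,
                 n_iter = n_iter, seed = seed),
            class = "imputation_set")
}

# character columns to factors so model.matrix can expand them
lapply2_df <- function(df) {
  as.data.frame(lapply(df, function(z) if (is.character(z)) factor(z) else z),
                stringsAsFactors = FALSE)
}

# One conditional draw for the missing rows of a column.
draw_conditional <- function(method, y_obs, X_obs, X_mis, k = 5) {
  n_mis <- nrow(X_mis)
  fallback <- function() sample(y_obs, n_mis, replace = TRUE)
  if (n_mis == 0) return(y_obs[0])
  if (method == "pmm") {
    tryCatch({
      qrX <- qr(X_obs)
      keep <- qrX$pivot[seq_len(qrX$rank)]
      Xo <- X_obs[, keep, drop = FALSE]; Xm <- X_mis[, keep, drop = FALSE]
      fit <- lm.fit(Xo, y_obs)
      betahat <- fit$coefficients
      res <- fit$residuals
      df_res <- max(length(y_obs) - ncol(Xo), 1)
      sigma2_star <- sum(res^2) / rchisq(1, df_res)
      XtXinv <- chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo))))
      beta_star <- betahat + t(chol(sigma2_star * XtXinv +
                                      diag(1e-12, ncol(Xo)))) %*%
        rnorm(ncol(Xo))
      yhat_obs <- as.vector(Xo %*% betahat)
      yhat_mis <- as.vector(Xm %*% beta_star)
      vapply(yhat_mis, function(yh) {
        donors <- order(abs(yhat_obs - yh))[seq_len(min(k, length(y_obs)))]
        y_obs[sample(donors, 1)]
      }, numeric(1))
    }, error = function(e) fallback())
  } else if (method == "logreg") {
    tryCatch({
      fit <- suppressWarnings(glm.fit(X_obs, y_obs, family = binomial()))
      beta <- fit$coefficients; beta[is.na(beta)] <- 0
      # approximate Bayesian draw from the asymptotic normal
      w <- fit$weights
      XtWX <- crossprod(X_obs * sqrt(pmax(w, 1e-10)))
      V <- chol2inv(chol(XtWX + diag(1e-8, ncol(X_obs))))
      beta_star <- beta + as.vector(t(chol(V + diag(1e-12, ncol(V)))) %*%
                                      rnorm(length(beta)))
      rbinom(n_mis, 1, plogis(as.vector(X_mis %*% beta_star)))
    }, error = function(e) fallback())
  } else {
    tryCatch({
      yf <- factor(y_obs)
      if (nlevels(yf) < 2) return(fallback())
      fit <- nnet::multinom(yf ~ X_obs - 1, trace = FALSE, maxit = 200)
      pr <- predict(fit, newdata = data.frame(X_obs = I(X_mis)),
                    type = "probs")
      if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
      drawn <- apply(pr, 1, function(p) sample(levels(yf), 1, prob = p))
      if (is.factor(y_obs)) factor(drawn, levels = levels(yf)) else drawn
    }, error = function(e) fallback())
  }
}
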