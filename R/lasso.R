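#' Posterior-probability-weighted response for class-membership prediction
#'
#' Rather than regressing on the modal class assignment, the predictive
#' stage propagates classification uncertainty from the mixture model: each
#' patient contributes a "member" row (y = 1, weight = posterior probability
#' of the target class) and a "non-member" row (y = 0, weight = complement).
#' With one-hot posteriors this reduces to ordinary modal-class
#' classification. Rows with weight below 1e-12 are dropped.
#'
#' @param fit a two-class [fit_gmm()] result; class 2 (the minority,
#'   persistently active class under canonical ordering) is the target.
#' @return data frame with `patient_id`, `y`, `w`.
#' @export
build_weighted_response <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (fit$spec$n_classes != 2)
    stop("weighted response is defined for the 2-class model, got G = ",
         fit$spec$n_classes)
  p2 <- fit$posterior[, 2]
  out <- data.frame(patient_id = rep(fit$patient_ids, 2),
                    y = rep(c(1, 0), each = length(p2)),
                    w = c(p2, 1 - p2))
  out[out$w >= 1e-12, , drop = FALSE]
}

LASSO_PREDICTORS <- c("diagnosis", "pga0", "cmas0", "das0",
                      "age_at_diagnosis", "time_to_first_visit",
                      BINARY_FEATURES)

#' Assemble the predictor matrix for the class-membership lasso
#'
#' Expands the baseline clinical features recorded at the first visit into
#' a numeric matrix: diagnosis as dummies against the definite-JDM
#' reference, the continuous scores as-is, and the binary features as 0/1.
#' The baseline table must be complete (use [impute_baseline()]).
#'
#' @param baseline completed baseline data frame.
#' @param weighted weighted response rows from [build_weighted_response()].
#' @return list of class `"lasso_task"` with `X`, `y`, `w`, `patient_id`.
#' @export
lasso_task <- function(baseline, weighted) {
  i <- match(weighted$patient_id, baseline$patient_id)
  if (anyNA(i)) stop("weighted response contains unknown patient ids")
  b <- baseline[i, , drop = FALSE]
  diag_f <- factor(b$diagnosis)
  if ("definite_jdm" %in% levels(diag_f))
    diag_f <- stats::relevel(diag_f, "definite_jdm")
  Xd <- model.matrix(~ diag_f)[, -1, drop = FALSE]
  colnames(Xd) <- sub("^diag_f", "diagnosis_", colnames(Xd))
  num_cols <- c("pga0", "cmas0", "das0", "age_at_diagnosis",
                "time_to_first_visit", BINARY_FEATURES)
  Xn <- as.matrix(b[num_cols])
  X <- cbind(Xd, Xn)
  if (anyNA(X)) stop("lasso predictors contain missing values; impute first")
  structure(list(X = X, y = weighted$y, w = weighted$w,
                 patient_id = weighted$patient_id),
            class = "lasso_task")
}

# Weighted standardisation constants: mean and SD under weights w/W.
weighted_standardize <- function(X, w) {
  W <- sum(w)
  m <- colSums(X * w) / W
  v <- colSums(sweep(X, 2, m)^2 * w) / W
  s <- sqrt(v)
  list(mean = m, sd = s)
}

#' L1-penalised weighted logistic regression path
#'
#' Minimises the weighted penalised objective
#' `-(1/W) sum_i w_i [y_i log p_i + (1-y_i) log(1-p_i)] + lambda ||beta||_1`
#' with an unpenalised intercept and predictors standardised to weighted
#' mean 0 and SD 1, by cyclic coordinate descent on the IRLS quadratic
#' approximation with warm starts along a descending lambda grid. The KKT
#' optimality conditions are verified at every solution. Coefficients are
#' returned on the original predictor scale.
#'
#' @param task a [lasso_task()], or a matrix `X` (then supply `y`, `w`).
#' @param lambda descending penalty grid; by default 100 log-spaced values
#'   from `lambda_max` (the smallest penalty with an all-zero solution)
#'   down to `1e-3 * lambda_max`.
#' @param nlambda,lambda_min_ratio grid size and ratio when `lambda` is NULL.
#' @param y,w response and weights when `task` is a plain matrix.
#' @param tol coordinate-descent convergence tolerance on the working
#'   objective scale (largest `v_j * delta_j^2` in a sweep).
#' @param max_sweeps cap on coordinate-descent sweeps per IRLS step.
#' @param check_kkt verify the KKT conditions at every solution (skipped
#'   inside cross-validation folds for speed).
#' @return list of class `"lasso_path"`: `lambda`, `beta` (p x nlambda,
#'   original scale), `intercept`, `beta_std`, `kkt_ok`, `lambda_max`,
#'   `dropped` (constant columns), standardisation constants.
#' @export
lasso_path <- function(task, lambda = NULL, nlambda = 100,
                       lambda_min_ratio = 1e-3, y = NULL, w = NULL,
                       tol = 1e-12, max_sweeps = 10000, check_kkt = TRUE) {
  if (inherits(task, "lasso_task")) {
    X <- task$X; y <- task$y; w <- task$w
  } else X <- as.matrix(task)
  stopifnot(length(y) == nrow(X), length(w) == nrow(X), all(w >= 0))
  if (length(unique(y[w > 0])) < 2)
    stop("need both outcome values with positive weight")
  std <- weighted_standardize(X, w)
  dropped <- colnames(X)[std$sd < 1e-12]
  if (length(dropped))
    warning("dropping constant predictor(s): ", paste(dropped, collapse = ", "))
  keep <- std$sd >= 1e-12
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, std$mean[keep]), 2,
              std$sd[keep], "/")
  W <- sum(w)
  ybar <- sum(w * y) / W
  lambda_max <- max(abs(colSums(w * Xs * (y - ybar)) / W))
  if (is.null(lambda))
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  lambda <- sort(lambda, decreasing = TRUE)

  nl <- length(lambda)
  cd <- lasso_cd_path_cpp(Xs, y, w, lambda, tol, max_sweeps)
  B <- cd$beta
  b0s <- as.vector(cd$b0)
  # beyond n_fit the path was frozen at a near-saturated fit; KKT applies
  # only to the penalties actually solved
  kkt_ok <- if (check_kkt)
    vapply(seq_len(nl), function(l)
      l <= cd$n_fit && kkt_check(Xs, y, w, W, B[, l], b0s[l], lambda[l]) ||
        l > cd$n_fit, logical(1))
  else rep(NA, nl)

  beta_orig <- matrix(0, ncol(X), nl,
                      dimnames = list(colnames(X), signif(lambda, 5)))
  beta_orig[keep, ] <- B / std$sd[keep]
  int_orig <- b0s - colSums(B * std$mean[keep] / std$sd[keep])
  structure(list(lambda = lambda, beta = beta_orig, intercept = int_orig,
                 beta_std = B, intercept_std = b0s, kkt_ok = kkt_ok,
                 n_fit = cd$n_fit, lambda_max = lambda_max,
                 dropped = dropped, std = std, keep = keep),
            class = "lasso_path")
}

# KKT conditions of the penalised objective at (b0, beta):
# active j:   grad_j + lam * sign(beta_j) = 0
# inactive j: |grad_j| <= lam
# with grad_j = (1/W) sum_i w_i x_ij (p_i - y_i).
kkt_check <- function(Xs, y, w, W, beta, b0, lam, tol = 1e-6) {
  pr <- plogis(b0 + as.vector(Xs %*% beta))
  g <- colSums(w * Xs * (pr - y)) / W
  active <- beta != 0
  ok_active <- !any(active) || max(abs(g[active] + lam * sign(beta[active]))) <= tol
  ok_inactive <- !any(!active) || max(abs(g[!active])) <= lam + tol
  ok0 <- abs(sum(w * (pr - y)) / W) <= tol
  ok_active && ok_inactive && ok0
}

# Weighted AUC (probability-weighted Mann-Whitney concordance).
weighted_auc <- function(score, y, w) {
  o <- order(score)
  s <- score[o]; yy <- y[o]; ww <- w[o]
  wneg <- ww * (yy == 0); wpos <- ww * (yy == 1)
  grp <- cumsum(c(1, diff(s) != 0))
  gn <- as.vector(tapply(wneg, grp, sum))
  below <- c(0, cumsum(gn))[grp]
  num <- sum(wpos * (below + 0.5 * gn[grp]))
  num / (sum(wpos) * sum(wneg))
}

weighted_loss <- function(loss, score, y, w) {
  switch(loss,
         auc = 1 - weighted_auc(score, y, w),
         deviance = {
           pr <- pmin(pmax(score, 1e-10), 1 - 1e-10)
           -2 * sum(w * (y * log(pr) + (1 - y) * log(1 - pr))) / sum(w)
         },
         misclassification = sum(w * ((score > 0.5) != y)) / sum(w))
}

#' Cross-validated selection of the lasso penalty
#'
#' Ten-fold (by default) cross-validation with folds that partition
#' patients — both weighted rows of a patient share a fold — stratified by
#' modal class. For each penalty on the grid the mean out-of-fold weighted
#' loss is computed (1 - AUC by default; weighted deviance and weighted
#' misclassification are the alternatives) and the penalty minimising it is
#' returned, ties resolved toward the larger (sparser) penalty.
#'
#' @param task a [lasso_task()].
#' @param n_folds number of folds (>= 2).
#' @param loss `"auc"`, `"deviance"` or `"misclassification"`.
#' @param seed RNG seed for the fold assignment.
#' @param lambda optional penalty grid (defaults to the full-data grid).
#' @return list with `lambda` (selected), `cv_curve` (mean loss per
#'   penalty), `lambda_grid`, `loss`, `folds`.
#' @export
cv_select_lambda <- function(task, n_folds = 10,
                             loss = c("auc", "deviance", "misclassification"),
                             seed = 1L, lambda = NULL) {
  loss <- match.arg(loss)
  stopifnot(n_folds >= 2)
  if (is.null(lambda)) {
    full <- lasso_path(task, nlambda = 100)
    lambda <- full$lambda
  }
  ids <- unique(task$patient_id)
  # modal class of each patient = the heavier of its two weighted rows
  modal <- vapply(ids, function(id) {
    rows <- task$patient_id == id
    task$y[rows][which.max(task$w[rows])]
  }, numeric(1))

  assign_folds <- function(s) {
    set.seed(s)
    fold <- integer(length(ids))
    for (cls in unique(modal)) {
      i <- which(modal == cls)
      fold[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
    fold
  }
  fold <- assign_folds(seed)
  one_class_fold <- function(fold) {
    any(vapply(seq_len(n_folds), function(f) {
      yy <- task$y[task$patient_id %in% ids[fold == f]]
      length(unique(yy)) < 2
    }, logical(1)))
  }
  if (one_class_fold(fold)) {
    fold <- assign_folds(seed + 1L)
    if (one_class_fold(fold))
      stop("a cross-validation fold contains a single outcome class")
  }

  losses <- matrix(NA_real_, n_folds, length(lambda))
  for (f in seq_len(n_folds)) {
    test_ids <- ids[fold == f]
    in_test <- task$patient_id %in% test_ids
    tr <- structure(list(X = task$X[!in_test, , drop = FALSE],
                         y = task$y[!in_test], w = task$w[!in_test],
                         patient_id = task$patient_id[!in_test]),
                    class = "lasso_task")
    path <- lasso_path(tr, lambda = lambda, check_kkt = FALSE)
    Xte <- task$X[in_test, , drop = FALSE]
    for (l in seq_along(lambda)) {
      pr <- plogis(path$intercept[l] + as.vector(Xte %*% path$beta[, l]))
      losses[f, l] <- weighted_loss(loss, pr, task$y[in_test],
                                    task$w[in_test])
    }
  }
  curve <- colMeans(losses)
  best <- min(curve)
  sel <- which(curve <= best + 1e-12)[1]   # grid descends: first = largest
  list(lambda = lambda[sel], cv_curve = curve, lambda_grid = lambda,
       loss = loss, folds = setNames(fold, ids))
}

#' Fit the weighted lasso on one completed dataset
#'
#' Runs [cv_select_lambda()] then [lasso_path()] and extracts the
#' coefficients at the selected penalty.
#'
#' @inheritParams cv_select_lambda
#' @return list with `coef` (original-scale coefficients incl. intercept),
#'   `lambda`, `cv`, `path`.
#' @export
fit_lasso <- function(task, n_folds = 10, loss = "auc", seed = 1L) {
  cv <- cv_select_lambda(task, n_folds = n_folds, loss = loss, seed = seed)
  path <- lasso_path(task, lambda = cv$lambda_grid)
  l <- which(path$lambda == cv$lambda)[1]
  cf <- c("(Intercept)" = path$intercept[l], path$beta[, l])
  list(coef = cf, lambda = cv$lambda, cv = cv, path = path)
}

#' Re-fit with pairwise interactions of retained predictors
#'
#' Adds all pairwise products of the retained predictors to the task and
#' re-runs penalty selection and fitting.
#'
#' @param task a [lasso_task()].
#' @param retained character vector of >= 2 retained predictor names.
#' @inheritParams cv_select_lambda
#' @return As [fit_lasso()], on the augmented predictor set.
#' @export
fit_with_interactions <- function(task, retained, n_folds = 10, loss = "auc",
                                  seed = 1L) {
  retained <- intersect(retained, colnames(task$X))
  if (length(retained) < 2)
    stop("need >= 2 retained predictors to form interactions")
  pairs <- utils::combn(retained, 2)
  Xint <- matrix(NA_real_, nrow(task$X), ncol(pairs))
  colnames(Xint) <- apply(pairs, 2, paste, collapse = ":")
  for (j in seq_len(ncol(pairs)))
    Xint[, j] <- task$X[, pairs[1, j]] * task$X[, pairs[2, j]]
  task2 <- structure(list(X = cbind(task$X, Xint), y = task$y, w = task$w,
                          patient_id = task$patient_id),
                     class = "lasso_task")
  fit_lasso(task2, n_folds = n_folds, loss = loss, seed = seed)
}

#' Pool lasso estimates across imputed datasets
#'
#' A predictor is retained when its coefficient is non-zero in more than
#' half of the imputations; its pooled coefficient is the mean over the
#' imputations where it is non-zero and the pooled odds ratio its
#' exponential. No standard errors are produced: they are unreliable for
#' penalised estimates. The intercept is pooled as the mean over all
#' imputations.
#'
#' @param coefs list of m named coefficient vectors (identical names,
#'   original scale, including `"(Intercept)"`).
#' @return list with `retained`, `coef` (pooled, retained predictors),
#'   `odds_ratio`, `intercept`, `n_nonzero` (per predictor), `m`.
#' @export
pool_over_imputations <- function(coefs) {
  m <- length(coefs)
  if (m < 2) stop("pooling needs >= 2 imputations")
  nm <- names(coefs[[1]])
  if (!all(vapply(coefs, function(cf) identical(names(cf), nm), logical(1))))
    stop("inconsistent predictor sets across imputations")
  M <- do.call(rbind, coefs)
  preds <- setdiff(nm, "(Intercept)")
  nz <- colSums(M[, preds, drop = FALSE] != 0)
  retained <- preds[nz > m / 2]
  pooled <- vapply(retained, function(j) mean(M[M[, j] != 0, j]), numeric(1))
  list(retained = retained, coef = pooled, odds_ratio = exp(pooled),
       intercept = mean(M[, "(Intercept)"]),
       n_nonzero = setNames(nz, preds), m = m)
}

#' Predicted class-2 probabilities over covariate combinations
#'
#' Evaluates the pooled model's inverse-logit linear predictor at each row
#' of `combinations`; retained predictors absent from `combinations` are
#' held at their weighted medians in `task` (continuous covariates) so the
#' grid isolates the features being varied.
#'
#' @param pooled a [pool_over_imputations()] result.
#' @param combinations data frame of covariate settings (columns named as
#'   in the predictor matrix).
#' @param task a [lasso_task()] supplying the weighted medians.
#' @return `combinations` with a `probability` column appended.
#' @export
predicted_probability_grid <- function(pooled, combinations, task) {
  unknown <- setdiff(names(combinations), colnames(task$X))
  if (length(unknown))
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
  eta <- rep(pooled$intercept, nrow(combinations))
  for (j in pooled$retained) {
    xj <- if (j %in% names(combinations)) combinations[[j]]
    else weighted_median(task$X[, j], task$w)
    eta <- eta + pooled$coef[[j]] * xj
  }
  combinations$probability <- plogis(eta)
  combinations
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' Identify baseline predictors of severe-class membership
#'
#' The full predictive stage: for each completed baseline table from the
#' imputation set, build the posterior-probability-weighted task, select
#' the penalty by cross-validation, fit the lasso, then pool coefficients
#' across imputations. When at least two predictors are retained the model
#' is re-run with their pairwise interactions and pooled again.
#'
#' @param fit a two-class [fit_gmm()] result.
#' @param imp an [impute_baseline()] result.
#' @param n_folds,loss,seed passed to [cv_select_lambda()].
#' @param interactions re-fit with interactions when possible.
#' @return list of class `"lasso_result"`: `pooled`, `per_imputation`
#'   (coefficient vectors), `pooled_interactions` and
#'   `per_imputation_interactions` (or NULL), `loss`.
#' @export
lasso_predict <- function(fit, imp, n_folds = 10, loss = "auc", seed = 1L,
                          interactions = TRUE) {
  stopifnot(inherits(imp, "imputation_set"))
  weighted <- build_weighted_response(fit)
  coefs <- vector("list", imp$m)
  for (d in seq_len(imp$m)) {
    task <- lasso_task(imp$tables[[d]], weighted)
    coefs[[d]] <- fit_lasso(task, n_folds = n_folds, loss = loss,
                            seed = seed + d)$coef
  }
  pooled <- pool_over_imputations(coefs)
  pooled_int <- NULL; coefs_int <- NULL
  if (interactions && length(pooled$retained) >= 2) {
    coefs_int <- vector("list", imp$m)
    for (d in seq_len(imp$m)) {
      task <- lasso_task(imp$tables[[d]], weighted)
      coefs_int[[d]] <- fit_with_interactions(task, pooled$retained,
                                              n_folds = n_folds, loss = loss,
                                              seed = seed + d)$coef
    }
    pooled_int <- pool_over_imputations(coefs_int)
  }
  structure(list(pooled = pooled, per_imputation = coefs,
                 pooled_interactions = pooled_int,
                 per_imputation_interactions = coefs_int, loss = loss),
            class = "lasso_result")
}

#' @export
print.lasso_result <- function(x, ...) {
  cat(sprintf("<lasso_result> loss = %s, m = %d imputations\n", x$loss,
              x$pooled$m))
  if (length(x$pooled$retained)) {
    cat("  retained predictors (pooled OR):\n")
    for (j in x$pooled$retained)
      cat(sprintf("    %-24s %.3f\n", j, x$pooled$odds_ratio[[j]]))
  } else cat("  no predictor retained\n")
  invisible(x)
}
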