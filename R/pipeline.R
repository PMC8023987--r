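#' Cross-tabulate two modal classifications
#'
#' Counts patients by (modal class of the first fit, modal class of the
#' second fit) over the patients classified by both, and attaches row and
#' column percentages: column percentages give the share of each column
#' class falling in each row class, row percentages the converse.
#'
#' @param fit_row,fit_col two [fit_gmm()] fits sharing patient ids (e.g.
#'   the PGA and modified-DAS models).
#' @return An object of class `"crosstab"`: `counts`, `col_pct`, `row_pct`,
#'   `n`, `n_excluded` (patients lacking one of the classifications).
#' @export
cross_tabulate <- function(fit_row, fit_col) {
  common <- intersect(fit_row$patient_ids, fit_col$patient_ids)
  if (!length(common)) stop("the two fits share no patients")
  r <- fit_row$modal_class[match(common, fit_row$patient_ids)]
  c_ <- fit_col$modal_class[match(common, fit_col$patient_ids)]
  counts <- as.matrix(table(factor(r, 1:fit_row$spec$n_classes),
                            factor(c_, 1:fit_col$spec$n_classes)))
  out <- crosstab_from_counts(counts)
  out$n_excluded <- length(union(fit_row$patient_ids, fit_col$patient_ids)) -
    length(common)
  out
}

#' @rdname cross_tabulate
#' @param counts a numeric matrix of cross-classified counts (rows = first
#'   classification's classes, columns = second's).
#' @export
crosstab_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  dimnames(counts) <- list(paste0("row_class", seq_len(nrow(counts))),
                           paste0("col_class", seq_len(ncol(counts))))
  col_pct <- sweep(counts, 2, colSums(counts), "/") * 100
  row_pct <- sweep(counts, 1, rowSums(counts), "/") * 100
  structure(list(counts = counts, col_pct = col_pct, row_pct = row_pct,
                 n = sum(counts), n_excluded = 0L),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat("<crosstab> counts (column %):\n")
  disp <- matrix(sprintf("%d (%.1f)", x$counts, x$col_pct),
                 nrow(x$counts), dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Sensitivity-analysis sub-cohorts
#'
#' Produces the named sub-cohorts on which the trajectory models are
#' refitted to check robustness: females only; males only; the inception
#' cohort (first recorded visit within one month of diagnosis); exclusion
#' of late-entry patients (first visit 5 or more years after diagnosis);
#' and additionally excluding patients with fewer than three visits (a
#' patient with exactly three is retained). Empty subsets are skipped with
#' a warning.
#'
#' @param x a [cohort()].
#' @param subsets which subsets to build.
#' @return Named list of [cohort()] objects.
#' @export
sensitivity_subsets <- function(x, subsets = c("females", "males",
                                               "inception", "no_late_entry",
                                               "no_late_entry_min3visits")) {
  stopifnot(inherits(x, "cohort"))
  b <- x$baseline
  n_visits <- table(factor(x$visits$patient_id, levels = b$patient_id))
  keep_ids <- list(
    females = b$patient_id[b$sex == "F"],
    males = b$patient_id[b$sex == "M"],
    inception = b$patient_id[b$time_to_first_visit <= 1 / 12],
    no_late_entry = b$patient_id[b$time_to_first_visit < 5],
    no_late_entry_min3visits =
      b$patient_id[b$time_to_first_visit < 5 & as.integer(n_visits) >= 3])
  out <- list()
  for (s in subsets) {
    ids <- keep_ids[[s]]
    if (!length(ids)) {
      warning("sensitivity subset '", s, "' is empty; skipped")
      next
    }
    out[[s]] <- cohort(b[b$patient_id %in% ids, , drop = FALSE],
                       x$visits[x$visits$patient_id %in% ids, , drop = FALSE])
  }
  out
}

#' Characterise patients by modal class
#'
#' Per modal class: n and %, median (Q1-Q3) of the continuous baseline
#' variables and counts (%) of the categorical ones — the per-class
#' description computed from the most likely class of each patient.
#'
#' @param x a [cohort()].
#' @param fit a [fit_gmm()] result on that cohort.
#' @return Named list of per-class summary data frames plus `n` and
#'   `proportion` vectors.
#' @export
characterize_classes <- function(x, fit) {
  b <- x$baseline[match(fit$patient_ids, x$baseline$patient_id), ,
                  drop = FALSE]
  cls <- fit$modal_class
  G <- fit$spec$n_classes
  n_g <- tabulate(cls, G)
  num_cols <- names(b)[vapply(b, is.numeric, logical(1))]
  cat_cols <- setdiff(names(b), c(num_cols, "patient_id"))
  per_class <- lapply(seq_len(G), function(g) {
    bg <- b[cls == g, , drop = FALSE]
    num <- do.call(rbind, lapply(num_cols, function(cn) {
      q <- quantile(bg[[cn]], c(0.25, 0.5, 0.75), na.rm = TRUE)
      data.frame(variable = cn, median = q[[2]], q1 = q[[1]], q3 = q[[3]])
    }))
    cat_ <- do.call(rbind, lapply(cat_cols, function(cn) {
      tb <- table(bg[[cn]])
      data.frame(variable = cn, level = names(tb), n = as.integer(tb),
                 pct = 100 * as.integer(tb) / nrow(bg))
    }))
    list(numeric = num, categorical = cat_)
  })
  list(per_class = per_class, n = n_g, proportion = n_g / sum(n_g))
}

#' Pipeline configuration
#'
#' Defaults for [run_pipeline()]: either paths to baseline/visit CSVs or
#' (default) simulation from [default_sim_spec()]; a 10-year follow-up
#' horizon; cubic square-root growth mixture models with centre as a common
#' covariate; class counts up to `G_max`; 10 imputations; 10-fold
#' cross-validation with AUC loss.
#'
#' @param baseline_path,visits_path input CSVs, or NULL to simulate.
#' @param n_patients simulated cohort size when simulating.
#' @param horizon follow-up truncation (years).
#' @param G_max largest class count fitted.
#' @param n_starts multistart count for [fit_gmm()].
#' @param m imputations; `cv_folds`, `loss` for the lasso stage.
#' @param interactions re-fit the lasso with pairwise interactions of the
#'   retained predictors.
#' @param sensitivity run the sensitivity subsets stage.
#' @param seed master seed.
#' @param out_dir output directory for stage artifacts.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(baseline_path = NULL, visits_path = NULL,
                            n_patients = 519L, horizon = 10, G_max = 6,
                            n_starts = 30, m = 10, cv_folds = 10,
                            loss = "auc", interactions = TRUE,
                            sensitivity = TRUE, seed = 1L,
                            out_dir = tempfile("trajmix_run_")) {
  structure(list(baseline_path = baseline_path, visits_path = visits_path,
                 n_patients = as.integer(n_patients), horizon = horizon,
                 G_max = G_max, n_starts = n_starts, m = m,
                 cv_folds = cv_folds, loss = loss,
                 interactions = interactions, sensitivity = sensitivity,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full trajectory analysis pipeline
#'
#' Executes, in order: (1) load or simulate the cohort; (2) truncate
#' follow-up at the horizon; (3) the logistic-GEE missingness diagnostic;
#' (4) growth mixture models for PGA over 1..G_max classes with BIC/entropy
#' selection; (5) the same for modified DAS; (6) cross-tabulation of the
#' two modal classifications; (7) chained-equations imputation of baseline
#' features; (8) the posterior-probability-weighted lasso. Optionally the
#' sensitivity subsets are refitted with the selected PGA specification.
#' Each stage writes flat CSV/JSON artifacts to `config$out_dir` and is
#' recorded in `manifest.json`; a stage failure halts the run with the
#' completed stages preserved on disk.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with all stage results and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  results <- list()
  t_start <- Sys.time()

  log_stage <- function(name, info = list()) {
    manifest$stages[[name]] <<- c(list(completed = TRUE), info)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # 1. cohort
  results$cohort <- stage("cohort", {
    if (!is.null(config$baseline_path)) {
      co <- read_cohort(config$baseline_path, config$visits_path)
      results$truth <- NULL
      co
    } else {
      sim <- simulate_cohort(default_sim_spec("pga", config$n_patients,
                                              seed = config$seed),
                             das_spec = default_sim_spec("das",
                                                         config$n_patients),
                             seed = config$seed)
      results$truth <- sim$truth
      write_cohort(sim$cohort, file.path(config$out_dir, "baseline.csv"),
                   file.path(config$out_dir, "visits.csv"))
      sim$cohort
    }
  })
  log_stage("cohort", list(n_patients = nrow(results$cohort$baseline),
                           n_visits = nrow(results$cohort$visits)))

  # 2. truncation
  results$truncated <- stage("truncate",
                             truncate_followup(results$cohort,
                                               config$horizon))
  log_stage("truncate",
            list(horizon = config$horizon,
                 n_visits = nrow(results$truncated$visits),
                 n_dropped_patients =
                   attr(results$truncated, "n_dropped_patients")))
  co <- results$truncated

  # 3. missingness GEE
  results$gee <- stage("missingness_gee", fit_gee_missingness(co))
  write.csv(data.frame(term = names(results$gee$coefficients),
                       estimate = results$gee$coefficients,
                       robust_se = results$gee$robust_se,
                       z = results$gee$z, p = results$gee$p_value),
            file.path(config$out_dir, "gee_missingness.csv"),
            row.names = FALSE)
  log_stage("missingness_gee", list(alpha = results$gee$alpha))

  # 4. GMM for PGA
  results$pga <- stage("gmm_pga", {
    fr <- fit_range(co, gmm_spec(2, outcome = "pga"), G_max = config$G_max,
                    n_starts = config$n_starts, seed = config$seed)
    fr$selection <- select_model(fr$table)
    fr
  })
  write.csv(results$pga$table, file.path(config$out_dir,
                                         "selection_pga.csv"),
            row.names = FALSE)
  log_stage("gmm_pga", list(G = results$pga$selection$G,
                            conflict = results$pga$selection$conflict))
  fit_pga <- results$pga$fits[[results$pga$selection$G]]

  # 5. GMM for DAS (no centre covariate: missingness was a PGA finding)
  results$das <- stage("gmm_das", {
    fr <- fit_range(co, gmm_spec(2, outcome = "das",
                                 covariates = character(0)),
                    G_max = config$G_max, n_starts = config$n_starts,
                    seed = config$seed + 1000L)
    fr$selection <- select_model(fr$table)
    fr
  })
  write.csv(results$das$table, file.path(config$out_dir,
                                         "selection_das.csv"),
            row.names = FALSE)
  log_stage("gmm_das", list(G = results$das$selection$G))
  fit_das <- results$das$fits[[results$das$selection$G]]

  # 6. cross-tabulation
  results$crosstab <- stage("crosstab", cross_tabulate(fit_pga, fit_das))
  write.csv(results$crosstab$counts,
            file.path(config$out_dir, "crosstab_counts.csv"))
  log_stage("crosstab", list(n = results$crosstab$n))

  # 7. imputation
  results$imputation <- stage("imputation",
                              impute_baseline(co$baseline, m = config$m,
                                              seed = config$seed + 2000L))
  log_stage("imputation", list(m = config$m))

  # 8. weighted lasso (needs the two-class PGA fit)
  results$lasso <- stage("lasso", {
    fit2 <- if (fit_pga$spec$n_classes == 2) fit_pga else
      results$pga$fits[[2]]
    lasso_predict(fit2, results$imputation, n_folds = config$cv_folds,
                  loss = config$loss, seed = config$seed + 3000L,
                  interactions = isTRUE(config$interactions))
  })
  pooled <- results$lasso$pooled
  write.csv(data.frame(predictor = pooled$retained,
                       coef = unname(pooled$coef),
                       odds_ratio = unname(pooled$odds_ratio)),
            file.path(config$out_dir, "lasso_pooled.csv"), row.names = FALSE)
  log_stage("lasso", list(retained = pooled$retained))

  if (config$sensitivity) {
    results$sensitivity <- stage("sensitivity", {
      subs <- sensitivity_subsets(co)
      lapply(subs, function(s)
        tryCatch(fit_gmm(s, fit_pga$spec, n_starts = max(5,
                                                         config$n_starts %/% 3),
                         seed = config$seed)$params$pi,
                 error = function(e) NULL))
    })
    log_stage("sensitivity", list(subsets = names(results$sensitivity)))
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  manifest$complete <- TRUE
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
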