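#' Fit growth mixture models over a range of class counts
#'
#' Stage one fits single-class models for every candidate (transform, time
#' degree) combination and keeps the structure with the lowest BIC; because
#' the candidate transforms put the outcome on different scales, the
#' log-likelihoods entering this comparison include the log-Jacobian of the
#' transform so BICs refer to the same (original-scale) data. Stage two
#' fits that structure with 2 to `G_max` classes. A failed fit marks its
#' row rather than aborting the table.
#'
#' @param x a [cohort()].
#' @param base_spec a [gmm_spec()]; its outcome, random effects and
#'   covariates are kept, its transform/degree replaced by the stage-one
#'   winner.
#' @param G_max largest class count (default 6).
#' @param n_starts multistart count passed to [fit_gmm()].
#' @param seed RNG seed.
#' @param transforms,degrees candidate outcome transforms and time-polynomial
#'   degrees for stage one.
#' @return list with `table` (one row per G: loglik, k, BIC, entropy, class
#'   proportions, mean posterior by class, converged), `fits` (the
#'   [fit_gmm()] objects, indexed by G), `structure` (chosen transform and
#'   degree) and `structure_table` (the stage-one comparison).
#' @export
fit_range <- function(x, base_spec, G_max = 6, n_starts = 30, seed = 1L,
                      transforms = c("identity", "sqrt"), degrees = 1:3) {
  stopifnot(G_max >= 2)
  cand <- expand.grid(transform = transforms, degree = degrees,
                      stringsAsFactors = FALSE)
  cand$bic <- NA_real_
  fits1 <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    sp <- gmm_spec(1, outcome = base_spec$outcome,
                   time_degree = cand$degree[i],
                   transform = cand$transform[i],
                   random_effects = base_spec$random_effects,
                   covariates = base_spec$covariates)
    f <- tryCatch(fit_gmm(x, sp, n_starts = max(3, n_starts %/% 5),
                          seed = seed),
                  error = function(e) NULL)
    fits1[[i]] <- f
    if (!is.null(f))
      cand$bic[i] <- -2 * (f$loglik + transform_log_jacobian(x, sp)) +
        f$k * log(f$n_patients)
  }
  if (all(is.na(cand$bic))) stop("no single-class model could be fitted")
  win <- which.min(cand$bic)
  structure_table <- cand

  rows <- list()
  fits <- list()
  for (G in seq_len(G_max)) {
    sp <- gmm_spec(G, outcome = base_spec$outcome,
                   time_degree = cand$degree[win],
                   transform = cand$transform[win],
                   random_effects = base_spec$random_effects,
                   covariates = base_spec$covariates)
    f <- if (G == 1) fits1[[win]] else
      tryCatch(fit_gmm(x, sp, n_starts = n_starts, seed = seed + G),
               error = function(e) NULL)
    fits[[G]] <- f
    rows[[G]] <- if (is.null(f)) {
      data.frame(G = G, loglik = NA, k = NA, bic = NA, entropy = NA,
                 proportions = NA, mean_posterior = NA, converged = FALSE,
                 failed = TRUE)
    } else {
      data.frame(G = G, loglik = f$loglik, k = f$k, bic = f$bic,
                 entropy = f$entropy,
                 proportions = paste(sprintf("%.3f", f$params$pi),
                                     collapse = "/"),
                 mean_posterior = paste(sprintf("%.3f",
                                                f$mean_posterior_by_class),
                                        collapse = "/"),
                 converged = f$convergence$converged, failed = FALSE)
    }
  }
  list(table = do.call(rbind, rows), fits = fits,
       structure = list(transform = cand$transform[win],
                        degree = cand$degree[win]),
       structure_table = structure_table)
}

# Log-Jacobian sum of the outcome transform over the usable visits, making
# likelihoods comparable across transforms.  For sqrt, |dy*/dy| = 1/(2 sqrt y);
# exact zeros (boundary scores) are floored at 0.05 — half the finest
# plausible score increment — so the Jacobian stays finite.
transform_log_jacobian <- function(x, spec) {
  y <- x$visits[[spec$outcome]]
  y <- y[!is.na(y)]
  if (spec$transform == "identity") return(0)
  sum(-log(2 * sqrt(pmax(y, 0.05))))
}

#' Select the number of classes from a comparison table
#'
#' Returns the class count with the lowest BIC among converged,
#' non-failed rows. Entropy is the secondary criterion: when the
#' entropy-maximal G differs from the BIC-minimal G the conflict is
#' reported, not silently resolved.
#'
#' @param table the `table` element of a [fit_range()] result.
#' @return list with `G` (chosen class count), `G_entropy` (entropy-maximal
#'   G among `G >= 2`) and `conflict` flag.
#' @export
select_model <- function(table) {
  ok <- !table$failed & table$converged & is.finite(table$bic)
  if (!any(ok)) stop("no converged model in the selection table")
  G_bic <- table$G[ok][which.min(table$bic[ok])]
  ent_ok <- ok & table$G >= 2 & is.finite(table$entropy)
  G_ent <- if (any(ent_ok))
    table$G[ent_ok][which.max(table$entropy[ent_ok])] else NA_integer_
  list(G = G_bic, G_entropy = G_ent,
       conflict = !is.na(G_ent) && G_ent != G_bic)
}
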