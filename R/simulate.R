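#' Specify a synthetic cohort generator
#'
#' Defines the generative model the analysis assumes: a latent trajectory
#' class per patient; a class-specific cubic polynomial mean of the
#' transformed outcome plus a common centre effect; patient-level random
#' intercept and slope; Gaussian residual noise on the transformed scale; a
#' visit process (log-normal recruitment delay, Gamma inter-visit gaps,
#' log-normal follow-up length); missing-at-random masking of the outcome
#' driven by baseline severity and centre; and class-dependent baseline
#' clinical features with stated log odds ratios.
#'
#' @param outcome outcome name, `"pga"` (0-10) or `"das"` (0-5).
#' @param n_patients number of patients.
#' @param class_probs latent class probabilities (simplex, length G).
#' @param beta G x 4 matrix of class-specific coefficients for
#'   `(1, t, t^2, t^3)` on the transformed scale.
#' @param gamma_centre additive effect of Centre A on the transformed scale.
#' @param re_cov 2 x 2 positive-semidefinite covariance of the random
#'   intercept and slope.
#' @param sigma residual SD on the transformed scale (> 0).
#' @param transform `"sqrt"` or `"identity"` (see [transform_outcome()]).
#' @param range_max upper bound of the instrument scale (10 for PGA, 5 for
#'   modified DAS); simulated outcomes are clipped to `[0, range_max]`.
#' @param visit_gap_shape,visit_gap_mean Gamma shape and mean (years) of
#'   inter-visit gaps; mean 0.5 gives about two visits per year.
#' @param t0_meanlog,t0_sdlog log-normal parameters of the recruitment delay
#'   (time from diagnosis to first recorded visit, years).
#' @param t0_class_shift additive shift on `t0_meanlog` per class (length G);
#'   lets late entry be associated with class membership.
#' @param followup_meanlog,followup_sdlog,followup_range log-normal
#'   parameters and clipping range of follow-up duration after first visit.
#' @param centre_prob probability of recruitment at Centre A.
#' @param miss_model named vector `(intercept, pga0, centreA)` of logistic
#'   coefficients for the per-visit probability that the outcome is missing.
#' @param feature_prev named vector of marginal prevalences of the binary
#'   baseline features.
#' @param feature_logor named vector of log odds ratios of each binary
#'   feature for membership of `severe_class` versus the rest.
#' @param severe_class index of the class whose membership the baseline
#'   features predict.
#' @param baseline_missing_probs named vector of MCAR missingness rates for
#'   baseline columns.
#' @param seed default RNG seed used by [simulate_cohort()].
#' @return An object of class `"sim_spec"`.
#' @export
sim_spec <- function(outcome = c("pga", "das"),
                     n_patients = 519L,
                     class_probs = c(0.89, 0.11),
                     beta = rbind(c(1.80, -0.28, 0.026, -0.0007),
                                  c(2.20, -0.15, 0.030, -0.0015)),
                     gamma_centre = 0.1,
                     re_cov = matrix(c(0.09, -0.002, -0.002, 0.0009), 2, 2),
                     sigma = 0.28,
                     transform = c("sqrt", "identity"),
                     range_max = NULL,
                     visit_gap_shape = 2, visit_gap_mean = 0.5,
                     t0_meanlog = log(0.2), t0_sdlog = 1.1,
                     t0_class_shift = NULL,
                     followup_meanlog = log(5.1), followup_sdlog = 0.8,
                     followup_range = c(0.2, 23.4),
                     centre_prob = 0.464,
                     miss_model = c(intercept = -2.72, pga0 = 0.15,
                                    centreA = 0.5),
                     feature_prev = c(arthritis = 0.244,
                                      abnormal_respiration = 0.092,
                                      calcinosis = 0.117,
                                      lipodystrophy = 0.063,
                                      ulceration = 0.125),
                     feature_logor = c(arthritis = 0,
                                       abnormal_respiration = log(1.91),
                                       calcinosis = 0,
                                       lipodystrophy = log(1.92),
                                       ulceration = 0),
                     severe_class = 2L,
                     baseline_missing_probs = c(pga0 = 0.128, cmas0 = 0.234,
                                                das0 = 0,
                                                arthritis = 0.100,
                                                abnormal_respiration = 0.058,
                                                calcinosis = 0.339,
                                                lipodystrophy = 0.087,
                                                ulceration = 0.089),
                     seed = 1L) {
  outcome <- match.arg(outcome)
  transform <- match.arg(transform)
  beta <- as.matrix(beta)
  G <- length(class_probs)
  if (abs(sum(class_probs) - 1) > 1e-8 || any(class_probs <= 0))
    stop("class_probs must be a positive vector summing to 1")
  if (nrow(beta) != G || ncol(beta) != 4)
    stop("beta must be a ", G, " x 4 matrix (intercept, t, t^2, t^3)")
  if (!isTRUE(all.equal(re_cov, t(re_cov))) ||
      any(eigen(re_cov, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    stop("re_cov must be symmetric positive-semidefinite")
  if (sigma < 0) stop("sigma must be >= 0")
  stopifnot(centre_prob >= 0, centre_prob <= 1,
            all(baseline_missing_probs >= 0), all(baseline_missing_probs <= 1),
            all(feature_prev > 0), all(feature_prev < 1),
            severe_class >= 1, severe_class <= G)
  if (is.null(range_max)) range_max <- if (outcome == "pga") 10 else 5
  if (is.null(t0_class_shift)) t0_class_shift <- rep(0, G)
  stopifnot(length(t0_class_shift) == G)
  structure(list(outcome = outcome, n_patients = as.integer(n_patients),
                 class_probs = class_probs, beta = beta,
                 gamma_centre = gamma_centre, re_cov = re_cov, sigma = sigma,
                 transform = transform, range_max = range_max,
                 visit_gap_shape = visit_gap_shape,
                 visit_gap_mean = visit_gap_mean,
                 t0_meanlog = t0_meanlog, t0_sdlog = t0_sdlog,
                 t0_class_shift = t0_class_shift,
                 followup_meanlog = followup_meanlog,
                 followup_sdlog = followup_sdlog,
                 followup_range = followup_range,
                 centre_prob = centre_prob, miss_model = miss_model,
                 feature_prev = feature_prev, feature_logor = feature_logor,
                 severe_class = as.integer(severe_class),
                 baseline_missing_probs = baseline_missing_probs,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Default simulation specification for each outcome
#'
#' Returns the [sim_spec()] the package treats as its reference cohort:
#' 519 patients, 46.4% recruited at Centre A, recruitment delay with median
#' 0.2 years, follow-up with median 5.1 years and about two visits per year.
#' For PGA: two classes with probabilities (0.89, 0.11), the minority class
#' starting higher and staying active while the majority class improves;
#' late entry shifted upward in the minority class; binary baseline features
#' at the cohort prevalences with odds ratios 1.91 (abnormal respiration)
#' and 1.92 (lipodystrophy) for minority-class membership; baseline feature
#' missingness 10/5.8/33.9/8.7/8.9% and PGA/CMAS baseline missingness
#' 12.8/23.4%. For modified DAS: three classes with probabilities
#' (0.16, 0.12, 0.72) — high-improving, high-persistent and low-improving.
#'
#' @param outcome `"pga"` or `"das"`.
#' @param n_patients cohort size (default 519).
#' @param seed default RNG seed carried by the specification object.
#' @return A [sim_spec()].
#' @export
default_sim_spec <- function(outcome = c("pga", "das"), n_patients = 519L,
                             seed = 1L) {
  outcome <- match.arg(outcome)
  if (outcome == "pga") {
    sim_spec(outcome = "pga", n_patients = n_patients, seed = seed)
  } else {
    sim_spec(outcome = "das", n_patients = n_patients,
             class_probs = c(0.16, 0.12, 0.72),
             beta = rbind(c(2.10, -0.26, 0.024, -0.0008),
                          c(1.90, 0.04, -0.002, 0.0000),
                          c(1.55, -0.38, 0.048, -0.0019)),
             re_cov = matrix(c(0.04, -0.001, -0.001, 0.0004), 2, 2),
             sigma = 0.26, range_max = 5, severe_class = 2L,
             t0_class_shift = c(0, 0.6, 0), seed = seed)
  }
}

# Solve the feature intercept a so that the marginal prevalence matches:
# sum_g pi_g * plogis(a + logor * [g == severe]) = prev.
solve_feature_intercept <- function(prev, logor, class_probs, severe_class) {
  ind <- as.numeric(seq_along(class_probs) == severe_class)
  f <- function(a) sum(class_probs * plogis(a + logor * ind)) - prev
  stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sim_outcome_values <- function(spec, cls, t, t0_index, centreA) {
  # transformed-scale mean + random effects + noise, then back-transform
  n <- length(cls)
  L <- if (all(spec$re_cov == 0)) matrix(0, 2, 2) else
    t(chol(spec$re_cov + diag(1e-12, 2)))
  b <- matrix(rnorm(2 * n), n, 2) %*% t(L)
  eps_all <- rnorm(length(t), 0, spec$sigma)
  X <- cbind(1, t, t^2, t^3)
  mu <- rowSums(X * spec$beta[cls[t0_index], , drop = FALSE]) +
    spec$gamma_centre * centreA[t0_index]
  ystar <- mu + b[t0_index, 1] + b[t0_index, 2] * t + eps_all
  y <- clip(inverse_transform(pmax(ystar, 0), spec$transform), 0,
            spec$range_max)
  list(y = y, b = b)
}

#' Simulate a synthetic longitudinal cohort
#'
#' Draws a cohort from the generative model in a [sim_spec()]: latent class,
#' centre, demographics and baseline features per patient; a visit schedule;
#' the outcome trajectory on the transformed scale (class mean curve +
#' random intercept/slope + noise) back-transformed and clipped to the
#' instrument range; missing-at-random masking of the outcome; and MCAR
#' missingness in baseline columns. All randomness flows from `seed`.
#'
#' If `das_spec` is supplied, a second outcome (modified DAS) is generated on
#' the same visits from its own, independently drawn latent class, so one
#' cohort carries both trajectories for cross-tabulation.
#'
#' @param spec a [sim_spec()] for the primary outcome.
#' @param das_spec optional [sim_spec()] with `outcome = "das"` for a second
#'   outcome on the same cohort.
#' @param seed integer seed; defaults to `spec$seed`.
#' @return A list with `cohort` (a [cohort()]) and `truth` (per-patient true
#'   class `class` — plus `das_class` if applicable —, random effects `re`,
#'   and the spec).
#' @export
simulate_cohort <- function(spec, das_spec = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(das_spec)) stopifnot(inherits(das_spec, "sim_spec"),
                                    das_spec$outcome == "das")
  set.seed(seed)
  n <- spec$n_patients
  G <- length(spec$class_probs)
  id <- sprintf("P%04d", seq_len(n))

  cls <- sample.int(G, n, replace = TRUE, prob = spec$class_probs)
  centreA <- rbinom(n, 1, spec$centre_prob)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.70, 0.30))
  ethnicity <- sample(c("White", "Black", "South Asian", "Other"), n,
                      replace = TRUE, prob = c(0.774, 0.091, 0.064, 0.071))
  diagnosis <- sample(c("definite_jdm", "probable_jdm", "polymyositis",
                        "jdm_overlap", "other_iim"), n, replace = TRUE,
                      prob = c(0.738, 0.089, 0.019, 0.103, 0.051))
  age <- clip(rlnorm(n, log(7.7), 0.55), 0.5, 16)

  # visit process
  t0 <- clip(rlnorm(n, spec$t0_meanlog + spec$t0_class_shift[cls],
                    spec$t0_sdlog), 0.02, 8)
  fup <- clip(rlnorm(n, spec$followup_meanlog, spec$followup_sdlog),
              spec$followup_range[1], spec$followup_range[2])
  times <- vector("list", n)
  for (i in seq_len(n)) {
    ti <- t0[i]
    repeat {
      gap <- rgamma(1, shape = spec$visit_gap_shape,
                    scale = spec$visit_gap_mean / spec$visit_gap_shape)
      nxt <- ti[length(ti)] + max(gap, 1e-3)
      if (nxt > t0[i] + fup[i]) break
      ti <- c(ti, nxt)
    }
    times[[i]] <- ti
  }
  n_vis <- lengths(times)
  t_all <- unlist(times)
  idx <- rep(seq_len(n), n_vis)

  out <- sim_outcome_values(spec, cls, t_all, idx, centreA)
  y <- out$y

  pga0_true <- if (spec$outcome == "pga") y[cumsum(n_vis) - n_vis + 1] else
    clip(rnorm(n, 3 - 0.0 + 1.2 * (cls == spec$severe_class), 2.2), 0, 10)

  visits <- data.frame(patient_id = id[idx], t = t_all,
                       pga = NA_real_, das = NA_real_,
                       gottron = NA_real_, heliotrope = NA_real_,
                       vasculitis = NA_real_, erythema = NA_real_)
  visits[[spec$outcome]] <- y

  truth <- list(class = cls, re = out$b, spec = spec)

  if (!is.null(das_spec)) {
    das_cls <- sample.int(length(das_spec$class_probs), n, replace = TRUE,
                          prob = das_spec$class_probs)
    das_out <- sim_outcome_values(das_spec, das_cls, t_all, idx, centreA)
    visits$das <- das_out$y
    truth$das_class <- das_cls
  }

  # baseline clinical features, class-dependent via stated log odds ratios
  feats <- matrix(NA_real_, n, length(spec$feature_prev),
                  dimnames = list(NULL, names(spec$feature_prev)))
  sev <- as.numeric(cls == spec$severe_class)
  for (j in names(spec$feature_prev)) {
    a <- solve_feature_intercept(spec$feature_prev[[j]],
                                 spec$feature_logor[[j]],
                                 spec$class_probs, spec$severe_class)
    feats[, j] <- rbinom(n, 1, plogis(a + spec$feature_logor[[j]] * sev))
  }
  cmas0 <- clip(rnorm(n, 40 - 2.5 * sev, 13), 0, 52)
  das0 <- if (!is.null(das_spec)) visits$das[cumsum(n_vis) - n_vis + 1] else
    clip(rnorm(n, 2.9, 1.5), 0, 5)

  baseline <- data.frame(patient_id = id, sex = sex, ethnicity = ethnicity,
                         diagnosis = diagnosis,
                         centre = ifelse(centreA == 1, "A", "Other"),
                         age_at_diagnosis = age, time_to_first_visit = t0,
                         pga0 = pga0_true, cmas0 = cmas0, das0 = das0,
                         arthritis = feats[, "arthritis"],
                         abnormal_respiration = feats[, "abnormal_respiration"],
                         calcinosis = feats[, "calcinosis"],
                         lipodystrophy = feats[, "lipodystrophy"],
                         ulceration = feats[, "ulceration"])

  co <- cohort(baseline, visits)

  # MAR masking of the modelled outcome, driven by true baseline severity
  if (spec$outcome %in% c("pga", "das")) {
    p_miss <- plogis(spec$miss_model[["intercept"]] +
                       spec$miss_model[["pga0"]] * pga0_true[idx] +
                       spec$miss_model[["centreA"]] * centreA[idx])
    mask <- runif(length(t_all)) < p_miss
    co$visits[[spec$outcome]][mask] <- NA_real_
  }

  # MCAR missingness in baseline columns
  for (j in names(spec$baseline_missing_probs)) {
    pj <- spec$baseline_missing_probs[[j]]
    if (pj > 0) co$baseline[[j]][runif(n) < pj] <- NA
  }

  list(cohort = co, truth = truth)
}

#' Mask a visit outcome missing-at-random
#'
#' Independently sets each visit's outcome to missing with probability
#' `plogis(b0 + b1 * pga0 + b2 * centreA)`, emulating outcome missingness
#' driven by baseline severity and recruiting centre. Visit rows are
#' retained with a missing outcome. Patients whose `pga0` is itself missing
#' contribute the cohort mean of `pga0` to the linear predictor.
#'
#' @param x a [cohort()].
#' @param miss_model named vector `(intercept, pga0, centreA)`; `-Inf`
#'   intercept disables masking.
#' @param seed integer seed.
#' @param outcome visit column to mask (default `"pga"`).
#' @return The cohort with masked outcomes.
#' @export
inject_mar_missingness <- function(x, miss_model, seed = 1L,
                                   outcome = "pga") {
  stopifnot(inherits(x, "cohort"), all(is.finite(miss_model[-1])))
  set.seed(seed)
  pga0 <- x$baseline$pga0
  pga0[is.na(pga0)] <- mean(pga0, na.rm = TRUE)
  i <- match(x$visits$patient_id, x$baseline$patient_id)
  eta <- miss_model[["intercept"]] + miss_model[["pga0"]] * pga0[i] +
    miss_model[["centreA"]] * as.numeric(x$baseline$centre[i] == "A")
  mask <- runif(nrow(x$visits)) < plogis(eta)
  x$visits[[outcome]][mask] <- NA_real_
  x
}
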