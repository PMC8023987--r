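#' @useDynLib trajmix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats binomial coef glm glm.fit lm lm.fit median model.matrix
#'   optim plogis predict qlogis quantile rbinom rgamma rlnorm rnorm runif
#'   sd setNames complete.cases pnorm poly qnorm rchisq var
#' @importFrom utils read.csv write.csv
"_PACKAGE"

VISIT_COLUMNS <- c("patient_id", "t", "pga", "das",
                   "gottron", "heliotrope", "vasculitis", "erythema")

BASELINE_COLUMNS <- c("patient_id", "sex", "ethnicity", "diagnosis", "centre",
                      "age_at_diagnosis", "time_to_first_visit",
                      "pga0", "cmas0", "das0",
                      "arthritis", "abnormal_respiration", "calcinosis",
                      "lipodystrophy", "ulceration")

BINARY_FEATURES <- c("arthritis", "abnormal_respiration", "calcinosis",
                     "lipodystrophy", "ulceration")

#' Construct a longitudinal cohort
#'
#' Bundles a per-patient baseline table with a long-format visit table and
#' validates the invariants both must satisfy: every visit belongs to a known
#' patient, every patient has at least one visit, times since diagnosis are
#' non-negative, scores lie in their instrument ranges (PGA 0-10, modified DAS
#' 0-5, CMAS 0-52), and no patient has two visits recorded at the same time.
#'
#' @param baseline data frame with columns `patient_id`, `sex`, `ethnicity`,
#'   `diagnosis`, `centre` (`"A"` or `"Other"`), `age_at_diagnosis`,
#'   `time_to_first_visit`, `pga0`, `cmas0`, `das0` and the binary clinical
#'   features `arthritis`, `abnormal_respiration`, `calcinosis`,
#'   `lipodystrophy`, `ulceration` (0/1/NA). One row per patient.
#' @param visits data frame with columns `patient_id`, `t` (years since
#'   diagnosis), `pga`, `das` and optionally the four skin component scores
#'   `gottron`, `heliotrope`, `vasculitis`, `erythema`. Missing scores are NA.
#' @return An object of class `"cohort"`: a list with elements `baseline` and
#'   `visits` (both data frames, visits sorted by patient then time).
#' @export
cohort <- function(baseline, visits) {
  baseline <- as.data.frame(baseline)
  visits <- as.data.frame(visits)
  for (col in setdiff(VISIT_COLUMNS, names(visits))) visits[[col]] <- NA_real_
  missing_base <- setdiff(c("patient_id"), names(baseline))
  if (length(missing_base))
    stop("baseline table lacks column(s): ", paste(missing_base, collapse = ", "))
  for (col in setdiff(BASELINE_COLUMNS, names(baseline))) baseline[[col]] <- NA
  baseline$patient_id <- as.character(baseline$patient_id)
  visits$patient_id <- as.character(visits$patient_id)
  # all-missing columns read back from CSV as logical; keep scores numeric
  for (col in setdiff(VISIT_COLUMNS, "patient_id"))
    visits[[col]] <- as.numeric(visits[[col]])
  for (col in c("age_at_diagnosis", "time_to_first_visit", "pga0", "cmas0",
                "das0", BINARY_FEATURES))
    baseline[[col]] <- as.numeric(baseline[[col]])

  validate_range <- function(x, lo, hi, what, table) {
    bad <- which(!is.na(x) & (x < lo | x > hi))
    if (length(bad))
      stop(sprintf("%s out of range [%g, %g] in %s row(s) %s (value %g)",
                   what, lo, hi, table, paste(bad, collapse = ", "), x[bad[1]]))
  }
  validate_range(visits$t, 0, Inf, "t", "visits")
  validate_range(visits$pga, 0, 10, "pga", "visits")
  validate_range(visits$das, 0, 5, "das", "visits")
  for (comp in c("gottron", "heliotrope", "vasculitis", "erythema"))
    validate_range(visits[[comp]], 0, Inf, comp, "visits")
  validate_range(baseline$pga0, 0, 10, "pga0", "baseline")
  validate_range(baseline$cmas0, 0, 52, "cmas0", "baseline")
  validate_range(baseline$das0, 0, 5, "das0", "baseline")
  for (feat in BINARY_FEATURES) {
    x <- baseline[[feat]]
    bad <- which(!is.na(x) & !(x %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("%s must be 0/1/NA in baseline row(s) %s", feat,
                   paste(bad, collapse = ", ")))
  }

  if (anyDuplicated(baseline$patient_id))
    stop("duplicate patient_id in baseline: ",
         paste(unique(baseline$patient_id[duplicated(baseline$patient_id)]),
               collapse = ", "))
  orphans <- setdiff(unique(visits$patient_id), baseline$patient_id)
  if (length(orphans))
    stop("visit(s) reference unknown patient_id: ",
         paste(orphans, collapse = ", "))
  no_visit <- setdiff(baseline$patient_id, unique(visits$patient_id))
  if (length(no_visit))
    stop("patient(s) without any visit: ", paste(no_visit, collapse = ", "))
  key <- paste(visits$patient_id, visits$t)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, t) visit rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))

  visits <- visits[order(visits$patient_id, visits$t), , drop = FALSE]
  rownames(visits) <- NULL
  rownames(baseline) <- NULL
  structure(list(baseline = baseline, visits = visits), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, %d visits, follow-up %.1f-%.1f y\n",
              nrow(x$baseline), nrow(x$visits),
              min(x$visits$t), max(x$visits$t)))
  n_pga <- sum(!is.na(x$visits$pga)); n_das <- sum(!is.na(x$visits$das))
  cat(sprintf("  PGA observed at %d visits, modified DAS at %d\n", n_pga, n_das))
  invisible(x)
}

#' Read a cohort from baseline and visit CSV files
#'
#' Both files are plain UTF-8 comma-separated text with a header row; missing
#' values may be encoded as an empty field or as `NA`. Scores are validated on
#' load and an error names the offending row; missing values are preserved,
#' never imputed.
#'
#' @param baseline_path path to the per-patient baseline CSV.
#' @param visits_path path to the long-format visits CSV
#'   (`patient_id,t,pga,das,gottron,heliotrope,vasculitis,erythema`).
#' @return A validated [cohort()].
#' @export
read_cohort <- function(baseline_path, visits_path) {
  for (p in c(baseline_path, visits_path))
    if (!file.exists(p)) stop("file not found: ", p)
  read1 <- function(path, required) {
    df <- read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
    unknown <- setdiff(names(df), required)
    if (length(unknown))
      stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
    df
  }
  cohort(read1(baseline_path, BASELINE_COLUMNS),
         read1(visits_path, VISIT_COLUMNS))
}

#' Write a cohort to baseline and visit CSV files
#'
#' Inverse of [read_cohort()]: missing values are written as empty fields.
#'
#' @param x a [cohort()].
#' @param baseline_path,visits_path output file paths.
#' @return `x`, invisibly.
#' @export
write_cohort <- function(x, baseline_path, visits_path) {
  stopifnot(inherits(x, "cohort"))
  write.csv(x$baseline[BASELINE_COLUMNS], baseline_path,
            row.names = FALSE, na = "")
  write.csv(x$visits[VISIT_COLUMNS], visits_path, row.names = FALSE, na = "")
  invisible(x)
}

#' Truncate follow-up at a horizon
#'
#' Drops visits recorded after `horizon_years` since diagnosis. The boundary
#' is closed: a visit at exactly the horizon is retained. Patients left with
#' no visits are removed from the baseline table; their count is attached as
#' attribute `n_dropped_patients`.
#'
#' @param x a [cohort()].
#' @param horizon_years positive truncation horizon in years (default 10).
#' @return A truncated [cohort()].
#' @export
truncate_followup <- function(x, horizon_years = 10) {
  stopifnot(inherits(x, "cohort"), horizon_years > 0)
  keep <- x$visits$t <= horizon_years
  visits <- x$visits[keep, , drop = FALSE]
  kept_ids <- unique(visits$patient_id)
  dropped <- setdiff(x$baseline$patient_id, kept_ids)
  baseline <- x$baseline[x$baseline$patient_id %in% kept_ids, , drop = FALSE]
  out <- cohort(baseline, visits)
  attr(out, "n_dropped_patients") <- length(dropped)
  out
}

#' Compose the modified skin DAS from its component scores
#'
#' The modified skin Disease Activity Score sums four cutaneous components
#' (Gottron's papules, heliotrope rash, vasculitis, erythema) to a 0-5 range.
#' A missing component is treated as absent (contributes 0), which avoids
#' imputing the score but can underestimate it; the returned `flag` records
#' whether any component was missing so that rule's effect is traceable.
#'
#' @param components named numeric vector or list with entries `gottron`,
#'   `heliotrope`, `vasculitis`, `erythema`; values may be NA.
#' @param maxima named vector of per-component maxima. The instrument's 0-5
#'   total is the sum of the defaults `c(1, 1, 1, 2)`.
#' @return list with `score` (sum of present components, capped at the sum of
#'   `maxima`) and `flag` (TRUE if any component was missing).
#' @export
compose_modified_das <- function(components,
                                 maxima = c(gottron = 1, heliotrope = 1,
                                            vasculitis = 1, erythema = 2)) {
  comp <- unlist(components)[names(maxima)]
  names(comp) <- names(maxima)
  if (any(!is.na(comp) & comp < 0))
    stop("negative modified-DAS component: ",
         paste(names(comp)[!is.na(comp) & comp < 0], collapse = ", "))
  flag <- any(is.na(comp))
  score <- min(sum(comp, na.rm = TRUE), sum(maxima))
  list(score = score, flag = flag)
}

#' Transform an outcome to the modelling scale (and back)
#'
#' The mixture models operate on a transformed outcome; the square-root
#' transform of PGA and modified DAS gives approximately Gaussian residuals
#' for these bounded, right-skewed activity scores. `inverse_transform`
#' undoes `transform_outcome` exactly, so predicted medians back-transform
#' through the monotone map.
#'
#' @param y numeric vector on the original scale (non-negative for `"sqrt"`).
#' @param transform `"identity"` or `"sqrt"`.
#' @return Transformed (resp. back-transformed) numeric vector.
#' @export
transform_outcome <- function(y, transform = c("sqrt", "identity")) {
  transform <- match.arg(transform)
  if (transform == "identity") return(y)
  if (any(!is.na(y) & y < 0)) stop("negative value passed to sqrt transform")
  sqrt(y)
}

#' @rdname transform_outcome
#' @param y_star numeric vector on the transformed scale.
#' @export
inverse_transform <- function(y_star, transform = c("sqrt", "identity")) {
  transform <- match.arg(transform)
  if (transform == "identity") y_star else y_star^2
}
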