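test_that("latent class fractions match the simplex within binomial noise", {
  spec <- default_sim_spec("pga", 5000)
  sim <- simulate_cohort(spec, seed = 123)
  frac1 <- mean(sim$truth$class == 1)
  se <- sqrt(0.89 * 0.11 / 5000)
  expect_lt(abs(frac1 - 0.89), 3 * se)
})

test_that("noise-free limit reproduces the class mean curves exactly", {
  spec <- sim_spec(outcome = "pga", n_patients = 20,
                   re_cov = matrix(0, 2, 2), sigma = 0,
                   miss_model = c(intercept = -Inf, pga0 = 0, centreA = 0),
                   baseline_missing_probs = c(pga0 = 0))
  sim <- simulate_cohort(spec, seed = 9)
  # beyond the horizon the class means leave the instrument range and are
  # clipped; within it they are interior, so the identity is exact
  v <- truncate_followup(sim$cohort, 10)$visits
  i <- match(v$patient_id, sim$cohort$baseline$patient_id)
  cls <- sim$truth$class[i]
  centreA <- as.numeric(sim$cohort$baseline$centre[i] == "A")
  mu <- rowSums(cbind(1, v$t, v$t^2, v$t^3) * spec$beta[cls, ]) +
    spec$gamma_centre * centreA
  expect_equal(sqrt(v$pga), mu, tolerance = 1e-12)
})

test_that("the same seed reproduces the cohort exactly", {
  a <- simulate_cohort(default_sim_spec("pga", 80), seed = 5)
  b <- simulate_cohort(default_sim_spec("pga", 80), seed = 5)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$class, b$truth$class)
  c_ <- simulate_cohort(default_sim_spec("pga", 80), seed = 6)
  expect_false(identical(a$cohort$visits$pga, c_$cohort$visits$pga))
})

test_that("simulation spec validation rejects bad inputs", {
  expect_error(sim_spec(class_probs = c(0.5, 0.4)), "summing to 1")
  expect_error(sim_spec(re_cov = matrix(c(1, 2, 2, 1), 2, 2)),
               "positive-semidefinite")
  expect_error(sim_spec(beta = matrix(0, 3, 4)), "matrix")
})

test_that("MAR masking hits the target rate with no covariate effects", {
  spec <- sim_spec(outcome = "pga", n_patients = 800,
                   miss_model = c(intercept = -Inf, pga0 = 0, centreA = 0))
  sim <- simulate_cohort(spec, seed = 21)
  expect_false(anyNA(sim$cohort$visits$pga))   # -Inf intercept: no masking
  masked <- inject_mar_missingness(sim$cohort,
                                   c(intercept = qlogis(0.13), pga0 = 0,
                                     centreA = 0), seed = 2)
  n_vis <- nrow(masked$visits)
  expect_gt(n_vis, 1e4)
  rate <- mean(is.na(masked$visits$pga))
  expect_lt(abs(rate - 0.13), 3 * sqrt(0.13 * 0.87 / n_vis))
})

test_that("missingness increases with baseline severity when b1 > 0", {
  spec <- sim_spec(outcome = "pga", n_patients = 700,
                   miss_model = c(intercept = -Inf, pga0 = 0, centreA = 0))
  sim <- simulate_cohort(spec, seed = 31)
  masked <- inject_mar_missingness(sim$cohort,
                                   c(intercept = -2.5, pga0 = 0.6,
                                     centreA = 0), seed = 3)
  b <- masked$baseline
  tert <- cut(b$pga0, quantile(b$pga0, c(0, 1/3, 2/3, 1), na.rm = TRUE),
              include.lowest = TRUE, labels = FALSE)
  rate_by <- vapply(1:3, function(k) {
    ids <- b$patient_id[which(tert == k)]
    mean(is.na(masked$visits$pga[masked$visits$patient_id %in% ids]))
  }, numeric(1))
  expect_true(all(diff(rate_by) > 0))
})

test_that("baseline feature prevalence and missingness track the generator settings", {
  spec <- default_sim_spec("pga", 4000)
  sim <- simulate_cohort(spec, seed = 77)
  b <- sim$cohort$baseline
  for (f in names(spec$feature_prev)) {
    prev <- mean(b[[f]], na.rm = TRUE)
    expect_lt(abs(prev - spec$feature_prev[[f]]), 0.03)
    miss <- mean(is.na(b[[f]]))
    expect_lt(abs(miss - spec$baseline_missing_probs[[f]]), 0.03)
  }
  # log odds ratio of abnormal respiration for the severe class near ln(1.91)
  fit <- glm(b$abnormal_respiration ~ I(sim$truth$class == 2),
             family = binomial())
  expect_lt(abs(coef(fit)[2] - log(1.91)), 3 * sqrt(vcov(fit)[2, 2]))
})

test_that("a joint cohort carries both outcomes on the same visits", {
  sim <- simulate_cohort(default_sim_spec("pga", 60),
                         das_spec = default_sim_spec("das", 60), seed = 4)
  v <- sim$cohort$visits
  expect_true(any(!is.na(v$pga)))
  expect_true(all(!is.na(v$das)))
  expect_true(all(v$das <= 5))
  expect_length(sim$truth$das_class, 60)
})
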