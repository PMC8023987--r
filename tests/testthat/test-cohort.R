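test_that("CSV round-trip preserves every field including missing values", {
  co <- tiny_cohort()
  co$visits$pga[2] <- NA
  co$baseline$cmas0[1] <- NA
  co <- cohort(co$baseline, co$visits)
  bp <- withr::local_tempfile(fileext = ".csv")
  vp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, bp, vp)
  back <- read_cohort(bp, vp)
  expect_equal(back$baseline, co$baseline)
  expect_equal(back$visits, co$visits)
  expect_equal(nrow(back$baseline), 2)
  expect_equal(as.integer(table(back$visits$patient_id)), c(3L, 3L))
})

test_that("validation names the offending rows", {
  v <- tiny_visits()
  v$pga[4] <- 11
  expect_error(cohort(tiny_baseline(), v), "pga.*row.*4")
  v <- tiny_visits()
  v$patient_id[6] <- "GHOST"
  expect_error(cohort(tiny_baseline(), v), "GHOST")
  v <- tiny_visits()
  v$t[2] <- v$t[1]
  expect_error(cohort(tiny_baseline(), v), "duplicate")
  b <- tiny_baseline()
  b$arthritis[1] <- 2
  expect_error(cohort(b, tiny_visits()), "arthritis")
})

test_that("follow-up truncation keeps the closed boundary and is idempotent", {
  b <- tiny_baseline("A1")
  v <- data.frame(patient_id = "A1", t = c(0.5, 10.0, 10.1),
                  pga = c(3, 2, 1), das = NA_real_, gottron = NA_real_,
                  heliotrope = NA_real_, vasculitis = NA_real_,
                  erythema = NA_real_)
  co <- cohort(b, v)
  tr <- truncate_followup(co, 10)
  expect_equal(tr$visits$t, c(0.5, 10.0))
  expect_equal(truncate_followup(tr, 10)$visits, tr$visits)
  expect_equal(truncate_followup(co, Inf)$visits, co$visits)
})

test_that("truncation drops exactly the visits a direct count would", {
  set.seed(11)
  n <- 60
  b <- tiny_baseline(sprintf("P%02d", 1:n))
  v <- data.frame(patient_id = rep(b$patient_id, each = 8),
                  t = runif(8 * n, 0, 20), pga = 2, das = NA_real_,
                  gottron = NA_real_, heliotrope = NA_real_,
                  vasculitis = NA_real_, erythema = NA_real_)
  co <- cohort(b, v)
  tr <- truncate_followup(co, 10)
  expect_equal(nrow(tr$visits), sum(co$visits$t <= 10))
  expect_lte(nrow(tr$visits), nrow(co$visits))
  # patients whose visits all fall beyond the horizon leave the baseline too
  expect_setequal(tr$baseline$patient_id, unique(tr$visits$patient_id))
})

test_that("modified DAS composition treats missing components as absent", {
  expect_equal(compose_modified_das(c(gottron = NA, heliotrope = NA,
                                      vasculitis = NA, erythema = NA)),
               list(score = 0, flag = TRUE))
  expect_equal(compose_modified_das(c(gottron = 1, heliotrope = 1,
                                      vasculitis = 0, erythema = 2)),
               list(score = 4, flag = FALSE))
  expect_equal(compose_modified_das(c(gottron = 1, heliotrope = NA,
                                      vasculitis = 1, erythema = NA)),
               list(score = 2, flag = TRUE))
  expect_error(compose_modified_das(c(gottron = -1, heliotrope = 0,
                                      vasculitis = 0, erythema = 0)),
               "negative")
})

test_that("modified DAS is capped at 5 and monotone in each component", {
  expect_equal(compose_modified_das(c(gottron = 3, heliotrope = 3,
                                      vasculitis = 3, erythema = 3))$score, 5)
  set.seed(2)
  for (rep in 1:20) {
    comp <- runif(4, 0, 1.5)
    names(comp) <- c("gottron", "heliotrope", "vasculitis", "erythema")
    base <- compose_modified_das(comp)$score
    for (j in 1:4) {
      bumped <- comp
      bumped[j] <- bumped[j] + 0.5
      expect_gte(compose_modified_das(bumped)$score, base)
    }
  }
})

test_that("outcome transforms invert exactly", {
  expect_equal(transform_outcome(0, "sqrt"), 0)
  expect_equal(transform_outcome(4, "sqrt"), 2)
  expect_equal(inverse_transform(2, "sqrt"), 4)
  expect_error(transform_outcome(-1, "sqrt"), "negative")
  y <- seq(0, 10, length.out = 101)
  expect_equal(inverse_transform(transform_outcome(y, "sqrt"), "sqrt"), y,
               tolerance = 1e-12)
  expect_identical(transform_outcome(y, "identity"), y)
})
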