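test_that("design matrices encode conjunctions and reduce without rules", {
  set.seed(1)
  co <- schema_cohort(matrix(rbinom(13 * 8, 1, 0.4), 8, 13,
                             dimnames = list(NULL, clhls_conditions())))
  co$hypertension <- c(1L, rep(0L, 7))
  co$tooth_loss <- rep(0L, 8)
  d <- build_design(co, "hypertension:tooth_loss")
  expect_true(all(d$x[, "hypertension:tooth_loss"] == 0))
  co$tooth_loss[1] <- 1L
  d <- build_design(co, "hypertension:tooth_loss")
  expect_identical(d$x[, "hypertension:tooth_loss"], c(1, rep(0, 7)))

  d0 <- build_design(co, NULL)
  expect_identical(colnames(d0$x), c("age", "male", clhls_conditions()))
  d13 <- build_design(co, paste(clhls_conditions()[1:13],
                                c(clhls_conditions()[2:13],
                                  clhls_conditions()[1]), sep = ":"))
  expect_equal(ncol(d13$x), 2 + 13 + 13)
  expect_error(build_design(co, "hypertension:no_such"), "not in the cohort")
})

test_that("fit_cox matches an independent Efron partial-likelihood optimiser", {
  # fixed 20-row dataset with tied event times to exercise the tie correction
  x <- cbind(z1 = c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0, 1, 1, 0, 0, 1),
             z2 = c(0.5, -1, 2, 0, 1.5, -0.5, 1, -2, 0, 0.7,
                    -0.3, 1.2, 0.1, -1.5, 0.9, 0.2, -0.8, 1.8, -0.1, 0.4))
  time <- c(1, 2, 2, 3, 3, 3, 4, 4.5, 5, 5, 1.5, 2.5, 3.5, 4, 1, 2, 3, 4, 5, 2.5)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0, 0, 1)
  fit <- fit_cox(x, time, event, horizon = 10)
  beta_oracle <- oracle_cox_efron(x, pmin(time, 10), event)
  expect_equal(unname(fit$coefficients), beta_oracle, tolerance = 1e-4)
  expect_equal(fit$hazard_ratios, exp(fit$coefficients))
  expect_true(all(fit$ci95[, "low"] <= fit$hazard_ratios &
                  fit$hazard_ratios <= fit$ci95[, "high"]))
  expect_true(fit$s0_horizon > 0 && fit$s0_horizon <= 1)
})

test_that("fit_cox recovers a known hazard ratio and drops constant columns", {
  cfg <- generator_config(8000L, prevalences = c(z = 0.5),
                          log_hazards = c(z = log(1.5)),
                          baseline_rate = 0.05, ltfu_rate = 0.03)
  co <- generate_cohort(cfg, seed = 21)
  fit <- fit_cox(cbind(z = co$z), co$time, co$event)
  expect_lt(abs(fit$coefficients[["z"]] - log(1.5)), 0.1)

  expect_warning(
    fit2 <- fit_cox(cbind(z = co$z, flat = rep(1, nrow(co))),
                    co$time, co$event),
    "constant")
  expect_named(fit2$coefficients, "z")

  # perfect separation is reported as an error naming the predictor
  sep <- data.frame(bad = c(rep(1, 30), rep(0, 30)),
                    time = c(runif(30, 0.1, 1), runif(30, 4, 5)),
                    event = c(rep(1, 30), rep(0, 30)))
  expect_error(
    suppressWarnings(fit_cox(cbind(bad = sep$bad), sep$time, sep$event)),
    "bad")
})

test_that("null-covariate confidence intervals achieve nominal coverage", {
  covered <- 0L
  for (r in 1:100) {
    cfg <- generator_config(8000L, prevalences = c(z = 0.5, w = 0.3),
                            log_hazards = c(w = log(1.4)),
                            baseline_rate = 0.04, ltfu_rate = 0.03)
    co <- generate_cohort(cfg, seed = 1000 + r)
    fit <- fit_cox(cbind(z = co$z, w = co$w), co$time, co$event)
    ci <- fit$ci95["z", ]
    if (ci[["low"]] <= 1 && 1 <= ci[["high"]]) covered <- covered + 1L
  }
  expect_gte(covered, 90)
})

test_that("hazard ratios map to integer weights by the half-open bins", {
  hrs <- c(a = 1.10, b = 1.35, c = 1.62, d = 1.00, e = 0.85,
           f = 1.199999, g = 1.2, h = 1.499999, i = 1.5, age = 2, male = 1.3)
  m <- hazard_model(log(hrs))
  w <- assign_weights(m)
  expect_identical(unclass(w)[c("a", "b", "c", "d", "e", "f", "g", "h", "i")],
                   c(a = 1L, b = 2L, c = 3L, d = 1L, e = 0L,
                     f = 1L, g = 2L, h = 2L, i = 3L))
  expect_false(any(c("age", "male") %in% names(w)))
})

test_that("index scoring sums weights over present predictors", {
  idx <- multimorbidity_index("MIDC", c(
    diabetes = 3L, lung_disease = 2L, "lung_disease:sensory_impairment" = 1L))
  expect_equal(idx$max_score, 6)
  prof <- matrix(0L, 3, 13, dimnames = list(NULL, clhls_conditions()))
  prof[2, c("diabetes", "lung_disease", "sensory_impairment")] <- 1L
  prof[3, ] <- 1L
  co <- schema_cohort(prof)
  expect_identical(score_index(idx, co), c(0L, 6L, 6L))

  cc <- condition_count_index()
  expect_equal(cc$max_score, 13)
  expect_identical(condition_count(co), c(0L, 3L, 13L))
  expect_identical(score_index(cc, co), condition_count(co))

  expect_error(multimorbidity_index("x", c(age = 1L)), "never weighted")
  expect_error(multimorbidity_index("x", c(a = 4L)), "0, 1, 2, 3")
})

test_that("scores are monotone in conditions and bounded by max_score", {
  set.seed(17)
  w <- setNames(sample(0:3, 16, replace = TRUE),
                c(clhls_conditions(),
                  "hypertension:depressive_symptoms",
                  "sensory_impairment:cognitive_impairment",
                  "hypertension:tooth_loss"))
  idx <- multimorbidity_index("MIDC", w)
  prof <- matrix(rbinom(13 * 50, 1, 0.3), 50, 13,
                 dimnames = list(NULL, clhls_conditions()))
  co <- schema_cohort(prof)
  s <- score_index(idx, co)
  expect_true(all(s >= 0 & s <= idx$max_score))
  for (r in 1:20) {
    i <- sample(50, 1); j <- sample(clhls_conditions(), 1)
    co2 <- co
    co2[[j]][i] <- 1L
    expect_gte(score_index(idx, co2)[i], s[i])
  }
  # an all-conditions participant attains max_score
  co_all <- schema_cohort(matrix(1L, 1, 13,
                                 dimnames = list(NULL, clhls_conditions())))
  expect_equal(score_index(idx, co_all), idx$max_score)
})

test_that("MI is the combination pipeline run with an empty rule set", {
  cfg <- default_clhls_config(n_participants = 3000L)
  co <- generate_cohort(cfg, seed = 4)
  dev <- develop_indices(co, rules = character(0))
  expect_identical(dev$mi$weights, dev$midc$weights)
  expect_identical(dev$model1$coefficients, dev$model2$coefficients)
})

test_that("indices round-trip through JSON", {
  idx <- multimorbidity_index("MI", c(diabetes = 3L, cancer = 2L,
                                      "hypertension:tooth_loss" = 1L))
  f <- withr::local_tempfile(fileext = ".json")
  write_index(idx, f)
  expect_equal(read_index(f), idx)
})
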