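test_that("predicted 5-year risk follows the closed form", {
  m <- hazard_model(c(age = 0, male = 0), s0_horizon = 0.8)
  co <- data.frame(id = 1:5, age = 65:69, male = c(0, 1, 0, 1, 0),
                   time = 5, event = 0)
  expect_equal(predict_risk5(m, co), rep(1 - 0.8, 5))

  beta <- c(age = 0.05, male = 0.3)
  m2 <- hazard_model(beta, means = c(age = 67, male = 0.4), s0_horizon = 0.8)
  lp <- 0.05 * (co$age - 67) + 0.3 * (co$male - 0.4)
  expect_equal(predict_risk5(m2, co), 1 - 0.8^exp(lp), tolerance = 1e-12)

  # monotone in a positively weighted score
  m3 <- hazard_model(c(score = 0.2), s0_horizon = 0.9)
  co3 <- data.frame(id = 1:3, age = 70, male = 0, score = c(0, 1, 5),
                    time = 5, event = 0)
  expect_true(all(diff(predict_risk5(m3, co3)) > 0))

  expect_error(predict_risk5(m3, co), "missing predictor")
  expect_error(predict_risk5(hazard_model(c(age = 0)), co),
               "baseline survival")
})

test_that("concordance matches hand enumeration and the all-pairs oracle", {
  # constant risk: every comparable pair is a risk tie
  expect_equal(harrell_c(c(1, 2, 3, 4), c(1, 1, 1, 0), rep(0.3, 4)), 0.5)
  # uncensored, risk order exactly reverses survival order
  tm <- c(5, 3, 8, 1, 2)
  expect_equal(harrell_c(tm, rep(1, 5), -tm), 1.0)
  # six-subject toy with censoring, a tied event time (subjects 2, 3) and
  # a risk tie (subjects 5, 6), enumerated by hand: 13 comparable pairs,
  # 11 concordant, the time-tie and the risk-tie pair at half credit
  time <- c(1, 2, 2, 3, 4, 5)
  event <- c(1, 1, 1, 0, 1, 0)
  risk <- c(0.9, 0.7, 0.7, 0.5, 0.6, 0.6)
  expect_equal(harrell_c(time, event, risk), (11 + 0.5 * 2) / 13)
  expect_equal(harrell_c(time, event, risk),
               oracle_harrell_c(time, event, risk))

  set.seed(8)
  for (rep in 1:20) {
    n <- sample(20:120, 1)
    tm <- round(runif(n, 0.1, 5), 1)     # force some ties
    ev <- rbinom(n, 1, 0.5)
    rk <- round(runif(n), 2)
    if (sum(ev) == 0) ev[1] <- 1L
    expect_equal(harrell_c(tm, ev, rk), oracle_harrell_c(tm, ev, rk))
  }
  # agreement with the survival package on tie-free data
  set.seed(9)
  n <- 300
  tm <- rexp(n); ev <- rbinom(n, 1, 0.6); rk <- runif(n)
  cidx <- survival::concordance(survival::Surv(tm, ev) ~ rk,
                                reverse = TRUE)$concordance
  expect_equal(harrell_c(tm, ev, rk), cidx, tolerance = 1e-12)

  expect_error(harrell_c(c(1, 2), c(0, 0), c(0.1, 0.2)), "comparable")
})

test_that("concordance comparison behaves under self- and informative contrasts", {
  set.seed(10)
  co <- random_cohort(150, k = 2)
  r <- runif(150)
  self <- compare_c(r, r, co, resamples = 60, seed = 1)
  expect_equal(self$delta_c, 0)
  expect_equal(self$p, 1)

  none <- compare_c(r, runif(150), co, resamples = 0, seed = 1)
  expect_true(is.na(none$p))

  # an informative one-point index raises C over the base model
  cfg <- generator_config(3500L, prevalences = c(z = 0.4),
                          log_hazards = c(z = log(2.2)),
                          baseline_rate = 0.05, ltfu_rate = 0.03,
                          age_log_hazard = log(1.05),
                          sex_log_hazard = log(1.3))
  co2 <- generate_cohort(cfg, seed = 77)
  base <- fit_cox(cbind(age = co2$age, male = co2$male), co2$time, co2$event)
  with_z <- fit_cox(cbind(age = co2$age, male = co2$male, z = co2$z),
                    co2$time, co2$event)
  cmp <- compare_c(base, with_z, co2, resamples = 0)
  expect_gt(cmp$delta_c, 0)

  # bootstrap p-values are reproducible under a fixed seed
  r2 <- r + runif(150, -0.05, 0.05)
  a <- compare_c(r, r2, co, resamples = 40, seed = 5)
  b <- compare_c(r, r2, co, resamples = 40, seed = 5)
  expect_identical(a$p, b$p)
  expect_identical(a$delta_c, b$delta_c)
})

test_that("IDI equals the discrimination-slope difference and is antisymmetric", {
  outcome <- c(1, 1, 0, 0)
  new <- c(0.9, 0.7, 0.2, 0.4)
  old <- c(0.6, 0.6, 0.4, 0.4)
  got <- idi(old, new, outcome, resamples = 0)
  expect_equal(got$idi, 0.3)
  expect_equal(idi(new, old, outcome, resamples = 0)$idi, -0.3)
  expect_equal(idi(old, old, outcome, resamples = 0)$idi, 0)

  # decomposition identity recomputed independently on random inputs
  set.seed(20)
  for (rep in 1:10) {
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    ro <- runif(60); rn <- runif(60)
    slope <- function(r) mean(r[y == 1]) - mean(r[y == 0])
    expect_equal(idi(ro, rn, y, resamples = 0)$idi,
                 slope(rn) - slope(ro), tolerance = 1e-12)
    expect_lte(abs(idi(ro, rn, y, resamples = 0)$idi), 1)
  }
  expect_error(idi(c(0.1, 0.2), c(0.2, 0.3), c(1, 1), resamples = 0),
               "both outcome classes")
})

test_that("continuous NRI tallies strict up/down movements with ties as zero", {
  y <- c(1, 1, 0, 0)
  expect_equal(continuous_nri(c(0.5, 0.5, 0.5, 0.5), c(0.5, 0.5, 0.5, 0.5),
                              y, resamples = 0)$nri, 0)
  # every event up, every non-event down: maximal value 2
  expect_equal(continuous_nri(c(0.4, 0.4, 0.4, 0.4), c(0.6, 0.6, 0.2, 0.2),
                              y, resamples = 0)$nri, 2)
  # 8-subject toy, hand-tallied: events 3 up / 1 down -> 0.5;
  # non-events 2 down / 1 up / 1 tie -> 0.25; total 0.75
  y8 <- c(1, 1, 1, 1, 0, 0, 0, 0)
  old8 <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  new8 <- c(0.6, 0.7, 0.8, 0.4, 0.3, 0.2, 0.6, 0.5)
  got <- continuous_nri(old8, new8, y8, resamples = 0)
  expect_equal(got$nri, 0.75)
  expect_equal(got$nri, oracle_nri(old8, new8, y8))

  set.seed(21)
  for (rep in 1:10) {
    y <- rbinom(50, 1, 0.5)
    if (length(unique(y)) < 2) next
    ro <- round(runif(50), 1); rn <- round(runif(50), 1)
    v <- continuous_nri(ro, rn, y, resamples = 0)$nri
    expect_equal(v, oracle_nri(ro, rn, y))
    expect_true(v >= -2 && v <= 2)
  }
})

test_that("five-year class treats early censoring as unknown", {
  co <- data.frame(id = 1:4, age = 70, male = 0,
                   time = c(2, 5, 3, 6), event = c(1L, 0L, 0L, 1L))
  expect_identical(five_year_class(co, 5), c(1L, 0L, NA_integer_, 0L))
})

test_that("Cronbach's alpha follows the variance formula", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  expect_equal(cronbach_alpha(x), 1)

  toy <- cbind(c(1, 2, 1, 0, 3), c(2, 2, 1, 1, 3), c(0, 1, 2, 1, 2))
  k <- 3
  by_hand <- k / (k - 1) *
    (1 - sum(apply(toy, 2, var)) / var(rowSums(toy)))
  expect_equal(cronbach_alpha(toy), by_hand)

  set.seed(30)
  ind <- matrix(rnorm(10000 * 4), ncol = 4)
  expect_lt(abs(cronbach_alpha(ind)), 0.05)

  expect_error(cronbach_alpha(cbind(c(1, 1), c(2, 2))), "zero variance")
  expect_error(cronbach_alpha(matrix(1:5, ncol = 1)), "at least 2")
})

test_that("item scores decompose the index score", {
  idx <- multimorbidity_index("MIDC", c(diabetes = 3L, cancer = 2L,
                                        "hypertension:tooth_loss" = 1L,
                                        arthritis = 0L))
  set.seed(31)
  co <- schema_cohort(matrix(rbinom(13 * 40, 1, 0.4), 40, 13,
                             dimnames = list(NULL, clhls_conditions())))
  items <- index_item_scores(idx, co)
  expect_identical(colnames(items),
                   c("diabetes", "cancer", "hypertension:tooth_loss"))
  expect_identical(as.integer(rowSums(items)), score_index(idx, co))
})

test_that("Pearson validity matches direct computation", {
  a <- c(1, 3, 2, 5, 4, 6)
  expect_equal(pearson_validity(a, 2 * a)$r, 1)
  expect_equal(pearson_validity(a, -a)$r, -1)
  b <- c(2, 1, 4, 4, 6, 5)
  got <- pearson_validity(a, b)
  expect_equal(got$r, cov(a, b) / (sd(a) * sd(b)))
  expect_equal(got$p, cor.test(a, b)$p.value)
  expect_error(pearson_validity(a, rep(1, 6)), "constant")
})
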