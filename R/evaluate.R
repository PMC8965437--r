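#' Predicted 5-year event probability from a fitted hazard model
#'
#' `risk = 1 - S0(h)^exp(lp)` where `S0(h)` is the baseline survival at
#' the horizon (at the model's centring point) and `lp` is the linear
#' predictor centred as in the fit. Deterministic.
#'
#' @param fitted A `fitted_hazard_model` with a recorded `s0_horizon`.
#' @param cohort A cohort `data.frame` from which every model predictor
#'   (age, sex, conditions, pair conjunctions, or index scores already
#'   present as columns) can be derived.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_risk5 <- function(fitted, cohort) {
  stopifnot(inherits(fitted, "fitted_hazard_model"))
  if (is.null(fitted$s0_horizon)) stop("model lacks a baseline survival")
  covs <- fitted$spec$covariates
  lp <- numeric(nrow(cohort))
  for (nm in covs) {
    xj <- if (nm %in% colnames(cohort)) {
      cohort[[nm]]
    } else if (is_pair_name(nm)) {
      ab <- pair_members(nm)
      if (!all(ab %in% colnames(cohort))) stop("missing predictor: ", nm)
      cohort[[ab[1]]] * cohort[[ab[2]]]
    } else {
      stop("missing predictor: ", nm)
    }
    lp <- lp + fitted$coefficients[[nm]] * (xj - fitted$means[[nm]])
  }
  1 - fitted$s0_horizon^exp(lp)
}

#' Harrell's concordance statistic for censored survival data
#'
#' A pair is comparable iff the smaller observed time belongs to an
#' event (pairs with equal observed times are comparable only when both
#' are events). A comparable pair is concordant when the participant
#' with the earlier event has the higher predicted risk; risk ties and
#' equal-time event pairs receive half credit:
#' `C = (concordant + 0.5 * ties) / comparable`.
#'
#' @param time Observed follow-up times.
#' @param event 0/1 event indicators.
#' @param risk Predicted risks (higher = worse prognosis).
#' @return C in `[0, 1]`.
#' @export
harrell_c <- function(time, event, risk) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk) == n)
  ev <- which(event == 1)
  if (length(ev) == 0) stop("no comparable pairs: no events")
  concordant <- 0; tied <- 0; comparable <- 0
  for (i in ev) {
    later <- time > time[i]
    m <- sum(later)
    if (m > 0) {
      comparable <- comparable + m
      r <- risk[later]
      concordant <- concordant + sum(risk[i] > r)
      tied <- tied + sum(risk[i] == r)
    }
    same <- time == time[i] & event == 1 & seq_len(n) > i
    k <- sum(same)
    if (k > 0) {
      comparable <- comparable + k
      tied <- tied + k  # no earlier event in the pair: half credit
    }
  }
  if (comparable == 0) stop("no comparable pairs")
  (concordant + 0.5 * tied) / comparable
}

risks_from <- function(model, cohort) {
  if (is.numeric(model)) model else predict_risk5(model, cohort)
}

# Two-sided p-value of a statistic against 0 from its bootstrap draws.
bootstrap_p <- function(stat, draws) {
  if (length(draws) == 0) return(NA_real_)
  min(1, 2 * min(mean(draws <= 0), mean(draws >= 0)))
}

#' Compare the concordance of two risk models
#'
#' `delta_c = C_new - C_old` on the evaluation cohort, with a two-sided
#' p-value from the participant-level nonparametric bootstrap
#' distribution of the difference (risks held fixed per participant;
#' both statistics recomputed on each resample).
#'
#' @param model_old,model_new Either `fitted_hazard_model`s or numeric
#'   risk vectors aligned with `cohort`.
#' @param cohort Evaluation cohort.
#' @param resamples Bootstrap resamples (default 1000); 0 returns the
#'   difference with `p = NA`.
#' @param seed Integer seed for the bootstrap.
#' @param horizon Horizon at which times are administratively censored
#'   before computing C.
#' @return A list with `c_old`, `c_new`, `delta_c`, `p`, `n_eval`,
#'   `resamples`.
#' @export
compare_c <- function(model_old, model_new, cohort, resamples = 1000L,
                      seed = 1L, horizon = 5.0) {
  r_old <- risks_from(model_old, cohort)
  r_new <- risks_from(model_new, cohort)
  time5 <- pmin(cohort$time, horizon)
  event5 <- as.integer(cohort$event == 1 & cohort$time <= horizon)
  c_old <- harrell_c(time5, event5, r_old)
  c_new <- harrell_c(time5, event5, r_new)
  n <- nrow(cohort)
  draws <- numeric(0)
  if (resamples > 0) {
    set.seed(as.integer(seed))
    draws <- vapply(seq_len(resamples), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      harrell_c(time5[idx], event5[idx], r_new[idx]) -
        harrell_c(time5[idx], event5[idx], r_old[idx])
    }, numeric(1))
  }
  list(c_old = c_old, c_new = c_new, delta_c = c_new - c_old,
       p = bootstrap_p(c_new - c_old, draws), n_eval = n,
       resamples = as.integer(resamples))
}

check_two_classes <- function(outcome) {
  if (anyNA(outcome)) stop("outcome contains missing values")
  if (length(unique(outcome)) < 2) {
    stop("both outcome classes must be present")
  }
}

idi_point <- function(risk_old, risk_new, outcome) {
  slope <- function(r) mean(r[outcome == 1]) - mean(r[outcome == 0])
  slope(risk_new) - slope(risk_old)
}

nri_point <- function(risk_old, risk_new, outcome) {
  up <- risk_new > risk_old
  down <- risk_new < risk_old
  ev <- outcome == 1
  (mean(up[ev]) - mean(down[ev])) + (mean(down[!ev]) - mean(up[!ev]))
}

#' Integrated discrimination improvement
#'
#' `idi = slope_new - slope_old`, where a model's discrimination slope is
#' the mean predicted risk among events minus the mean among non-events.
#' The p-value comes from a seeded participant-level bootstrap.
#'
#' @param risk_old,risk_new Aligned risk vectors.
#' @param outcome Binary event-within-horizon indicator (complete cases:
#'   participants censored before the horizon are excluded upstream).
#' @param resamples Bootstrap resamples; 0 gives `p = NA`.
#' @param seed Integer seed.
#' @return A list with `idi`, `p`, `n_eval`, `resamples`.
#' @export
idi <- function(risk_old, risk_new, outcome, resamples = 1000L, seed = 1L) {
  check_two_classes(outcome)
  est <- idi_point(risk_old, risk_new, outcome)
  draws <- numeric(0)
  n <- length(outcome)
  if (resamples > 0) {
    set.seed(as.integer(seed))
    draws <- vapply(seq_len(resamples), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(outcome[idx])) < 2) return(NA_real_)
      idi_point(risk_old[idx], risk_new[idx], outcome[idx])
    }, numeric(1))
    draws <- draws[!is.na(draws)]
  }
  list(idi = est, p = bootstrap_p(est, draws), n_eval = n,
       resamples = as.integer(resamples))
}

#' Continuous net reclassification improvement
#'
#' `nri = [P(up | event) - P(down | event)] + [P(down | non-event) -
#' P(up | non-event)]`, where "up"/"down" mean the new model's risk is
#' strictly higher/lower than the old model's; exact ties contribute 0.
#' Range `[-2, 2]`. The p-value comes from a seeded participant-level
#' bootstrap.
#'
#' @inheritParams idi
#' @return A list with `nri`, `p`, `n_eval`, `resamples`.
#' @export
continuous_nri <- function(risk_old, risk_new, outcome, resamples = 1000L,
                           seed = 1L) {
  check_two_classes(outcome)
  est <- nri_point(risk_old, risk_new, outcome)
  draws <- numeric(0)
  n <- length(outcome)
  if (resamples > 0) {
    set.seed(as.integer(seed))
    draws <- vapply(seq_len(resamples), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(outcome[idx])) < 2) return(NA_real_)
      nri_point(risk_old[idx], risk_new[idx], outcome[idx])
    }, numeric(1))
    draws <- draws[!is.na(draws)]
  }
  list(nri = est, p = bootstrap_p(est, draws), n_eval = n,
       resamples = as.integer(resamples))
}

#' Known 5-year outcome class, with censoring as missing
#'
#' 1 for deaths at or before the horizon, 0 for participants known to
#' survive to the horizon, `NA` for participants censored earlier (whose
#' 5-year status is unknown). The reclassification statistics use the
#' complete cases.
#'
#' @param cohort A cohort `data.frame`.
#' @param horizon Horizon in years.
#' @return Integer vector with `NA` for indeterminate rows.
#' @export
five_year_class <- function(cohort, horizon = 5.0) {
  out <- rep(NA_integer_, nrow(cohort))
  out[cohort$event == 1 & cohort$time <= horizon] <- 1L
  out[cohort$time >= horizon] <- 0L
  out
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(row totals))`
#' with sample (n-1) variances.
#'
#' @param items Numeric matrix or data.frame, one column per item.
#' @return Alpha (a real number, at most 1).
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  k <- ncol(x)
  if (k < 2 || nrow(x) < 2) stop("need at least 2 items and 2 rows")
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) stop("total score has zero variance")
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
}

#' Weighted item-score matrix of an index
#'
#' One column per weighted predictor, entries `weight * indicator`; the
#' row sums equal [score_index()]. This is the item matrix used for the
#' index's internal-consistency reliability.
#'
#' @param index A `multimorbidity_index`.
#' @param cohort A cohort `data.frame`.
#' @return Integer matrix with one column per positively weighted
#'   predictor.
#' @export
index_item_scores <- function(index, cohort) {
  preds <- names(index$weights)[index$weights > 0]
  out <- matrix(0L, nrow(cohort), length(preds),
                dimnames = list(NULL, preds))
  for (nm in preds) {
    sub <- multimorbidity_index(index$name,
                                setNames(index$weights[nm], nm))
    out[, nm] <- score_index(sub, cohort)
  }
  out
}

#' Pearson validity correlation
#'
#' Product-moment correlation between two score vectors with a two-sided
#' p-value.
#'
#' @param scores_a,scores_b Aligned numeric vectors (length >= 3,
#'   non-constant).
#' @return A list with `r` and `p`.
#' @export
pearson_validity <- function(scores_a, scores_b) {
  if (length(scores_a) < 3 || length(scores_a) != length(scores_b)) {
    stop("need aligned vectors of length >= 3")
  }
  if (stats::var(scores_a) == 0 || stats::var(scores_b) == 0) {
    stop("constant input")
  }
  ct <- stats::cor.test(scores_a, scores_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

fit_score_model <- function(training, score = NULL, horizon = 5.0) {
  x <- cbind(age = training$age, male = training$male)
  if (!is.null(score)) x <- cbind(x, score = score)
  fit_cox(x, training$time, training$event, horizon)
}

#' Fit and compare the four risk models on a validation set
#'
#' Fits the base model (age + sex) and, one at a time, models adding the
#' condition count, the individual-disease index (MI) and the
#' disease-combination index (MIDC) as a single score covariate on the
#' training set; predicts 5-year risk on the validation set; and
#' compares every reference/new pair in the published layout (each index
#' model against base, MI and MIDC against count, MIDC against MI) by
#' the C-statistic difference, IDI and continuous NRI with bootstrap
#' p-values. IDI/NRI use the complete cases of [five_year_class()].
#'
#' @param training,validation Cohort `data.frame`s.
#' @param mi,midc `multimorbidity_index` objects.
#' @param horizon Horizon in years.
#' @param resamples Bootstrap resamples per comparison.
#' @param seed Integer seed.
#' @return A `data.frame`, one row per comparison, with columns
#'   `reference`, `model`, `c_old`, `c_new`, `p_c`, `idi`, `p_idi`,
#'   `nri`, `p_nri`, `n_eval`, `n_class`, `resamples`.
#' @export
evaluate_models <- function(training, validation, mi, midc,
                            horizon = 5.0, resamples = 1000L, seed = 1L) {
  scores_tr <- list(
    base = NULL,
    condition_count = condition_count(training),
    MI = score_index(mi, training),
    MIDC = score_index(midc, training))
  scores_va <- list(
    base = NULL,
    condition_count = condition_count(validation),
    MI = score_index(mi, validation),
    MIDC = score_index(midc, validation))
  risks <- Map(function(s_tr, s_va) {
    fit <- fit_score_model(training, s_tr, horizon)
    cohort <- validation
    if (!is.null(s_va)) cohort$score <- s_va
    predict_risk5(fit, cohort)
  }, scores_tr, scores_va)

  cls <- five_year_class(validation, horizon)
  cc <- !is.na(cls)
  pairs <- list(c("base", "condition_count"), c("base", "MI"),
                c("base", "MIDC"), c("condition_count", "MI"),
                c("condition_count", "MIDC"), c("MI", "MIDC"))
  rows <- lapply(seq_along(pairs), function(i) {
    old <- pairs[[i]][1]; new <- pairs[[i]][2]
    cmp <- compare_c(risks[[old]], risks[[new]], validation,
                     resamples = resamples, seed = seed + i,
                     horizon = horizon)
    d <- idi(risks[[old]][cc], risks[[new]][cc], cls[cc],
             resamples = resamples, seed = seed + i)
    r <- continuous_nri(risks[[old]][cc], risks[[new]][cc], cls[cc],
                        resamples = resamples, seed = seed + i)
    data.frame(reference = old, model = new,
               c_old = cmp$c_old, c_new = cmp$c_new, p_c = cmp$p,
               idi = d$idi, p_idi = d$p, nri = r$nri, p_nri = r$p,
               n_eval = nrow(validation), n_class = sum(cc),
               resamples = as.integer(resamples))
  })
  do.call(rbind, rows)
}

#' Write an evaluation table (with a full-precision JSON sidecar)
#'
#' The delimited table mirrors the published comparison layout with
#' 3-decimal rounding applied at write time only; the sidecar
#' (`<path>.json`) keeps full precision plus the seed and resample count.
#'
#' @param results Output of [evaluate_models()].
#' @param path CSV file path.
#' @param seed Seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(results, path, seed = NA_integer_) {
  out <- results
  for (j in c("c_old", "c_new", "p_c", "idi", "p_idi", "nri", "p_nri")) {
    out[[j]] <- round(out[[j]], 3)
  }
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(list(seed = seed, results = results),
                       paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
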