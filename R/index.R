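#' Model specification for a proportional-hazards index model
#'
#' An ordered covariate list: `age` and `male` first, then the condition
#' main effects, then any condition-pair indicators. Pair indicators must
#' have both parent conditions among the main effects.
#'
#' @param covariates Ordered character vector of predictor names.
#' @param horizon Outcome horizon in years.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(covariates, horizon = 5.0) {
  if (anyDuplicated(covariates)) stop("duplicate covariate names")
  mains <- covariates[!is_pair_name(covariates)]
  for (nm in covariates[is_pair_name(covariates)]) {
    if (!all(pair_members(nm) %in% mains)) {
      stop("pair indicator '", nm, "' lacks a parent main effect")
    }
  }
  structure(list(covariates = covariates, horizon = horizon),
            class = "model_spec")
}

#' Build the design matrix for an index model
#'
#' Columns are `age`, `male`, one column per condition, and — when mined
#' rules are supplied — one conjunction indicator per rule antecedent
#' (1 iff both conditions are present), with all main effects retained.
#' An empty rule set reduces to the individual-disease design.
#'
#' @param cohort A cohort `data.frame`.
#' @param rules Either `NULL`, a rules `data.frame` from [mine_rules()],
#'   or a character vector of pair names (`"a:b"`).
#' @param horizon Outcome horizon (years) recorded in the model
#'   specification.
#' @return A list of class `model_design` with elements `x` (numeric
#'   matrix) and `spec` (a [model_spec()]).
#' @export
build_design <- function(cohort, rules = NULL, horizon = 5.0) {
  cond <- cohort_conditions(cohort)
  pair_names <- if (is.null(rules)) {
    character(0)
  } else if (is.data.frame(rules)) {
    rules$antecedent
  } else {
    as.character(rules)
  }
  for (nm in pair_names) {
    if (!all(pair_members(nm) %in% cond)) {
      stop("rule '", nm, "' references a condition not in the cohort")
    }
  }
  covs <- c("age", "male", cond, pair_names)
  x <- matrix(0, nrow(cohort), length(covs), dimnames = list(NULL, covs))
  x[, "age"] <- cohort$age
  x[, "male"] <- cohort$male
  for (j in cond) x[, j] <- cohort[[j]]
  for (nm in pair_names) {
    ab <- pair_members(nm)
    x[, nm] <- cohort[[ab[1]]] * cohort[[ab[2]]]
  }
  structure(list(x = x, spec = model_spec(covs, horizon)),
            class = "model_design")
}

#' Construct a fitted-hazard-model object directly
#'
#' Builds the object [fit_cox()] returns from its parts. Useful for
#' applying a published set of coefficients or weights to new cohorts
#' without refitting.
#'
#' @param coefficients Named numeric vector of log hazard ratios.
#' @param means Covariate means used to centre the linear predictor
#'   (default all zero).
#' @param s0_horizon Baseline survival at the horizon (at the centring
#'   point), in `(0, 1]`.
#' @param horizon Horizon in years.
#' @param ci95 Optional 2-column matrix (rownames = predictors) of 95% CI
#'   bounds on the hazard-ratio scale.
#' @return An object of class `fitted_hazard_model`.
#' @export
hazard_model <- function(coefficients, means = NULL, s0_horizon = NULL,
                         horizon = 5.0, ci95 = NULL) {
  stopifnot(!is.null(names(coefficients)))
  if (is.null(means)) means <- setNames(rep(0, length(coefficients)),
                                        names(coefficients))
  hr <- exp(coefficients)
  if (is.null(ci95)) {
    ci95 <- cbind(low = hr, high = hr)
  }
  structure(list(coefficients = coefficients,
                 hazard_ratios = hr,
                 se = rep(NA_real_, length(coefficients)),
                 ci95 = ci95,
                 means = means,
                 s0_horizon = s0_horizon,
                 horizon = horizon,
                 spec = model_spec(names(coefficients), horizon),
                 n = NA_integer_, n_event = NA_integer_),
            class = "fitted_hazard_model")
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the Cox partial likelihood with the Efron tie correction
#' (via the survival package), computes 95% confidence intervals from the
#' observed-information normal approximation, and the baseline survival
#' at the horizon by the Breslow estimator. Constant columns are dropped
#' with a warning; non-convergence or (near-)infinite estimates raise an
#' error naming the offending predictor.
#'
#' @param design A `model_design` from [build_design()], or a numeric
#'   matrix / data.frame of covariates.
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @param horizon Horizon (years) at which baseline survival is recorded;
#'   observations are administratively censored at the horizon before
#'   fitting.
#' @return An object of class `fitted_hazard_model` with elements
#'   `coefficients`, `hazard_ratios`, `se`, `ci95`, `means`,
#'   `s0_horizon`, `horizon`, `spec`, `n`, `n_event`.
#' @export
fit_cox <- function(design, time, event, horizon = 5.0) {
  if (inherits(design, "model_design")) {
    x <- design$x
    horizon <- design$spec$horizon
  } else {
    x <- as.matrix(design)
  }
  stopifnot(nrow(x) == length(time), length(time) == length(event))
  time5 <- pmin(time, horizon)
  event5 <- as.integer(event == 1 & time <= horizon)
  if (sum(event5) < 2 || length(unique(time5[event5 == 1])) < 2) {
    stop("need at least two distinct event times")
  }
  keep <- apply(x, 2, function(col) length(unique(col)) > 1)
  if (any(!keep)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  df <- as.data.frame(x)
  df$.time <- time5
  df$.event <- event5
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron",
                         x = FALSE, y = TRUE)
  beta <- stats::coef(fit)
  names(beta) <- colnames(x)
  se <- sqrt(diag(stats::vcov(fit)))
  names(se) <- colnames(x)
  bad <- is.na(beta) | abs(beta) > 15 | se > 10
  if (any(bad)) {
    stop("Cox fit failed (non-convergence or separation) for predictor(s): ",
         paste(colnames(x)[bad], collapse = ", "))
  }
  sf <- survival::survfit(fit, stype = 2, ctype = 1)
  s0 <- summary(sf, times = horizon, extend = TRUE)$surv
  hr <- exp(beta)
  ci <- cbind(low = exp(beta - stats::qnorm(0.975) * se),
              high = exp(beta + stats::qnorm(0.975) * se))
  rownames(ci) <- colnames(x)
  structure(list(coefficients = beta,
                 hazard_ratios = hr,
                 se = se,
                 ci95 = ci,
                 means = fit$means,
                 s0_horizon = s0,
                 horizon = horizon,
                 spec = model_spec(colnames(x), horizon),
                 n = nrow(x), n_event = sum(event5)),
            class = "fitted_hazard_model")
}

#' @export
print.fitted_hazard_model <- function(x, ...) {
  cat("Proportional-hazards model (", x$n, " rows, ", x$n_event,
      " events, horizon ", x$horizon, "y)\n", sep = "")
  tab <- data.frame(beta = x$coefficients, HR = x$hazard_ratios,
                    low = x$ci95[, "low"], high = x$ci95[, "high"])
  print(round(tab, 3))
  invisible(x)
}

#' Convert hazard ratios to integer index weights
#'
#' Each condition or condition-pair predictor (never age or sex) is
#' weighted from its unrounded adjusted hazard ratio: weight 1 for
#' HR in `[1.0, 1.2)`, 2 for HR in `[1.2, 1.5)`, 3 for HR >= 1.5, and 0
#' (excluded from the index) for HR < 1.
#'
#' @param model A `fitted_hazard_model`.
#' @return An object of class `weight_table`: a named integer vector of
#'   weights over the model's condition and pair predictors.
#' @export
assign_weights <- function(model) {
  stopifnot(inherits(model, "fitted_hazard_model"))
  preds <- setdiff(model$spec$covariates, c("age", "male"))
  hr <- model$hazard_ratios[preds]
  w <- integer(length(preds))
  names(w) <- preds
  w[hr >= 1.0 & hr < 1.2] <- 1L
  w[hr >= 1.2 & hr < 1.5] <- 2L
  w[hr >= 1.5] <- 3L
  structure(w, class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  cat("Index weight table (", sum(x > 0), " weighted of ", length(x),
      " predictors, max score ", sum(x), ")\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' A weighted multimorbidity index
#'
#' Bundles a name with a weight table; `max_score` is the sum of the
#' positive weights (the score of a participant with every weighted
#' predictor present).
#'
#' @param name Index name, e.g. `"MI"`, `"MIDC"` or `"condition_count"`.
#' @param weights A `weight_table` (or named integer vector) over
#'   condition / pair predictors.
#' @return An object of class `multimorbidity_index`.
#' @export
multimorbidity_index <- function(name, weights) {
  w <- as.integer(weights)
  names(w) <- names(weights)
  if (any(w < 0L | w > 3L)) stop("weights must lie in {0, 1, 2, 3}")
  if (any(c("age", "male") %in% names(w))) stop("age and sex are never weighted")
  structure(list(name = name, weights = w, max_score = sum(w)),
            class = "multimorbidity_index")
}

#' The simple condition-count index
#'
#' Identity weights of 1 per condition; `max_score` equals the number of
#' conditions.
#'
#' @param conditions Condition names (default the canonical 13).
#' @return A `multimorbidity_index`.
#' @export
condition_count_index <- function(conditions = clhls_conditions()) {
  multimorbidity_index("condition_count",
                       setNames(rep(1L, length(conditions)), conditions))
}

#' Score an index on a cohort
#'
#' The per-participant score is the sum of `weight * indicator` over the
#' index's weighted predictors, pair indicators recomputed as
#' conjunctions of their parent conditions.
#'
#' @param index A `multimorbidity_index`.
#' @param cohort A cohort `data.frame`.
#' @return Integer vector of scores in `[0, max_score]`.
#' @export
score_index <- function(index, cohort) {
  stopifnot(inherits(index, "multimorbidity_index"))
  cond <- cohort_conditions(cohort)
  s <- integer(nrow(cohort))
  for (nm in names(index$weights)) {
    w <- index$weights[[nm]]
    if (w == 0L) next
    ind <- if (is_pair_name(nm)) {
      ab <- pair_members(nm)
      if (!all(ab %in% cond)) stop("cohort lacks condition(s) for ", nm)
      cohort[[ab[1]]] * cohort[[ab[2]]]
    } else {
      if (!nm %in% cond) stop("cohort lacks condition ", nm)
      cohort[[nm]]
    }
    s <- s + w * as.integer(ind)
  }
  s
}

#' Unweighted condition count per participant
#'
#' @param cohort A cohort `data.frame`.
#' @return Integer vector: the number of conditions present per row.
#' @export
condition_count <- function(cohort) {
  cond <- cohort_conditions(cohort)
  as.integer(rowSums(cohort[, cond, drop = FALSE]))
}

#' Develop the individual-disease and disease-combination indices
#'
#' Fits the two index-development models on a training cohort — the
#' individual-disease model with age, sex and the condition main effects,
#' and the combination model additionally containing one conjunction
#' indicator per mined rule — and converts each model's hazard ratios to
#' integer weights. The individual-disease index (MI) is exactly the
#' combination index (MIDC) pipeline run with an empty rule set.
#'
#' @param training Training cohort `data.frame`.
#' @param rules Mined rules (`data.frame` or pair-name vector); may be
#'   empty.
#' @param horizon Outcome horizon in years.
#' @return A list with `model1`, `model2` (fitted hazard models), `mi`
#'   and `midc` (`multimorbidity_index` objects).
#' @export
develop_indices <- function(training, rules, horizon = 5.0) {
  d1 <- build_design(training, NULL, horizon)
  m1 <- fit_cox(d1, training$time, training$event, horizon)
  d2 <- build_design(training, rules, horizon)
  m2 <- fit_cox(d2, training$time, training$event, horizon)
  list(model1 = m1, model2 = m2,
       mi = multimorbidity_index("MI", assign_weights(m1)),
       midc = multimorbidity_index("MIDC", assign_weights(m2)))
}

#' Read / write a multimorbidity index as JSON
#'
#' Serialises predictor-to-weight maps with the index name and
#' `max_score` so a published index can be applied to new cohorts
#' without refitting.
#'
#' @param index A `multimorbidity_index`.
#' @param path File path.
#' @return `read_index` returns a `multimorbidity_index`; `write_index`
#'   returns `path` invisibly.
#' @export
write_index <- function(index, path) {
  jsonlite::write_json(
    list(name = index$name,
         weights = as.list(index$weights),
         max_score = index$max_score),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  idx <- multimorbidity_index(x$name, unlist(x$weights))
  if (!is.null(x$max_score) && idx$max_score != x$max_score) {
    stop("stored max_score disagrees with the sum of weights")
  }
  idx
}
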