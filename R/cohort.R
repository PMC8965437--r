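#' Canonical chronic-condition schema
#'
#' The 13 binary chronic conditions used throughout the package, in the
#' order they appear in the survey's descriptive table: hypertension,
#' diabetes, heart disease, cerebrovascular disease, Parkinson's disease,
#' arthritis, tooth loss, lung disease, cancer, sensory impairment,
#' cognitive impairment, bedridden status and depressive symptoms.
#'
#' @return Character vector of length 13 with the canonical column names.
#' @export
clhls_conditions <- function() {
  c("hypertension", "diabetes", "heart_disease", "cerebrovascular_disease",
    "parkinsons_disease", "arthritis", "tooth_loss", "lung_disease",
    "cancer", "sensory_impairment", "cognitive_impairment", "bedridden",
    "depressive_symptoms")
}

#' Canonical name for a condition-pair predictor
#'
#' Pair predictors (conjunctions of two conditions) are named
#' `"a:b"` with the two parent conditions ordered by the condition schema
#' (canonical conditions first, in schema order; unknown names
#' lexicographically).
#'
#' @param a,b Condition names.
#' @return A single string naming the pair predictor.
#' @export
pair_name <- function(a, b) {
  ord <- match(c(a, b), clhls_conditions())
  if (anyNA(ord)) {
    nm <- sort(c(a, b))
  } else {
    nm <- c(a, b)[order(ord)]
  }
  paste(nm[1], nm[2], sep = ":")
}

#' Split a pair-predictor name into its two parent conditions
#' @param name A pair name produced by [pair_name()].
#' @return Character vector of length 2.
#' @export
pair_members <- function(name) {
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("not a pair predictor name: ", name)
  }
  parts
}

is_pair_name <- function(name) grepl(":", name, fixed = TRUE)

#' Construct and validate a synthetic-cohort generator configuration
#'
#' The generator draws correlated binary condition indicators by Gaussian
#' copula latent thresholding, then survival times from an exponential
#' proportional-hazards model with exponential loss to follow-up and
#' administrative censoring at a fixed horizon.
#'
#' @param n_participants Number of rows to generate.
#' @param prevalences Named numeric vector of marginal condition
#'   prevalences in `[0, 1]`.
#' @param dependence Symmetric positive-definite latent correlation matrix
#'   with unit diagonal, dimnames matching `names(prevalences)`.
#' @param age_range Integer vector `c(lo, hi)`; ages are discrete uniform
#'   on `lo:hi` years.
#' @param sex_male_fraction Fraction male in `[0, 1]`.
#' @param log_hazards Named numeric vector of ground-truth log hazard
#'   ratios; names are condition names or pair names (`"a:b"`) for
#'   condition-pair interaction terms.
#' @param baseline_rate Exponential baseline hazard (events per
#'   person-year) at age `age_range[1]`, female, no conditions.
#' @param age_log_hazard Log hazard ratio per year of age above
#'   `age_range[1]`.
#' @param sex_log_hazard Log hazard ratio for male sex.
#' @param ltfu_rate Loss-to-follow-up hazard (per person-year); 0 disables
#'   random censoring.
#' @param admin_horizon Administrative censoring horizon in years.
#' @param seed Default integer seed used by [generate_cohort()] when no
#'   explicit seed is passed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_participants,
                             prevalences,
                             dependence = NULL,
                             age_range = c(65L, 84L),
                             sex_male_fraction = 0.5,
                             log_hazards = numeric(0),
                             baseline_rate = 0.05,
                             age_log_hazard = 0,
                             sex_log_hazard = 0,
                             ltfu_rate = 0,
                             admin_horizon = 5.0,
                             seed = 1L) {
  k <- length(prevalences)
  if (k < 1 || is.null(names(prevalences)) || anyNA(names(prevalences))) {
    stop("prevalences must be a named numeric vector")
  }
  if (is.null(dependence)) {
    dependence <- diag(k)
    dimnames(dependence) <- list(names(prevalences), names(prevalences))
  }
  cfg <- structure(
    list(n_participants = as.integer(n_participants),
         prevalences = prevalences,
         dependence = dependence,
         age_range = as.integer(age_range),
         sex_male_fraction = sex_male_fraction,
         log_hazards = log_hazards,
         baseline_rate = baseline_rate,
         age_log_hazard = age_log_hazard,
         sex_log_hazard = sex_log_hazard,
         ltfu_rate = ltfu_rate,
         admin_horizon = admin_horizon,
         seed = as.integer(seed)),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks all structural invariants: fractions in `[0, 1]`, a symmetric
#' positive-definite dependence matrix with unit diagonal, a positive
#' horizon, at least one participant, and that every hazard-term name
#' refers to a known condition (or pair of known conditions).
#'
#' @param config A `generator_config`.
#' @return `config`, invisibly, if valid; otherwise an error.
#' @export
validate_generator_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  p <- config$prevalences
  if (any(p < 0 | p > 1)) stop("prevalences must lie in [0, 1]")
  if (config$sex_male_fraction < 0 || config$sex_male_fraction > 1) {
    stop("sex_male_fraction must lie in [0, 1]")
  }
  if (config$n_participants < 1) stop("n_participants must be >= 1")
  if (config$admin_horizon <= 0) stop("admin_horizon must be > 0")
  if (config$ltfu_rate < 0) stop("ltfu_rate must be >= 0")
  if (config$baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (length(config$age_range) != 2 || config$age_range[1] > config$age_range[2]) {
    stop("age_range must be c(lo, hi) with lo <= hi")
  }
  D <- config$dependence
  k <- length(p)
  if (!is.matrix(D) || nrow(D) != k || ncol(D) != k) {
    stop("dependence must be a ", k, "x", k, " matrix")
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("dependence matrix must be symmetric")
  }
  if (any(abs(diag(D) - 1) > 1e-8)) stop("dependence matrix must have unit diagonal")
  ok <- tryCatch({ chol(D); TRUE }, error = function(e) FALSE)
  if (!ok) stop("dependence matrix is not positive definite")
  cond <- names(p)
  for (nm in names(config$log_hazards)) {
    members <- if (is_pair_name(nm)) pair_members(nm) else nm
    if (!all(members %in% cond)) {
      stop("log_hazards term '", nm, "' refers to an unknown condition")
    }
  }
  invisible(config)
}

# Latent (tetrachoric-style) correlation such that two thresholded standard
# normals with marginal exceedance probabilities pa, pb have joint exceedance
# probability p_joint. Solved by root-finding on the bivariate normal upper
# orthant probability.
latent_correlation <- function(pa, pb, p_joint) {
  if (pa <= 0 || pb <= 0 || pa >= 1 || pb >= 1) return(0)
  a <- stats::qnorm(1 - pa)
  b <- stats::qnorm(1 - pb)
  f <- function(rho) {
    sig <- matrix(c(1, rho, rho, 1), 2)
    mvtnorm::pmvnorm(lower = c(a, b), upper = c(Inf, Inf), corr = sig)[1] - p_joint
  }
  lo <- -0.99; hi <- 0.99
  if (f(lo) > 0 || f(hi) < 0) {
    stop("requested joint prevalence is not attainable for these marginals")
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Default survey-calibrated generator configuration
#'
#' Returns a generator configuration emulating the structure of the
#' community-dwelling 65--84 year-old survey cohort the package's indices
#' were designed around: 13 condition prevalences matching the published
#' descriptive table (hypertension 0.556 down to Parkinson's disease and
#' cancer at 0.005), latent pairwise dependence calibrated so the 13
#' published disease-combination prevalences are reproduced in
#' expectation, ground-truth log hazard ratios spanning every weight bin
#' (at least four predictors per bin, including three condition-pair
#' interaction terms), and baseline / loss-to-follow-up rates pre-tuned so
#' that about 25.2% of participants die and about 16.3% are lost to
#' follow-up within the 5-year horizon.
#'
#' @param n_participants Cohort size (default 11853, the analytic sample
#'   size the configuration is calibrated for).
#' @param seed Default seed stored in the configuration.
#' @return A `generator_config`.
#' @export
default_clhls_config <- function(n_participants = 11853L, seed = 1L) {
  cond <- clhls_conditions()
  prev <- c(hypertension = 0.556, diabetes = 0.032, heart_disease = 0.105,
            cerebrovascular_disease = 0.063, parkinsons_disease = 0.005,
            arthritis = 0.183, tooth_loss = 0.060, lung_disease = 0.134,
            cancer = 0.005, sensory_impairment = 0.237,
            cognitive_impairment = 0.048, bedridden = 0.011,
            depressive_symptoms = 0.360)[cond]

  # Joint prevalences of the 13 published disease combinations (fractions of
  # the whole cohort); used to calibrate the latent correlation structure.
  pair_prev <- c(
    "hypertension:depressive_symptoms"          = 0.204,
    "hypertension:sensory_impairment"           = 0.142,
    "sensory_impairment:depressive_symptoms"    = 0.116,
    "hypertension:lung_disease"                 = 0.075,
    "lung_disease:depressive_symptoms"          = 0.057,
    "arthritis:depressive_symptoms"             = 0.079,
    "cognitive_impairment:depressive_symptoms"  = 0.034,
    "hypertension:heart_disease"                = 0.075,
    "sensory_impairment:cognitive_impairment"   = 0.034,
    "hypertension:cerebrovascular_disease"      = 0.046,
    "hypertension:cognitive_impairment"         = 0.028,
    "hypertension:tooth_loss"                   = 0.035,
    "lung_disease:sensory_impairment"           = 0.039)

  D <- diag(length(cond))
  dimnames(D) <- list(cond, cond)
  for (nm in names(pair_prev)) {
    ab <- pair_members(nm)
    rho <- latent_correlation(prev[ab[1]], prev[ab[2]], pair_prev[[nm]])
    D[ab[1], ab[2]] <- D[ab[2], ab[1]] <- rho
  }

  # Ground-truth hazard structure. Rare conditions sit in the unbounded
  # >= 1.5 bin (interior bins are too narrow to be identifiable for
  # prevalences below ~5% at the calibrated sample size); each weight bin
  # holds at least four predictors, three of them pair interactions.
  lh <- log(c(
    hypertension = 0.95, arthritis = 0.95,
    depressive_symptoms = 1.10, sensory_impairment = 1.10,
    lung_disease = 1.10, heart_disease = 1.10,
    cerebrovascular_disease = 1.35, tooth_loss = 1.35,
    cognitive_impairment = 1.35,
    diabetes = 1.8, bedridden = 2.0, cancer = 2.2, parkinsons_disease = 2.5,
    "hypertension:sensory_impairment" = 1.10,
    "hypertension:depressive_symptoms" = 1.35,
    "cognitive_impairment:depressive_symptoms" = 2.0))

  generator_config(
    n_participants = n_participants,
    prevalences = prev,
    dependence = D,
    age_range = c(65L, 84L),
    sex_male_fraction = 0.530,
    log_hazards = lh,
    baseline_rate = 0.018729,
    age_log_hazard = log(1.08),
    sex_log_hazard = log(1.40),
    ltfu_rate = 0.042285,
    admin_horizon = 5.0,
    seed = seed)
}

# Linear predictor (excluding age/sex) for condition columns X under a named
# log-hazard vector that may contain pair-interaction terms.
condition_linear_predictor <- function(X, log_hazards) {
  eta <- numeric(nrow(X))
  for (nm in names(log_hazards)) {
    if (is_pair_name(nm)) {
      ab <- pair_members(nm)
      eta <- eta + log_hazards[[nm]] * X[, ab[1]] * X[, ab[2]]
    } else {
      eta <- eta + log_hazards[[nm]] * X[, nm]
    }
  }
  eta
}

#' Generate a synthetic cohort
#'
#' Draws `config$n_participants` participants. Condition indicators come
#' from a Gaussian copula: a multivariate normal latent vector with the
#' configured correlation matrix is thresholded at the
#' `1 - prevalence` quantile, which preserves the marginal prevalences
#' exactly in distribution. Event times are exponential with hazard
#' `baseline_rate * exp(sum(beta * x) + beta_age * (age - age_lo) + beta_sex * male)`;
#' censoring time is the minimum of an exponential loss-to-follow-up time
#' and the administrative horizon. A tie between event and censoring time
#' counts as an event.
#'
#' @param config A validated `generator_config`.
#' @param seed Integer seed; defaults to `config$seed`. Identical
#'   `(config, seed)` give identical output.
#' @return A `data.frame` with columns `id`, `age`, `male`, one column per
#'   condition, `time` and `event`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_generator_config(config)
  n <- config$n_participants
  cond <- names(config$prevalences)

  set.seed(as.integer(seed))
  ages <- config$age_range
  age <- sample(ages[1]:ages[2], n, replace = TRUE)
  male <- as.integer(stats::runif(n) < config$sex_male_fraction)

  # multivariate normal via the Cholesky factor: deterministic and stable
  # under ulp-level perturbation of the correlation matrix (unlike
  # eigendecomposition-based samplers, whose eigenvector signs can flip)
  k <- length(cond)
  Z <- matrix(stats::rnorm(n * k), n, k) %*% chol(config$dependence)
  thr <- stats::qnorm(1 - config$prevalences)
  X <- matrix(0L, n, length(cond), dimnames = list(NULL, cond))
  for (j in seq_along(cond)) X[, j] <- as.integer(Z[, j] > thr[j])

  eta <- condition_linear_predictor(X, config$log_hazards) +
    config$age_log_hazard * (age - ages[1]) +
    config$sex_log_hazard * male
  lambda <- config$baseline_rate * exp(eta)
  t_event <- stats::rexp(n, rate = 1) / lambda
  t_ltfu <- if (config$ltfu_rate > 0) {
    stats::rexp(n, rate = config$ltfu_rate)
  } else {
    rep(Inf, n)
  }
  t_cens <- pmin(t_ltfu, config$admin_horizon)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  out <- data.frame(id = seq_len(n), age = age, male = male,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(X))
  out$time <- time
  out$event <- event
  out
}

#' Condition columns of a cohort table
#'
#' Every column of a cohort table other than the reserved ones
#' (`id`, `age`, `male`, `time`, `event`) is treated as a binary condition
#' indicator.
#'
#' @param cohort A cohort `data.frame`.
#' @return Character vector of condition column names.
#' @export
cohort_conditions <- function(cohort) {
  setdiff(colnames(cohort), c("id", "age", "male", "time", "event"))
}

#' Validate a cohort table
#'
#' Checks the structural contract: required columns present, positive
#' follow-up times, binary event and condition indicators, no missing
#' values.
#'
#' @param cohort A cohort `data.frame`.
#' @param admin_horizon Optional horizon; if given, checks `time <= horizon`.
#' @return `cohort`, invisibly.
#' @export
validate_cohort <- function(cohort, admin_horizon = NULL) {
  need <- c("id", "age", "male", "time", "event")
  miss <- setdiff(need, colnames(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  if (anyNA(cohort)) stop("cohort contains missing values")
  if (any(cohort$time <= 0)) stop("follow-up times must be positive")
  if (!is.null(admin_horizon) && any(cohort$time > admin_horizon + 1e-12)) {
    stop("follow-up times exceed the administrative horizon")
  }
  if (!all(cohort$event %in% c(0L, 1L))) stop("event must be binary")
  for (j in cohort_conditions(cohort)) {
    if (!all(cohort[[j]] %in% c(0L, 1L))) stop("condition column ", j, " is not binary")
  }
  if (anyDuplicated(cohort$id)) stop("participant ids must be unique")
  invisible(cohort)
}

#' Split a cohort into training and validation sets
#'
#' Simple random partition with training size
#' `ceiling(training_fraction * N)` — so a 70/30 split of 11,853 rows
#' yields 8,298 and 3,555.
#'
#' @param cohort A cohort `data.frame`.
#' @param training_fraction Fraction in `[0, 1]`.
#' @param seed Integer seed driving the partition.
#' @return A list with elements `training` and `validation`, disjoint and
#'   jointly covering all rows.
#' @export
split_cohort <- function(cohort, training_fraction = 0.7, seed = 1L) {
  if (training_fraction < 0 || training_fraction > 1) {
    stop("training_fraction must lie in [0, 1]")
  }
  n <- nrow(cohort)
  n_train <- as.integer(ceiling(training_fraction * n))
  set.seed(as.integer(seed))
  idx <- sample.int(n, n_train)
  list(training = cohort[sort(idx), , drop = FALSE],
       validation = cohort[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

#' Read / write a cohort table as comma-delimited text
#'
#' @param cohort A cohort `data.frame`.
#' @param path File path.
#' @return `read_cohort` returns the cohort `data.frame`; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE)
  for (j in c("male", "event", cohort_conditions(x))) x[[j]] <- as.integer(x[[j]])
  validate_cohort(x)
  x
}

#' Read / write a generator configuration (YAML or JSON)
#'
#' The format is chosen from the file extension (`.yaml`/`.yml` or
#' `.json`). The dependence matrix round-trips as a list of rows.
#'
#' @param config A `generator_config`.
#' @param path File path.
#' @return `read_generator_config` returns a validated `generator_config`;
#'   `write_generator_config` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  x$dependence <- lapply(seq_len(nrow(config$dependence)),
                         function(i) as.numeric(config$dependence[i, ]))
  x$prevalences <- as.list(config$prevalences)
  x$log_hazards <- as.list(config$log_hazards)
  if (grepl("\\.ya?ml$", path)) {
    # 17 significant digits: lossless round-trip for IEEE doubles
    yaml::write_yaml(x, path, precision = 17)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  prev <- unlist(x$prevalences)
  D <- x$dependence
  if (is.list(D)) D <- do.call(rbind, lapply(D, unlist))
  D <- as.matrix(D)
  dimnames(D) <- list(names(prev), names(prev))
  generator_config(
    n_participants = x$n_participants,
    prevalences = prev,
    dependence = D,
    age_range = x$age_range,
    sex_male_fraction = x$sex_male_fraction,
    log_hazards = unlist(x$log_hazards),
    baseline_rate = x$baseline_rate,
    age_log_hazard = x$age_log_hazard,
    sex_log_hazard = x$sex_log_hazard,
    ltfu_rate = x$ltfu_rate,
    admin_horizon = x$admin_horizon,
    seed = x$seed)
}
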