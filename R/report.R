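fmt_count_pct <- function(n, N) sprintf("%d (%.1f)", n, 100 * n / N)

fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7)
  sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
}

binary_p <- function(a, n1, b, n2) {
  tot <- a + b
  if (tot == 0 || tot == n1 + n2) return(NA_real_)
  tab <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2)
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' Descriptive comparison of training and validation sets
#'
#' One row per baseline characteristic: age as median (IQR) compared by
#' the Mann-Whitney U-test, sex and each condition as count (%) compared
#' by the chi-square test without continuity correction.
#'
#' @param training,validation Non-empty cohort `data.frame`s.
#' @return A `data.frame` with columns `characteristic`, `total`,
#'   `training`, `validation`, `p_value`.
#' @export
describe_cohort <- function(training, validation) {
  stopifnot(nrow(training) > 0, nrow(validation) > 0)
  n1 <- nrow(training); n2 <- nrow(validation); N <- n1 + n2
  all_age <- c(training$age, validation$age)
  rows <- list(data.frame(
    characteristic = "age_years_median_iqr",
    total = fmt_median_iqr(all_age),
    training = fmt_median_iqr(training$age),
    validation = fmt_median_iqr(validation$age),
    p_value = suppressWarnings(
      stats::wilcox.test(training$age, validation$age)$p.value)))
  for (nm in c("male", intersect(cohort_conditions(training),
                                 cohort_conditions(validation)))) {
    a <- sum(training[[nm]]); b <- sum(validation[[nm]])
    rows[[length(rows) + 1]] <- data.frame(
      characteristic = nm,
      total = fmt_count_pct(a + b, N),
      training = fmt_count_pct(a, n1),
      validation = fmt_count_pct(b, n2),
      p_value = binary_p(a, n1, b, n2))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: the cohort source (a
#' generator configuration or a path to a cohort file), mining
#' thresholds, split fraction, horizon, bootstrap resamples, the master
#' seed and the output directory. Rules are mined on the full analytic
#' sample by default (`mine_scope = "all"`); set `mine_scope =
#' "training"` to restrict mining to the training set.
#'
#' @param generator A `generator_config`, or a path (string) to a cohort
#'   CSV.
#' @param thresholds An [arm_thresholds()].
#' @param training_fraction Fraction in `(0, 1]`.
#' @param horizon Outcome horizon in years.
#' @param resamples Bootstrap resamples (>= 0).
#' @param seed Master integer seed.
#' @param output_dir Directory for the artifact bundle.
#' @param mine_scope `"all"` or `"training"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = default_clhls_config(),
                            thresholds = arm_thresholds(),
                            training_fraction = 0.7,
                            horizon = 5.0,
                            resamples = 1000L,
                            seed = 1L,
                            output_dir = tempfile("midc_run_"),
                            mine_scope = c("all", "training")) {
  if (training_fraction <= 0 || training_fraction > 1) {
    stop("training_fraction must lie in (0, 1]")
  }
  if (resamples < 0) stop("resamples must be >= 0")
  structure(list(generator = generator, thresholds = thresholds,
                 training_fraction = training_fraction, horizon = horizon,
                 resamples = as.integer(resamples), seed = as.integer(seed),
                 output_dir = output_dir,
                 mine_scope = match.arg(mine_scope)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full index-development pipeline
#'
#' Generates (or loads) the cohort, splits it, mines disease-combination
#' rules, fits the two index-development models on the training set,
#' assigns weights, builds the MI and MIDC indices, evaluates the base /
#' count / MI / MIDC models on the validation set, computes reliability
#' and validity of the MIDC, and writes the artifact bundle: cohort,
#' descriptive table, rule table, two index JSONs, evaluation table
#' (with full-precision sidecar) and a run manifest. Reruns with the
#' same configuration are identical up to floating-point determinism.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate object plus
#'   `files`, the named vector of written paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$output_dir, f)

  cohort <- stage("cohort", {
    if (is.character(config$generator)) {
      read_cohort(config$generator)
    } else {
      generate_cohort(config$generator, seed = config$seed)
    }
  })
  halves <- stage("split",
    split_cohort(cohort, config$training_fraction, seed = config$seed))
  descriptives <- stage("describe",
    describe_cohort(halves$training, halves$validation))
  rules <- stage("mine", {
    base <- if (config$mine_scope == "all") cohort else halves$training
    mine_rules(base, config$thresholds, config$horizon)
  })
  dev <- stage("develop",
    develop_indices(halves$training, rules, config$horizon))
  evaluation <- stage("evaluate",
    evaluate_models(halves$training, halves$validation, dev$mi, dev$midc,
                    horizon = config$horizon, resamples = config$resamples,
                    seed = config$seed))
  reliability <- stage("reliability", {
    va <- halves$validation
    midc_score <- score_index(dev$midc, va)
    list(cronbach_alpha = cronbach_alpha(index_item_scores(dev$midc, va)),
         r_vs_count = pearson_validity(midc_score, condition_count(va)),
         r_vs_mi = pearson_validity(midc_score, score_index(dev$mi, va)))
  })

  files <- c(cohort = path("cohort.csv"),
             descriptives = path("descriptives.csv"),
             rules = path("rules.csv"),
             index_mi = path("index_mi.json"),
             index_midc = path("index_midc.json"),
             evaluation = path("evaluation.csv"),
             manifest = path("manifest.json"))
  stage("write", {
    write_cohort(cohort, files[["cohort"]])
    utils::write.csv(descriptives, files[["descriptives"]], row.names = FALSE)
    write_rules(rules, files[["rules"]])
    write_index(dev$mi, files[["index_mi"]])
    write_index(dev$midc, files[["index_midc"]])
    write_evaluation(evaluation, files[["evaluation"]], seed = config$seed)
    manifest <- list(
      package = "midcindex",
      package_version = as.character(utils::packageVersion("midcindex")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      horizon = config$horizon,
      resamples = config$resamples,
      training_fraction = config$training_fraction,
      mine_scope = config$mine_scope,
      n_total = nrow(cohort),
      n_training = nrow(halves$training),
      n_validation = nrow(halves$validation),
      n_rules = nrow(rules),
      thresholds = unclass(config$thresholds),
      reliability = list(
        cronbach_alpha = reliability$cronbach_alpha,
        r_vs_count = reliability$r_vs_count$r,
        p_vs_count = reliability$r_vs_count$p,
        r_vs_mi = reliability$r_vs_mi$r,
        p_vs_mi = reliability$r_vs_mi$p))
    jsonlite::write_json(manifest, files[["manifest"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(cohort = cohort, training = halves$training,
                 validation = halves$validation, descriptives = descriptives,
                 rules = rules, model1 = dev$model1, model2 = dev$model2,
                 mi = dev$mi, midc = dev$midc, evaluation = evaluation,
                 reliability = reliability, files = files))
}
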