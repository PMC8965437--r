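#' Thresholds for restrictive association rule mining
#'
#' Rules are retained only if support, confidence and lift all *strictly*
#' exceed their thresholds, evaluated on unrounded values. Defaults follow
#' the restrictive mining parameters the indices were developed with:
#' support > 1.5%, confidence > 10%, lift > 1.0, antecedents of exactly
#' two conditions, consequent fixed to 5-year mortality.
#'
#' @param min_support Minimum support (strict), fraction of the cohort.
#' @param min_confidence Minimum confidence (strict).
#' @param min_lift Minimum lift (strict).
#' @param antecedent_size Number of conditions in each antecedent.
#' @return An object of class `arm_thresholds`.
#' @export
arm_thresholds <- function(min_support = 0.015, min_confidence = 0.10,
                           min_lift = 1.0, antecedent_size = 2L) {
  stopifnot(min_support >= 0, min_support <= 1,
            min_confidence >= 0, min_confidence <= 1,
            min_lift >= 0, antecedent_size >= 1)
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 min_lift = min_lift, antecedent_size = as.integer(antecedent_size)),
            class = "arm_thresholds")
}

#' Five-year mortality outcome indicator
#'
#' Returns 1 for participants who died at or before the horizon, 0
#' otherwise. Participants censored before the horizon count as
#' non-events and remain in every denominator — the reading under which
#' the all-participant support/prevalence proportions and the marginal
#' death fraction cohere (see the methods vignette for the limitation
#' this implies).
#'
#' @param cohort A cohort `data.frame` with `time` and `event`.
#' @param horizon Horizon in years (> 0).
#' @return Integer 0/1 vector, one entry per row.
#' @export
five_year_outcome <- function(cohort, horizon = 5.0) {
  stopifnot(horizon > 0)
  as.integer(cohort$event == 1 & cohort$time <= horizon)
}

rule_row <- function(pair, counts) {
  pair <- pair_members(pair_name(pair[1], pair[2]))  # canonical order
  n_ant <- counts[["n_antecedent"]]
  n_both <- counts[["n_antecedent_and_death"]]
  n_death <- counts[["n_death"]]
  n_total <- counts[["n_total"]]
  degenerate <- n_ant == 0 || n_death == 0
  data.frame(
    condition_a = pair[1],
    condition_b = pair[2],
    antecedent = pair_name(pair[1], pair[2]),
    consequent = "five_year_mortality",
    support = n_both / n_total,
    confidence = if (n_ant > 0) n_both / n_ant else NA_real_,
    lift = if (n_ant > 0 && n_death > 0) (n_both / n_ant) * n_total / n_death else NA_real_,
    prevalence = n_ant / n_total,
    n_antecedent = n_ant,
    n_antecedent_and_death = n_both,
    n_death = n_death,
    n_total = n_total,
    degenerate = degenerate,
    stringsAsFactors = FALSE)
}

#' Exact association-rule metrics for one condition pair
#'
#' Counts the 2x2 joint occurrence of the pair antecedent (both
#' conditions present) and the 5-year mortality consequent, and derives
#' support (`n_both / n_total`), confidence (`n_both / n_antecedent`),
#' lift (`confidence * n_total / n_death`) and prevalence
#' (`n_antecedent / n_total`) exactly from the counts. Rules with a zero
#' denominator are flagged `degenerate` with `NA` ratios rather than
#' numeric artifacts.
#'
#' @param cohort A cohort `data.frame`.
#' @param pair Character vector of two condition names.
#' @param horizon Outcome horizon in years.
#' @return A one-row `data.frame` with metrics and raw counts.
#' @export
compute_rule_metrics <- function(cohort, pair, horizon = 5.0) {
  pair <- as.character(pair)
  stopifnot(length(pair) == 2)
  unknown <- setdiff(pair, cohort_conditions(cohort))
  if (length(unknown)) {
    stop("unknown condition name(s): ", paste(unknown, collapse = ", "))
  }
  y <- five_year_outcome(cohort, horizon)
  a <- cohort[[pair[1]]] == 1 & cohort[[pair[2]]] == 1
  rule_row(pair, c(n_antecedent = sum(a),
                   n_antecedent_and_death = sum(a & y == 1),
                   n_death = sum(y),
                   n_total = nrow(cohort)))
}

#' Mine disease-combination rules against 5-year mortality
#'
#' Exhaustively enumerates every unordered pair of condition columns
#' (78 pairs for the canonical 13-condition schema), computes exact
#' metrics for each, and retains a rule iff support, confidence and lift
#' all strictly exceed their thresholds on unrounded values. Output is
#' sorted by support descending, ties broken lexicographically by
#' antecedent name.
#'
#' @param cohort A cohort `data.frame` with at least two condition columns.
#' @param thresholds An [arm_thresholds()] object.
#' @param horizon Outcome horizon in years.
#' @return A `data.frame` of retained rules (possibly zero rows) with the
#'   same columns as [compute_rule_metrics()].
#' @export
mine_rules <- function(cohort, thresholds = arm_thresholds(), horizon = 5.0) {
  cond <- cohort_conditions(cohort)
  if (length(cond) < 2) stop("need at least two condition columns")
  if (thresholds$antecedent_size != 2L) {
    stop("only antecedents of exactly two conditions are supported")
  }
  pairs <- utils::combn(cond, 2, simplify = FALSE)
  rules <- do.call(rbind, lapply(pairs, function(p) {
    compute_rule_metrics(cohort, p, horizon)
  }))
  keep <- !rules$degenerate &
    rules$support > thresholds$min_support &
    rules$confidence > thresholds$min_confidence &
    rules$lift > thresholds$min_lift
  rules <- rules[keep, , drop = FALSE]
  rules <- rules[order(-rules$support, rules$antecedent), , drop = FALSE]
  rownames(rules) <- NULL
  rules
}

#' Read / write mined rules as delimited text
#'
#' The writer mirrors the published rule table: antecedent, consequent,
#' support / confidence / prevalence as percentages rounded to one
#' decimal, lift to one decimal — rounding happens only at write time —
#' plus the raw counts, from which the reader reconstructs the exact
#' unrounded metrics.
#'
#' @param rules A rules `data.frame` from [mine_rules()].
#' @param path File path.
#' @return `read_rules` returns the rules `data.frame` with exact metrics
#'   recomputed from counts; `write_rules` returns `path` invisibly.
#' @export
write_rules <- function(rules, path) {
  out <- data.frame(
    antecedent = rules$antecedent,
    consequent = rules$consequent,
    support_pct = round(100 * rules$support, 1),
    confidence_pct = round(100 * rules$confidence, 1),
    lift = round(rules$lift, 1),
    prevalence_pct = round(100 * rules$prevalence, 1),
    n_antecedent = rules$n_antecedent,
    n_antecedent_and_death = rules$n_antecedent_and_death,
    n_death = rules$n_death,
    n_total = rules$n_total)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE)
  rows <- lapply(seq_len(nrow(x)), function(i) {
    pair <- pair_members(x$antecedent[i])
    rule_row(pair, c(n_antecedent = x$n_antecedent[i],
                     n_antecedent_and_death = x$n_antecedent_and_death[i],
                     n_death = x$n_death[i],
                     n_total = x$n_total[i]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- rule_row(c("a", "b"), c(n_antecedent = 0,
    n_antecedent_and_death = 0, n_death = 0, n_total = 1))[0, ]
  out
}
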