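---
title: "Methods: mining disease combinations and weighting multimorbidity indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining disease combinations and weighting multimorbidity indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midcindex)
```

## The problem

A weighted multimorbidity index summarises a person's chronic-condition
profile as a single integer that predicts an adverse outcome — here,
death within five years — better than a raw condition count. Most such
indices weight individual diseases only. This package implements, as a
reusable and fully testable pipeline, an index-construction procedure
that additionally weights *disease combinations*: pairs of conditions
whose joint presence is over-represented among people who die within the
horizon, discovered by restrictive association rule mining (ARM). Two
indices come out of the pipeline:

* **MI** — integer weights on the 13 individual conditions;
* **MIDC** — the same construction with the mined condition pairs added
  as extra weighted predictors.

Both are compared against the simple condition count and a base model
with age and sex only.

## Pipeline overview

1. **Cohort.** A participant-level table: age (65–84 years), sex, 13
   binary chronic-condition indicators (hypertension, diabetes, heart
   disease, cerebrovascular disease, Parkinson's disease, arthritis,
   tooth loss, lung disease, cancer, sensory impairment, cognitive
   impairment, bedridden status, depressive symptoms), follow-up time
   and a death indicator, administratively censored at 5 years.
2. **Split.** A simple random 70/30 training/validation partition with
   training size `ceiling(0.7 * N)` — for N = 11,853 this gives
   8,298 / 3,555.
3. **Rule mining** (`mine_rules()`). All 78 unordered condition pairs
   are enumerated exhaustively against the fixed consequent
   *death within 5 years*. For a pair A with joint indicator
   `x_A = x_a * x_b` and outcome `y`:
   support `= P(x_A = 1, y = 1)`, confidence `= P(y = 1 | x_A = 1)`,
   prevalence `= P(x_A = 1)`, lift `= confidence / P(y = 1)`; all
   computed exactly from integer counts. A rule is retained iff
   support > 1.5%, confidence > 10% and lift > 1.0 — strict
   inequalities on *unrounded* values. (A published rule can print as
   lift 1.0 after one-decimal rounding and still pass; filtering before
   rounding is the only consistent reading.)
4. **Weighting** (`fit_cox()`, `assign_weights()`). Two proportional
   hazards models are fitted on the training set with the Efron tie
   correction: Model 1 with age, sex and the 13 conditions; Model 2
   additionally with one conjunction indicator per mined rule, main
   effects retained. Each condition or pair predictor is then weighted
   from its unrounded adjusted hazard ratio:
   weight 1 for HR in [1.0, 1.2), 2 for [1.2, 1.5), 3 for HR ≥ 1.5,
   and 0 (excluded) for HR < 1. Age and sex are adjustment covariates
   only and are never weighted. The index score is the sum of the
   weights of the predictors present; `max_score` is attained by a
   participant with every weighted predictor present.
5. **Evaluation** (`evaluate_models()`). On the validation set, 5-year
   risk is predicted as `1 − S0(5)^exp(lp)` with the Breslow baseline
   survival and the centred linear predictor, for the base model
   (age + sex) and the base model plus condition count, MI or MIDC as a
   single score covariate. Models are compared by Harrell's C, the
   integrated discrimination improvement (IDI) and the continuous net
   reclassification improvement (NRI).

## Evaluation statistics: exact conventions

**Harrell's C.** A pair of participants is comparable iff the smaller
observed time belongs to an event; pairs with equal observed times are
comparable only when both are events. Concordance credit is 1 when the
earlier event carries the higher predicted risk, 0.5 for exact risk
ties and for equal-time event pairs, 0 otherwise. These conventions are
pinned down so that the implementation can be tested for exact equality
against a brute-force all-pairs enumeration; on tie-free data it agrees
with `survival::concordance()` to machine precision. Which concordance
variant the original analysis used is not recoverable from the published
description; Harrell's convention is this package's choice and users
comparing absolute C values elsewhere should note the variant.

**IDI.** `idi = slope_new − slope_old`, a model's discrimination slope
being the mean predicted risk among events minus the mean among
non-events. **Continuous NRI.**
`nri = [P(up|event) − P(down|event)] + [P(down|non-event) − P(up|non-event)]`
with "up"/"down" meaning strict risk movement and exact ties contributing
zero; range [−2, 2].

**Censoring in IDI/NRI.** Both statistics need a binary 5-year outcome.
Participants censored before the horizon have an unknown status and are
excluded (complete-case); with the calibrated ~16% loss to follow-up
this drops about one participant in six from these two statistics (never
from C, which handles censoring natively). Inverse-probability-of-
censoring weighting would be the principled extension; it is documented
here as out of scope rather than half-implemented.

**Inference.** The published analysis names no test for the
comparisons, so a single uniform procedure is used for all three:
participant-level nonparametric bootstrap (default 1,000 resamples,
seeded), two-sided p-value `2 * min(P(Δ* ≤ 0), P(Δ* ≥ 0))` from the
resampled difference. p-values are exactly reproducible under a fixed
seed.

## The synthetic cohort generator

No public fixture of the original survey can ship with the package, so
the generator is a first-class module that emulates the *structure* of
that cohort with known ground truth:

* **Marginals.** The 13 condition prevalences equal the published
  descriptive proportions (hypertension 0.556 … Parkinson's disease and
  cancer 0.005); ages are discrete-uniform on 65–84 (the source reports
  only median/IQR, so a maximum-entropy choice over the supported range
  is used); 53.0% male.
* **Dependence.** Binary indicators are drawn by Gaussian-copula latent
  thresholding: a multivariate normal vector with a configured
  correlation matrix, condition j set to 1 when its latent coordinate
  exceeds the (1 − prevalence_j) quantile. This preserves marginals
  exactly in distribution and lets tests plant recoverable pairwise
  dependence. The 13 pair correlations corresponding to the published
  disease combinations are calibrated at construction time (by
  root-finding on the bivariate-normal orthant probability) so the
  model-implied joint prevalences match the published pair prevalences
  (e.g. hypertension ∧ depressive symptoms = 20.4%); all other pairs
  default to latent independence, since no other joint information is
  published.
* **Survival.** Event times are exponential with hazard
  `baseline_rate * exp(Σ β x + β_age (age − 65) + β_sex male)`; loss to
  follow-up is exponential and independent; administrative censoring at
  5 years; an event/censoring tie counts as an event (measure-zero but
  deterministic). A proportional-hazards analysis never identifies the
  baseline shape from these data, so the single-parameter exponential
  is the minimal honest choice. `baseline_rate = 0.018729` and
  `ltfu_rate = 0.042285` per person-year were pre-tuned by numerical
  root-finding on the large-sample expectations so that 25.2% of
  participants die and 16.3% are lost to follow-up within 5 years,
  matching the published cohort; age (HR 1.08/year) and male sex
  (HR 1.40) effects are typical old-age all-cause mortality gradients.
* **Ground-truth weights.** The default log-hazards place at least four
  predictors in every weight bin, three of them pair-interaction terms:
  hypertension and arthritis at HR 0.95 (the excluded bin, mirroring
  the published exclusion of those two conditions), four common
  conditions plus hypertension ∧ sensory impairment at HR 1.10, three
  conditions plus hypertension ∧ depressive symptoms at HR 1.35, and
  the four rare conditions (diabetes 1.8, bedridden 2.0, cancer 2.2,
  Parkinson's 2.5) plus cognitive impairment ∧ depressive symptoms
  (2.0) in the open ≥ 1.5 bin. Rare conditions are deliberately kept
  out of the two narrow interior bins: with prevalence below ~5% at
  n ≈ 8,000 the standard error of a log-hazard estimate (≳ 0.1)
  exceeds those bins' half-width (≈ 0.09–0.11 on the log scale), so no
  estimator could reliably recover an interior bin there. Placing
  strong hazards on rare severe diseases is also the epidemiologically
  realistic configuration.

**What the generator does not emulate** — and therefore what passing
tests do and do not show: the multi-wave dynamic enrolment of the real
survey (a single baseline cross-section is drawn), instrument-level
measurement (MMSE scores, depression items, blood-pressure readings),
higher-order dependence among conditions beyond pairwise copula
correlations, non-proportional or time-varying hazards, and
age/condition interactions. Tests passing on these synthetic cohorts
demonstrate that the pipeline's algebra, estimation and recovery
behaviour are correct under a faithful proportional-hazards world; they
do not reproduce the real-data hazard ratios or absolute C-statistics,
which would require the original survey data.

## Design choices where the procedure was genuinely open

* **Censored-before-horizon participants in rule metrics** count as
  non-events and stay in all denominators. This is the only reading
  under which "among all participants" proportions and the 25.2%
  marginal death fraction cohere; it biases confidence (hence lift)
  slightly toward zero, which is conservative for rule retention and is
  flagged as a limitation.
* **Antecedents are exactly pairs** (not "up to 2"): singletons are
  handled as individual conditions by MI, and only pairs are reported
  as combinations.
* **Weights come from one joint fit**; predictors with HR < 1 get
  weight 0 without refitting, since exclusion is described only for the
  final score calculation.
* **Unrounded HRs are binned.** Whether the original analysis rounded
  to two decimals before binning is unknowable; binning the unrounded
  value avoids an arbitrary rounding step and the half-open bins
  [1.0, 1.2) / [1.2, 1.5) reconcile the "1.19 / 1.20" phrasing exactly.
* **Model 2 keeps all main effects** when pair indicators are added
  ("further added"); any induced collinearity surfaces through the
  explicit separation/non-convergence error contract of `fit_cox()`
  rather than silent dropping.
* **Rules are mined on the full analytic sample** by default (the
  published combination table is reported for all participants), with
  `mine_scope = "training"` available for leakage-sensitive re-use.
* **Chi-square without continuity correction** in the descriptive
  table; the source is silent and the uncorrected statistic matches the
  textbook formula the tests verify.

## Numerical and degenerate-input behaviour

Zero-denominator rules are flagged `degenerate` with `NA` metrics, never
emitted as numbers. Constant design columns are dropped with a warning
before Cox fitting; separation or non-convergence raises an error naming
the offending predictor (|β| > 15 or SE > 10 on the log scale).
Rule output ordering is deterministic (support descending, antecedent
lexicographic within ties). All randomness flows through explicit
integer seeds: cohort generation is a pure function of
`(config, seed)`, and a pipeline rerun with the same configuration
reproduces rules, weights and point estimates exactly.

## Problem sizes used by the test-suite

The suite verifies marginal and calibration fidelity at n = 20,000
(tolerance ±0.01 on prevalences, justified by the binomial standard
error), rule-mining equivalence against brute-force counting on 200
random cohorts of n = 500, concordance against an all-pairs oracle on
100 instances of n ≤ 200, coefficient recovery (true HR 1.5, ±0.1 on
the log scale) and null-covariate CI coverage at n = 8,000, weight-bin
recovery on a dedicated planted design (12 predictors, four per bin,
prevalence 0.25, n = 8,000, 20 replicates, ≥ 80% of predictor-replicates
recovered — bin edges are finite-sample fragile, hence a tolerance
rather than exactness), and the qualitative validation-set pattern
(ΔC, IDI, NRI all positive for base + MIDC versus base) across 20
seeded replicates at the full cohort scale.

## Known limitations

The index transfers to new cohorts only through its serialised weight
table; absolute risk predictions additionally require the stored
baseline survival and covariate means, which are cohort-specific.
Cronbach's α is reported for continuity with the index-validation
literature, but weighted binary items with heterogeneous prevalences
bound α well below 1 even under a faithful model. The bootstrap p-value
for the C difference is approximate in small validation sets; 1,000
resamples put its Monte-Carlo resolution at 0.002.
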