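# midcindex

Weighted multimorbidity indices for 5-year mortality prediction in
community-dwelling older adults (ages 65–84), with disease-pair
combinations discovered by restrictive association rule mining.

## The problem

Multimorbidity — two or more chronic conditions in one person — is
usually summarised either as a raw condition count or as an index that
weights individual diseases. Neither captures the fact that specific
*combinations* of diseases (for example hypertension together with
depressive symptoms, or cognitive impairment together with depressive
symptoms) carry mortality risk beyond their parts. This package builds
and validates, end to end, two weighted indices over 13 binary chronic
conditions:

* **MI** — the multimorbidity index with individual diseases: integer
  weights on the 13 conditions;
* **MIDC** — the multimorbidity index incorporating disease
  combinations: the same construction with mined condition pairs added
  as extra weighted predictors;

and compares both, plus the simple condition count, against a base
model with age and sex for predicting death within 5 years.

## Method at a glance

1. **Rule mining.** Every unordered condition pair {A, B} is scored
   against the fixed consequent *death within 5 years*:
   support = P(A ∧ B ∧ death), confidence = P(death | A ∧ B),
   lift = confidence / P(death), prevalence = P(A ∧ B) — all exact
   integer-count ratios. A pair is a *disease combination* iff
   support > 1.5 %, confidence > 10 % and lift > 1.0 (strict, unrounded).
2. **Weighting.** Cox proportional-hazards models on a 70/30 training
   split (Efron ties): Model 1 with age, sex and the 13 conditions;
   Model 2 additionally with one conjunction indicator per mined pair.
   Each condition/pair predictor is weighted from its unrounded
   adjusted hazard ratio: HR ∈ [1.0, 1.2) → 1, [1.2, 1.5) → 2,
   ≥ 1.5 → 3, HR < 1 → excluded. An index score is the sum of the
   weights of the predictors present.
3. **Validation.** On the held-out 30 %: Harrell's C, the integrated
   discrimination improvement (IDI) and the continuous net
   reclassification improvement (NRI), each with participant-level
   bootstrap p-values; plus Cronbach's α of the MIDC items and Pearson
   correlations of MIDC with condition count and MI.

Because the original survey data cannot ship with the package, a
calibrated synthetic cohort generator (Gaussian-copula binary
conditions, exponential proportional-hazards survival, exponential
loss to follow-up, administrative censoring at 5 years) reproduces the
published cohort's structure — marginal prevalences, published
pair prevalences, ~25.2 % deaths and ~16.3 % loss to follow-up within
5 years — with known ground-truth hazards, so every stage is testable.
See `vignettes/multimorbidity-index-methods.Rmd` for the full methods
account.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
calibrated synthetic cohort (N = 11,853, seed 1) and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort, 70/30 split, descriptives
Rscript analysis/02_mine_rules.R    # disease combinations
Rscript analysis/03_build_indices.R # Cox fits, weights, MI & MIDC
Rscript analysis/04_evaluate.R      # C / IDI / NRI, reliability, validity
```

Stage 1 prints the calibration check — 11,853 participants, 8,298
training / 3,555 validation, 25.3 % 5-year deaths, 16.5 % lost to
follow-up — and stage 2 retains 11 of the 78 candidate pairs, e.g.:

```
                               antecedent support_pct confidence_pct lift prevalence_pct
         hypertension:depressive_symptoms         6.7           32.9  1.3           20.4
          hypertension:sensory_impairment         4.5           31.9  1.3           13.9
 cognitive_impairment:depressive_symptoms         2.0           57.3  2.3            3.5
```

Read: 20.4 % of participants have both hypertension and depressive
symptoms; 32.9 % of those die within 5 years, 1.3 times the marginal
5-year death rate; the combination-and-death event covers 6.7 % of the
cohort. Stage 3 turns the training-set hazard ratios into integer
weights (here MI spans 0–26 and MIDC 0–33; e.g. cognitive impairment ∧
depressive symptoms has HR 2.07 → weight 3). Stage 4 prints the
validation-set comparisons (1,000 bootstrap resamples):

```
       reference           model c_old c_new   p_c   idi p_idi    nri p_nri
            base condition_count 0.636 0.654 0.000 0.020 0.000  0.199  0.00
            base              MI 0.636 0.659 0.002 0.030 0.000  0.286  0.00
            base            MIDC 0.636 0.662 0.000 0.031 0.000  0.282  0.00
 condition_count              MI 0.654 0.659 0.020 0.010 0.000  0.195  0.00
 condition_count            MIDC 0.654 0.662 0.000 0.011 0.000  0.153  0.00
              MI            MIDC 0.659 0.662 0.080 0.001 0.392 -0.019  0.59

Cronbach's alpha (MIDC items): 0.51
Pearson r, MIDC vs condition count: 0.87 (p = 0)
Pearson r, MIDC vs MI: 0.94 (p = 0)
```

Every index beats the age-and-sex base model on all three criteria, and
the combination index (MIDC) tops condition count and MI on
discrimination — the qualitative pattern the index construction is
designed to produce. Absolute values are properties of the synthetic
cohort, not of any real survey.

The same run is available as a single call:

```r
library(midcindex)
res <- run_pipeline(pipeline_config(seed = 1, output_dir = "results"))
res$evaluation
```

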