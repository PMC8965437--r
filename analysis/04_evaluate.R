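#!/usr/bin/env Rscript
# Stage 4: predictive validity, reliability and construct validity on the
# validation set.
#
# Compares the base model (age + sex) with models adding condition count,
# MI and MIDC as a single score covariate: Harrell's C, IDI and
# continuous NRI with participant-level bootstrap p-values (1,000
# resamples). Also reports Cronbach's alpha of the MIDC item scores and
# Pearson correlations of MIDC with condition count and MI.

suppressPackageStartupMessages(library(midcindex))

seed <- 1L
training <- read_cohort("results/training.csv")
validation <- read_cohort("results/validation.csv")
mi <- read_index("results/index_mi.json")
midc <- read_index("results/index_midc.json")

ev <- evaluate_models(training, validation, mi, midc,
                      horizon = 5, resamples = 1000L, seed = seed)
write_evaluation(ev, "results/evaluation.csv", seed = seed)

midc_score <- score_index(midc, validation)
rel <- list(
  cronbach_alpha = cronbach_alpha(index_item_scores(midc, validation)),
  r_vs_count = pearson_validity(midc_score, condition_count(validation)),
  r_vs_mi = pearson_validity(midc_score, score_index(mi, validation)))
jsonlite::write_json(rel, "results/reliability.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("Model comparisons on the validation set (n =", nrow(validation), "):\n")
print(data.frame(reference = ev$reference, model = ev$model,
                 c_old = round(ev$c_old, 3), c_new = round(ev$c_new, 3),
                 p_c = round(ev$p_c, 3), idi = round(ev$idi, 3),
                 p_idi = round(ev$p_idi, 3), nri = round(ev$nri, 3),
                 p_nri = round(ev$p_nri, 3)),
      row.names = FALSE)
cat(sprintf("\nCronbach's alpha (MIDC items): %.2f\n", rel$cronbach_alpha))
cat(sprintf("Pearson r, MIDC vs condition count: %.2f (p = %.3g)\n",
            rel$r_vs_count$r, rel$r_vs_count$p))
cat(sprintf("Pearson r, MIDC vs MI: %.2f (p = %.3g)\n",
            rel$r_vs_mi$r, rel$r_vs_mi$p))
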