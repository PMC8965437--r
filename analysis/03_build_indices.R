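#!/usr/bin/env Rscript
# Stage 3: develop the two weighted multimorbidity indices on the
# training set.
#
# Fits the individual-disease model (age + sex + 13 conditions) and the
# combination model (additionally one conjunction indicator per mined
# rule) by Cox proportional hazards, converts unrounded hazard ratios to
# integer weights (HR in [1.0,1.2) -> 1, [1.2,1.5) -> 2, >= 1.5 -> 3,
# HR < 1 excluded), and writes the MI and MIDC weight tables.

suppressPackageStartupMessages(library(midcindex))

training <- read_cohort("results/training.csv")
rules <- read_rules("results/rules.csv")
dev <- develop_indices(training, rules, horizon = 5)

write_index(dev$mi, "results/index_mi.json")
write_index(dev$midc, "results/index_midc.json")

hr_table <- function(model, index) {
  preds <- setdiff(model$spec$covariates, c("age", "male"))
  data.frame(predictor = preds,
             hr = round(model$hazard_ratios[preds], 3),
             ci_low = round(model$ci95[preds, "low"], 3),
             ci_high = round(model$ci95[preds, "high"], 3),
             weight = index$weights[preds],
             row.names = NULL)
}
tab1 <- hr_table(dev$model1, dev$mi)
tab2 <- hr_table(dev$model2, dev$midc)
write.csv(tab1, "results/weights_mi.csv", row.names = FALSE)
write.csv(tab2, "results/weights_midc.csv", row.names = FALSE)

cat("Individual-disease index (MI): max score", dev$mi$max_score, "\n")
print(tab1, row.names = FALSE)
cat("\nCombination index (MIDC): max score", dev$midc$max_score, "\n")
print(tab2, row.names = FALSE)
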