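#!/usr/bin/env Rscript
# Stage 2: restrictive association rule mining on the full analytic sample.
#
# Enumerates all 78 condition pairs against the 5-year-mortality
# consequent and keeps rules with support > 1.5%, confidence > 10% and
# lift > 1.0 (strict, on unrounded values). Writes results/rules.csv.

suppressPackageStartupMessages(library(midcindex))

cohort <- read_cohort("results/cohort.csv")
rules <- mine_rules(cohort, arm_thresholds(), horizon = 5)
write_rules(rules, "results/rules.csv")

cat(sprintf("retained %d of %d candidate disease combinations\n\n",
            nrow(rules), choose(length(clhls_conditions()), 2)))
shown <- data.frame(antecedent = rules$antecedent,
                    support_pct = round(100 * rules$support, 1),
                    confidence_pct = round(100 * rules$confidence, 1),
                    lift = round(rules$lift, 1),
                    prevalence_pct = round(100 * rules$prevalence, 1))
print(shown, row.names = FALSE)
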