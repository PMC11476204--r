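#!/usr/bin/env Rscript
# Stage 5: apply the refit weighted model 4 to all screened variants,
# prioritize gnomAD-rare selected variants by position / effect / gene
# tier, and run the case-control burden analyses.

suppressPackageStartupMessages(library(cardiosplice))

cohort <- read_cohort("results/cohort")
screened <- read.delim("results/screened_variants.tsv",
                       stringsAsFactors = FALSE)
model <- readRDS("results/model4_weighted.rds")

scores <- predict(model, screened)
rare <- rare_in_controls(screened)
scores <- scores[match(rare$variant_id, screened$variant_id)]
prior <- prioritize_variants(rare, cohort$models, scores)
prior$selected <- prior$score >= 0.5
write.table(prior, "results/prioritized.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sel <- prior[prior$selected, ]
cat("Model-selected gnomAD-rare variants:", nrow(sel), "of", nrow(prior), "\n")
cat("\nPosition classes of selected variants:\n")
print(round(100 * prop.table(table(sel$region_class)), 1))
cat("\nPredicted effect classes:\n")
print(round(100 * prop.table(table(sel$effect_class)), 1))

cases <- cohort$samples$sample_id[cohort$samples$cohort == "case"]
controls <- cohort$samples$sample_id[cohort$samples$cohort == "control"]

syn <- count_synonymous(cohort$variants, cohort$samples$sample_id)
sb <- synonymous_burden(syn[cases], syn[controls])
cat(sprintf("\nSynonymous technical control: median %g vs %g, MWU p = %.3g\n",
            sb$median_cases, sb$median_controls, sb$p))

qual <- sel[sel$tier_call != "none", ]
burden <- rbind(
  carrier_burden(cases, controls, qual, "tier1_2_all"),
  carrier_burden(cases, controls,
                 qual[qual$tier_call == "tier1_reportable", ], "tier1"),
  carrier_burden(cases, controls,
                 qual[qual$region_class == "deep_intronic", ],
                 "deep_intronic"))
write.table(burden, "results/burden.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nCarrier burden (HA-corrected OR, Wald 95% CI, Fisher p):\n")
print(burden, row.names = FALSE, digits = 3)
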