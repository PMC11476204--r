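#!/usr/bin/env Rscript
# Stage 3: screen DNA variants (delta >= 0.2, PASS, internally rare),
# assemble model features, and label RNA-cohort variants by myocardial
# confirmation within +-100 bp of an altered splicing boundary.

suppressPackageStartupMessages(library(cardiosplice))

cohort <- read_cohort("results/cohort")
outliers <- read.delim("results/outliers.tsv", stringsAsFactors = FALSE)

screened <- screen_variants(cohort$variants)
screened <- assemble_features(screened, cohort$models, cohort$median_tpm)
write.table(screened, "results/screened_variants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rna <- cohort$samples$sample_id[cohort$samples$has_rna]
discovery <- screened[sub(",.*", "", screened$samples) %in% rna, ]
labeled <- label_variants(discovery, outliers)
write.table(labeled, "results/labeled_variants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

enr <- univariate_enrichment(labeled)
write.table(enr, "results/univariate_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

chd_genes <- cohort$models$genes$gene_id[cohort$models$genes$tier > 0]
orph <- orphan_events(outliers, screened, chd_genes)
write.table(orph, "results/orphan_events.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Screened", nrow(screened), "of", nrow(cohort$variants),
    "variants;", nrow(discovery), "carried by RNA-profiled samples\n")
print(table(labeled$label))
cat("\nUnivariable enrichment (confirmed vs unconfirmed):\n")
print(enr, row.names = FALSE)
cat("\nOrphan significant events in disease genes (no candidate DNA",
    "variant):", nrow(orph), "\n")
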