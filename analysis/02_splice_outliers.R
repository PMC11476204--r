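#!/usr/bin/env Rscript
# Stage 2: call per-sample aberrant splicing events (psi5 / psi3 / theta
# against the cohort beta-binomial null) and compute gene expression
# Z-scores on the RNA cohort.

suppressPackageStartupMessages(library(cardiosplice))

cohort <- read_cohort("results/cohort")
outliers <- splice_outliers(cohort$jcs)
write.table(outliers, "results/outliers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

retained <- filter_genes(cohort$gene_counts)
ez <- expression_zscores(cohort$gene_counts, retained)
write.table(data.frame(gene_id = rownames(ez$z), ez$z, check.names = FALSE),
            "results/expression_z.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- outliers[outliers$significant, ]
cat("Splice outlier calling:\n")
cat("  tested sample x site observations:", nrow(outliers), "\n")
cat("  significant events:", nrow(sig), "in",
    length(unique(sig$gene_id)), "genes\n")
cat("  median genes affected per sample:",
    median(table(factor(sig$sample, unique(outliers$sample)))), "\n")
cat("Expression:", length(retained), "of", nrow(cohort$gene_counts),
    "genes pass the >=10-counts-in->50%-samples filter\n")
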