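#!/usr/bin/env Rscript
# Stage 1: simulate the discovery study - a case cohort with genome
# sequencing plus myocardial RNA-Seq and a genome-only control cohort -
# with latent causal truth for every variant.

suppressPackageStartupMessages(library(cardiosplice))

seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))
cfg <- sim_config(seed = seed)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "results/cohort")

rna <- cohort$samples$has_rna
cat("Simulated cohort (seed ", seed, "):\n", sep = "")
cat("  samples:            ", nrow(cohort$samples), " (",
    sum(rna), " with RNA-Seq)\n", sep = "")
cat("  genes:              ", nrow(cohort$models$genes), "\n", sep = "")
cat("  screened variants:  ", nrow(cohort$variants), "\n", sep = "")
cat("  latent causal:      ", sum(cohort$truth$causal),
    sprintf(" (1 per %.0f variants)\n", 1 / mean(cohort$truth$causal)))
cat("  genes median TPM<1: ",
    sum(cohort$median_tpm < 1), "\n", sep = "")
cat("Written to results/cohort/\n")
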