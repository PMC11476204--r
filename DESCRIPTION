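Package: cardiosplice
Title: Heart-Specific Discovery of Splice-Disrupting Variants from Genome and
    Myocardial RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis framework for discovering splice-disrupting
    DNA variants in childhood heart disease cohorts by combining genome
    sequencing with myocardial RNA sequencing. Provides a synthetic cohort
    generator with latent causal truth; per-sample splice-outlier calling on
    psi5/psi3/theta metrics against a cohort beta-binomial null; gene
    expression Z-scores with a nonsense-mediated-decay check; SpliceAI-score
    based variant screening and feature assembly; DNA-to-RNA confirmation
    labeling; class-imbalance-aware random forest models with cross-validated
    evaluation; positional and gene-tier variant prioritization; and rare
    variant case-control carrier burden analysis with Haldane-Anscombe
    corrected odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    randomForest,
    DESeq2
Config/testthat/edition: 3
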