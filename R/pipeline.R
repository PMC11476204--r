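#' Default end-to-end pipeline configuration
#'
#' All thresholds default to the discovery decision rules: SpliceAI delta
#' >= 0.2 screen, internal rarity of at most one carrier, junction count
#' filter 15, outlier significance (FDR < 0.2, |Z| >= 1, |delta psi| >= 0.2,
#' expected psi <= 0.1 or >= 0.9), expression filter (>= 10 counts in > 50%
#' of samples), +-100 bp confirmation window, gnomAD 1e-4 rarity, pLI >=
#' 0.9 Tier 2 rule, and five-fold cross-validation. The global seed
#' deterministically derives per-stage seeds.
#'
#' @param seed Global integer seed.
#' @param sim A [sim_config()] for the synthetic cohort (its seed is derived
#'   from `seed`).
#' @param stages Named logical toggles: `simulate`, `splice`, `expression`,
#'   `screen`, `label`, `model`, `prioritize`, `burden`.
#' @param ... Threshold overrides: `delta_min`, `max_internal_carriers`,
#'   `min_junction_count`, `thresholds` ([outlier_thresholds()]),
#'   `expr_min_count`, `expr_min_frac`, `window`, `gnomad_max`, `pli_min`,
#'   `model` ([model_config()] template).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL, stages = NULL, ...) {
  dots <- list(...)
  stage_seed <- function(i) as.integer((seed * 1009L + i * 101L) %% 2147483647L)
  if (is.null(sim)) sim <- sim_config(seed = stage_seed(1L))
  defaults <- list(
    delta_min = 0.2, max_internal_carriers = 1L, min_junction_count = 15,
    thresholds = outlier_thresholds(), expr_min_count = 10,
    expr_min_frac = 0.5, window = 100, gnomad_max = 1e-4, pli_min = 0.9,
    model = model_config(feature_set = 4L, imbalance = "weighted",
                         seed = stage_seed(2L))
  )
  for (nm in names(dots)) defaults[[nm]] <- dots[[nm]]
  st <- list(simulate = TRUE, splice = TRUE, expression = TRUE,
             screen = TRUE, label = TRUE, model = TRUE,
             prioritize = TRUE, burden = TRUE)
  for (nm in names(stages)) st[[nm]] <- stages[[nm]]
  structure(c(list(seed = as.integer(seed), sim = sim, stages = st),
              defaults),
            class = "pipeline_config")
}

#' Run the discovery pipeline end to end
#'
#' Simulates (or accepts) a cohort, calls splice and expression outliers on
#' the RNA cohort, screens variants and assembles features, labels variants
#' by RNA confirmation, cross-validates the configured model and refits it
#' on all labeled data, prioritizes model-selected gnomAD-rare variants by
#' region/effect/tier, and runs the synonymous control and carrier burden
#' analyses. Stages can be toggled off; a stage whose upstream output is
#' missing fails with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built `sim_cohort` (used when the simulate
#'   stage is disabled).
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSVs plus a `run_log.tsv` of applied thresholds.
#' @return List with the artifacts of every executed stage.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- function(x, stage, from) {
    if (is.null(x)) stop("run_pipeline: stage '", stage,
                         "' requires output of disabled/missing stage '",
                         from, "'", call. = FALSE)
    x
  }
  res <- list(config = config)

  if (config$stages$simulate) cohort <- simulate_cohort(config$sim)
  res$cohort <- cohort

  outliers <- NULL
  if (config$stages$splice) {
    jcs <- need(cohort, "splice", "simulate")$jcs
    outliers <- splice_outliers(jcs, config$thresholds,
                                min_count = config$min_junction_count)
    res$outliers <- outliers
  }

  ez <- NULL
  if (config$stages$expression) {
    counts <- need(cohort, "expression", "simulate")$gene_counts
    retained <- filter_genes(counts, config$expr_min_count,
                             config$expr_min_frac)
    ez <- expression_zscores(counts, retained)
    res$expression <- ez
  }

  screened <- NULL
  if (config$stages$screen) {
    ch <- need(cohort, "screen", "simulate")
    screened <- screen_variants(ch$variants, config$delta_min,
                                config$max_internal_carriers)
    screened <- assemble_features(screened, ch$models, ch$median_tpm)
    res$screened <- screened
  }

  labeled <- NULL
  if (config$stages$label) {
    sc <- need(screened, "label", "screen")
    # only variants carried by an RNA-profiled sample can be confirmed or
    # refuted in the myocardium; genome-only carriers stay out of training
    rna <- cohort$samples$sample_id[cohort$samples$has_rna]
    sc <- sc[sub(",.*", "", sc$samples) %in% rna, , drop = FALSE]
    labeled <- label_variants(sc, need(outliers, "label", "splice"),
                              window = config$window)
    res$labeled <- labeled
    res$enrichment <- tryCatch(univariate_enrichment(labeled),
                               error = function(e) NULL)
  }

  model <- NULL
  if (config$stages$model) {
    cv <- cross_validate(need(labeled, "model", "label"), config$model)
    model <- cv$final_model
    res$cv <- cv
  }

  prioritized <- NULL
  if (config$stages$prioritize) {
    sc <- need(screened, "prioritize", "screen")
    scores <- predict(need(model, "prioritize", "model"), sc)
    rare <- rare_in_controls(sc, config$gnomad_max, config$gnomad_max)
    scores <- scores[match(rare$variant_id, sc$variant_id)]
    prioritized <- prioritize_variants(rare, cohort$models, scores,
                                       pli_min = config$pli_min)
    prioritized$selected <- prioritized$score >= config$model$vote_threshold
    res$prioritized <- prioritized
  }

  if (config$stages$burden) {
    ch <- need(cohort, "burden", "simulate")
    pr <- need(prioritized, "burden", "prioritize")
    cases <- ch$samples$sample_id[ch$samples$cohort == "case"]
    controls <- ch$samples$sample_id[ch$samples$cohort == "control"]
    syn <- count_synonymous(ch$variants, ch$samples$sample_id,
                            config$max_internal_carriers, config$gnomad_max)
    res$synonymous <- synonymous_burden(syn[cases], syn[controls])
    qualifying <- pr[pr$selected & pr$tier_call != "none", , drop = FALSE]
    res$burden <- rbind(
      carrier_burden(cases, controls, qualifying, "tier1_2_all"),
      carrier_burden(cases, controls,
                     qualifying[qualifying$tier_call == "tier1_reportable", ],
                     "tier1"),
      carrier_burden(cases, controls,
                     qualifying[qualifying$region_class == "deep_intronic", ],
                     "deep_intronic")
    )
  }

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(x, f) if (!is.null(x)) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$cohort)) write_cohort(res$cohort, file.path(out_dir, "cohort"))
  w(res$outliers, "outliers.tsv")
  if (!is.null(res$expression)) {
    w(data.frame(gene_id = rownames(res$expression$z), res$expression$z,
                 check.names = FALSE), "expression_z.tsv")
  }
  w(res$screened, "screened_variants.tsv")
  w(res$labeled, "labeled_variants.tsv")
  w(res$enrichment, "univariate_enrichment.tsv")
  if (!is.null(res$cv)) {
    pooled <- res$cv$pooled
    w(data.frame(metric = c("auc", "sensitivity", "specificity", "or_ha",
                            "fisher_p"),
                 value = c(pooled$auc, pooled$sensitivity,
                           pooled$specificity, pooled$or_ha,
                           pooled$fisher_p)),
      "cv_metrics.tsv")
    imp <- feature_importance(res$cv$final_model)
    w(data.frame(feature = names(imp), importance = as.numeric(imp)),
      "importances.tsv")
  }
  w(res$prioritized, "prioritized.tsv")
  w(res$burden, "burden.tsv")
  cfg <- res$config
  w(data.frame(
    parameter = c("seed", "delta_min", "max_internal_carriers",
                  "min_junction_count", "fdr", "min_z", "min_dpsi",
                  "psi_lo", "psi_hi", "expr_min_count", "expr_min_frac",
                  "window", "gnomad_max", "pli_min", "cv_folds",
                  "imbalance", "feature_set"),
    value = c(cfg$seed, cfg$delta_min, cfg$max_internal_carriers,
              cfg$min_junction_count, cfg$thresholds$fdr,
              cfg$thresholds$min_z, cfg$thresholds$min_dpsi,
              cfg$thresholds$psi_lo, cfg$thresholds$psi_hi,
              cfg$expr_min_count, cfg$expr_min_frac, cfg$window,
              cfg$gnomad_max, cfg$pli_min, cfg$model$cv_folds,
              cfg$model$imbalance, cfg$model$feature_set)),
    "run_log.tsv")
  invisible(out_dir)
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys: `seed`, `sim` (passed to [sim_config()]),
#' `stages`, and any threshold override accepted by [pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  sim <- if (is.null(y$sim)) NULL else do.call(sim_config, y$sim)
  extra <- y[setdiff(names(y), c("seed", "sim", "stages"))]
  do.call(pipeline_config,
          c(list(seed = seed, sim = sim, stages = y$stages), extra))
}
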