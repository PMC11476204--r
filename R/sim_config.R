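#' Configuration for the synthetic DNA + RNA cohort generator
#'
#' Bundles every tunable of the cohort simulator into a validated list.
#' Defaults describe a desk-scale discovery design: a case cohort with both
#' genome sequencing and myocardial RNA-Seq, plus a genome-only control
#' cohort, with roughly an 80:1 imbalance between variants that truly disrupt
#' splicing and those that do not.
#'
#' @param seed Integer seed; the same seed and config reproduce the cohort
#'   byte for byte.
#' @param n_case_samples,n_control_samples Cohort sizes. Cases carry RNA-Seq
#'   (junction counts, gene counts, TPM); controls are genome-only.
#' @param n_genes Number of genes, each on its own synthetic chromosome.
#' @param frac_tier1,frac_tier2 Proportions of genes annotated as Tier 1 /
#'   Tier 2 disease genes (remainder unannotated).
#' @param exons_per_gene Length-2 integer range (inclusive) of exon counts.
#' @param mean_depth Expected split-read count per annotated junction per
#'   sample for a gene at the cohort-typical expression level.
#' @param expr_lognormal_params Named numeric `c(mu, sigma)`: per-sample
#'   log-TPM is `gene_baseline + N(0, sigma)` where gene baselines are
#'   `N(mu, expr_gene_sd)` on the natural-log scale.
#' @param expr_gene_sd Between-gene SD of baseline log-TPM; with the default
#'   a realistic minority of genes falls below median TPM 1 and exercises
#'   the expression filter.
#' @param variants_per_sample Expected number of screened (delta >= 0.2)
#'   variants per sample.
#' @param causal_logit_coefs Named numeric
#'   `c(intercept, b_delta, b_logtpm, b_repeat)` of the latent logistic
#'   causality model on (max SpliceAI delta, log median TPM, repeat flag).
#' @param planted_delta_psi Magnitude of the splice perturbation planted for
#'   each causal variant in its carrier sample (psi scale).
#' @param nmd_shift Expression Z-score shift applied to the carrier sample of
#'   each causal variant's gene, emulating nonsense-mediated decay.
#' @param flag_probs Named numeric marginal probabilities
#'   `c(branchpoint, low_complexity, repeat)` for region-flag membership.
#' @param case_excess_rate Extra per-sample Poisson rate of causal variants
#'   in reportable Tier 1/2 genes for case samples; controls the planted
#'   case-control carrier burden.
#' @param frac_indel Fraction of variants that are indels rather than SNVs.
#' @param frac_multicarrier Fraction of variants assigned a second carrier
#'   (these fail the internal-rarity screen; used to exercise it).
#' @param alt_junction_frac Fraction of annotated junctions that receive a
#'   competing alternative junction at the same donor.
#' @param count_depth Expected gene-level read count per unit TPM.
#' @param nb_size Negative-binomial size (inverse dispersion) for all count
#'   draws.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_case_samples = 100L,
                       n_control_samples = 250L,
                       n_genes = 300L,
                       frac_tier1 = 0.10,
                       frac_tier2 = 0.30,
                       exons_per_gene = c(4L, 8L),
                       mean_depth = 80,
                       expr_lognormal_params = c(mu = 1.5, sigma = 0.25),
                       expr_gene_sd = 1.5,
                       variants_per_sample = 80,
                       causal_logit_coefs = c(intercept = -10, b_delta = 10,
                                              b_logtpm = 0.8, b_repeat = -1.5),
                       planted_delta_psi = 0.4,
                       nmd_shift = -0.2,
                       flag_probs = c(branchpoint = 0.02,
                                      low_complexity = 0.08,
                                      repeat_region = 0.25),
                       case_excess_rate = 0,
                       frac_indel = 0.10,
                       frac_multicarrier = 0.02,
                       alt_junction_frac = 0.15,
                       count_depth = 50,
                       nb_size = 10) {
  cfg <- list(
    seed = as.integer(seed),
    n_case_samples = as.integer(n_case_samples),
    n_control_samples = as.integer(n_control_samples),
    n_genes = as.integer(n_genes),
    frac_tier1 = frac_tier1,
    frac_tier2 = frac_tier2,
    exons_per_gene = as.integer(exons_per_gene),
    mean_depth = mean_depth,
    expr_lognormal_params = expr_lognormal_params,
    expr_gene_sd = expr_gene_sd,
    variants_per_sample = variants_per_sample,
    causal_logit_coefs = causal_logit_coefs,
    planted_delta_psi = planted_delta_psi,
    nmd_shift = nmd_shift,
    flag_probs = flag_probs,
    case_excess_rate = case_excess_rate,
    frac_indel = frac_indel,
    frac_multicarrier = frac_multicarrier,
    alt_junction_frac = alt_junction_frac,
    count_depth = count_depth,
    nb_size = nb_size
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, is.finite(cfg$seed))
  if (cfg$n_genes < 1L) {
    stop("sim_config: n_genes must be >= 1", call. = FALSE)
  }
  if (any(cfg$exons_per_gene < 2L)) {
    stop("sim_config: genes need at least 2 exons (one junction)", call. = FALSE)
  }
  props <- c(cfg$frac_tier1, cfg$frac_tier2, cfg$frac_indel,
             cfg$frac_multicarrier, cfg$alt_junction_frac, cfg$flag_probs)
  if (any(props < 0 | props > 1)) {
    stop("sim_config: proportions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$frac_tier1 + cfg$frac_tier2 > 1) {
    stop("sim_config: frac_tier1 + frac_tier2 must be <= 1", call. = FALSE)
  }
  if (cfg$planted_delta_psi < 0 || cfg$planted_delta_psi >= 1) {
    stop("sim_config: planted_delta_psi must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(
    all(c("mu", "sigma") %in% names(cfg$expr_lognormal_params)),
    all(c("intercept", "b_delta", "b_logtpm", "b_repeat") %in%
          names(cfg$causal_logit_coefs)),
    length(cfg$flag_probs) == 3L
  )
  invisible(cfg)
}
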