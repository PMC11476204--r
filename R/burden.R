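#' Synonymous-variant technical burden control
#'
#' Compares per-sample counts of rare synonymous variants between cases and
#' controls with a two-sided Mann-Whitney U test (normal approximation with
#' tie correction). A significant difference flags technical artefacts
#' (platform, pipeline, reference) rather than biology.
#'
#' @param case_counts,control_counts Per-sample counts (non-empty vectors).
#' @return List with `median_cases`, `median_controls`, `p`.
#' @export
synonymous_burden <- function(case_counts, control_counts) {
  stopifnot(length(case_counts) > 0, length(control_counts) > 0)
  p <- if (length(unique(c(case_counts, control_counts))) == 1L) 1 else
    stats::wilcox.test(case_counts, control_counts, exact = FALSE)$p.value
  list(median_cases = stats::median(case_counts),
       median_controls = stats::median(control_counts),
       p = p)
}

#' Count rare synonymous variants per sample
#'
#' Counts, for each sample, PASS variants annotated as synonymous in a
#' canonical transcript that are internally rare (carrier count at most
#' `max_internal_carriers`) and rare in gnomAD (both frequency fields below
#' `af_max`, missing treated as 0).
#'
#' @param variants Variant data frame (columns `filter`, `consequence`,
#'   `is_canonical`, `samples`, `n_carriers`, gnomAD frequency columns).
#' @param sample_ids Samples to report (zero-count samples included).
#' @param max_internal_carriers Internal rarity rule (default 1).
#' @param af_max gnomAD frequency cutoff (default 1e-4).
#' @return Named integer vector of per-sample counts over `sample_ids`.
#' @export
count_synonymous <- function(variants, sample_ids,
                             max_internal_carriers = 1L, af_max = 1e-4) {
  v <- variants[variants$filter == "PASS" &
                  variants$consequence == "synonymous" &
                  variants$is_canonical &
                  variants$n_carriers <= max_internal_carriers, ,
                drop = FALSE]
  v <- rare_in_controls(v, af_max, af_max)
  carriers <- unlist(strsplit(v$samples, ","))
  counts <- table(factor(carriers, levels = sample_ids))
  stats::setNames(as.integer(counts), sample_ids)
}

#' Case-control carrier burden of qualifying variants
#'
#' A sample is a carrier when it harbors at least one qualifying variant.
#' The two-sided Fisher exact p-value is computed on the raw 2x2 counts;
#' the odds ratio and its Wald 95% CI use Haldane-Anscombe corrected cells
#' (`exp(log OR +- 1.96 * sqrt(sum 1/(cell + 0.5)))`).
#'
#' @param case_samples,control_samples Sample id vectors (non-empty).
#' @param qualifying_variants Variant data frame whose `samples` column
#'   (comma-separated carriers) defines carrier status.
#' @param stratum Label describing the stratum (gene set / region class).
#' @return One-row data frame of class `burden_table` with the counts,
#'   `or_ha`, `ci_low`, `ci_high`, `fisher_p`.
#' @export
carrier_burden <- function(case_samples, control_samples,
                           qualifying_variants, stratum = "all") {
  if (length(case_samples) == 0L || length(control_samples) == 0L) {
    stop("carrier_burden: empty cohort", call. = FALSE)
  }
  carriers <- unique(unlist(strsplit(qualifying_variants$samples, ",")))
  a <- sum(case_samples %in% carriers)      # cases with
  b <- length(case_samples) - a             # cases without
  c_ <- sum(control_samples %in% carriers)  # controls with
  d <- length(control_samples) - c_         # controls without
  or_ha <- ha_odds_ratio(a, b, c_, d)
  se <- sqrt(sum(1 / (c(a, b, c_, d) + 0.5)))
  fisher_p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L))$p.value
  out <- data.frame(
    stratum = stratum,
    cases_with = a, cases_without = b,
    controls_with = c_, controls_without = d,
    or_ha = or_ha,
    ci_low = exp(log(or_ha) - 1.96 * se),
    ci_high = exp(log(or_ha) + 1.96 * se),
    fisher_p = fisher_p,
    stringsAsFactors = FALSE
  )
  class(out) <- c("burden_table", "data.frame")
  out
}

#' Case excess rate that plants a target carrier odds ratio
#'
#' Given the control-arm per-sample Poisson rate of qualifying variants
#' `baseline_rate` (carrier probability `1 - exp(-rate)`), returns the extra
#' case-arm rate such that the expected carrier odds ratio equals
#' `target_or`.
#'
#' @param target_or Target carrier odds ratio (> 0).
#' @param baseline_rate Baseline qualifying-variant rate per sample (> 0).
#' @return The extra per-sample rate for cases.
#' @export
excess_rate_for_or <- function(target_or, baseline_rate) {
  stopifnot(target_or > 0, baseline_rate > 0)
  p0 <- 1 - exp(-baseline_rate)
  odds1 <- target_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  -log(1 - p1) - baseline_rate
}
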