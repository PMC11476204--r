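#' Filter lowly expressed genes
#'
#' A gene is retained when it has at least `min_count` reads in strictly
#' more than `min_frac` of the samples (with the defaults: >= 10 counts in
#' more than 50% of samples).
#'
#' @param gene_counts Integer matrix (genes x samples).
#' @param min_count Minimal per-sample read count (default 10).
#' @param min_frac Fraction of samples that must exceed it, strict
#'   inequality (default 0.5).
#' @return Character vector of retained gene ids.
#' @export
filter_genes <- function(gene_counts, min_count = 10, min_frac = 0.5) {
  stopifnot(is.matrix(gene_counts), all(gene_counts >= 0))
  keep <- rowSums(gene_counts >= min_count) > min_frac * ncol(gene_counts)
  rownames(gene_counts)[keep]
}

#' Per-gene expression Z-scores on normalized log counts
#'
#' Normalizes by median-of-ratios size factors (computed across the
#' retained genes, excluding genes with a zero geometric mean from the
#' reference) and standardizes `log2(normalized count + 1)` per gene so each
#' retained gene's Z column has mean 0 and SD 1.
#'
#' @param gene_counts Integer matrix (genes x samples), >= 3 samples.
#' @param retained Gene ids to keep; default [filter_genes()] on the input.
#' @return List of class `expression_z` with `z` (retained genes x samples),
#'   `size_factors`, and `retained_genes`.
#' @export
expression_zscores <- function(gene_counts, retained = NULL) {
  stopifnot(is.matrix(gene_counts), ncol(gene_counts) >= 3L)
  if (is.null(retained)) retained <- filter_genes(gene_counts)
  counts <- gene_counts[retained, , drop = FALSE]
  log_geo <- rowMeans(log(counts))
  ref <- is.finite(log_geo)
  if (!any(ref)) stop("expression_zscores: no reference genes for size factors")
  sf <- apply(counts[ref, , drop = FALSE], 2L, function(col)
    exp(stats::median(log(col) - log_geo[ref])))
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("expression_zscores: undefined size factor (all-zero sample?)")
  }
  norm <- sweep(counts, 2L, sf, "/")
  lg <- log2(norm + 1)
  mu <- rowMeans(lg)
  sd <- apply(lg, 1L, stats::sd)
  z <- (lg - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  structure(list(z = z, size_factors = sf, retained_genes = retained),
            class = "expression_z")
}

#' Nonsense-mediated-decay check on expression Z-scores
#'
#' Compares the carrier-sample expression Z-scores of genes harboring
#' model-selected variants against those of rejected variants with a Welch
#' two-sided t-test. True splice-disrupting variants are expected to show
#' lower Z-scores (transcript degradation). Variants in genes that did not
#' pass the expression filter are skipped and counted.
#'
#' @param ez An `expression_z` object.
#' @param selected,rejected Data frames with columns `gene_id` and `samples`
#'   (first carrier is used).
#' @return List with `mean_z_selected`, `mean_z_rejected`, `p` (NA when a
#'   group has fewer than two usable values), group sizes and `n_skipped`.
#' @export
nmd_check <- function(ez, selected, rejected) {
  stopifnot(inherits(ez, "expression_z"))
  pull_z <- function(df) {
    if (nrow(df) == 0L) return(list(z = numeric(), skipped = 0L))
    gene <- df$gene_id
    sample <- sub(",.*", "", df$samples)
    ok <- gene %in% rownames(ez$z) & sample %in% colnames(ez$z)
    list(z = ez$z[cbind(gene[ok], sample[ok])], skipped = sum(!ok))
  }
  zs <- pull_z(selected)
  zr <- pull_z(rejected)
  if (length(zs$z) == 0L || length(zr$z) == 0L) {
    stop("nmd_check: empty group after resolving variants to Z-scores")
  }
  p <- if (length(zs$z) < 2L || length(zr$z) < 2L) NA_real_ else
    tryCatch(stats::t.test(zs$z, zr$z)$p.value, error = function(e) NA_real_)
  list(mean_z_selected = mean(zs$z), mean_z_rejected = mean(zr$z),
       p = p, n_selected = length(zs$z), n_rejected = length(zr$z),
       n_skipped = zs$skipped + zr$skipped)
}
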