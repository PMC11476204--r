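#' Screen variants for putative splice disruption
#'
#' Retains variants with a PASS filter flag, a maximum SpliceAI delta score
#' of at least `delta_min` (inclusive), and at most `max_internal_carriers`
#' carrier samples (the carrier-count form of the internal-rarity rule).
#' Records with malformed delta fields (missing or outside \[0, 1\]) are
#' rejected per-record and reported in the `"rejected"` attribute.
#'
#' @param variants Variant data frame with columns `filter`, `ds_ag`,
#'   `ds_al`, `ds_dg`, `ds_dl` and either `n_carriers` or a comma-separated
#'   `samples` column.
#' @param delta_min Minimal max delta score (default 0.2).
#' @param max_internal_carriers Maximal carrier-sample count (default 1).
#' @param require_pass Require `filter == "PASS"` (default TRUE).
#' @return The screened subset, with a `max_delta` column added and an
#'   attribute `rejected` (data frame of variant_id + reason).
#' @export
screen_variants <- function(variants, delta_min = 0.2,
                            max_internal_carriers = 1L,
                            require_pass = TRUE) {
  dcols <- c("ds_ag", "ds_al", "ds_dg", "ds_dl")
  stopifnot(all(dcols %in% names(variants)))
  d <- as.matrix(variants[, dcols])
  bad <- rowSums(!is.finite(d) | d < 0 | d > 1) > 0
  rejected <- data.frame(variant_id = variants$variant_id[bad],
                         reason = rep("malformed delta score", sum(bad)),
                         stringsAsFactors = FALSE)
  variants <- variants[!bad, , drop = FALSE]
  d <- d[!bad, , drop = FALSE]
  variants$max_delta <- if (nrow(variants)) apply(d, 1L, max) else numeric()

  n_carriers <- if (!is.null(variants$n_carriers)) variants$n_carriers else
    lengths(strsplit(variants$samples, ","))
  keep <- variants$max_delta >= delta_min &
    n_carriers <= max_internal_carriers
  if (require_pass) keep <- keep & variants$filter == "PASS"
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Filter variants to those rare in population controls
#'
#' Retains variants with gnomAD v2 allele frequency and gnomAD v3 PopMax
#' allele frequency both strictly below their cutoffs. Missing frequencies
#' are treated as 0 (absent from controls) and tallied in the
#' `"missing_af"` attribute.
#'
#' @param variants Variant data frame with `af_gnomad_v2`,
#'   `af_gnomad_v3_popmax`.
#' @param v2_max,v3_popmax_max Frequency cutoffs (default 1e-4 each).
#' @return The filtered subset with attribute `missing_af` (count).
#' @export
rare_in_controls <- function(variants, v2_max = 1e-4, v3_popmax_max = 1e-4) {
  v2 <- variants$af_gnomad_v2
  v3 <- variants$af_gnomad_v3_popmax
  missing <- is.na(v2) | is.na(v3)
  v2[is.na(v2)] <- 0
  v3[is.na(v3)] <- 0
  out <- variants[v2 < v2_max & v3 < v3_popmax_max, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing_af") <- sum(missing)
  out
}

#' Assemble the model feature vector for screened variants
#'
#' Adds to each variant: `max_delta`; `dist_junction`, the minimal absolute
#' distance from the variant position to any annotated junction endpoint
#' (donor or acceptor) of its gene (NA when the gene has no junctions;
#' indels use their leftmost reference position); `is_snv`; the three
#' region flags; and `median_tpm` from the discovery TPM table (NA when the
#' gene is absent). Missing values are carried as NA, never imputed —
#' downstream models omit incomplete rows. Variants not mapping to a known
#' gene are rejected (attribute `rejected`).
#'
#' @param variants Screened variant data frame.
#' @param models A `gene_models` object.
#' @param median_tpm Named per-gene median TPM vector.
#' @return The variant data frame with feature columns appended.
#' @export
assemble_features <- function(variants, models, median_tpm) {
  stopifnot(inherits(models, "gene_models"))
  known <- variants$gene_id %in% models$genes$gene_id
  rejected <- data.frame(variant_id = variants$variant_id[!known],
                         reason = rep("variant outside any gene", sum(!known)),
                         stringsAsFactors = FALSE)
  variants <- variants[known, , drop = FALSE]

  if (is.null(variants$max_delta)) {
    variants$max_delta <- apply(
      as.matrix(variants[, c("ds_ag", "ds_al", "ds_dg", "ds_dl")]), 1L, max)
  }
  ends_by_gene <- with(models$junctions,
                       split(c(donor, acceptor), c(gene_id, gene_id)))
  variants$dist_junction <- vapply(seq_len(nrow(variants)), function(i) {
    ends <- ends_by_gene[[variants$gene_id[i]]]
    if (is.null(ends)) return(NA_real_)
    min(abs(variants$pos[i] - ends))
  }, numeric(1))
  variants$is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  variants$median_tpm <- unname(median_tpm[variants$gene_id])
  rownames(variants) <- NULL
  attr(variants, "rejected") <- rejected
  variants
}
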