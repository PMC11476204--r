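#' Classify a variant's position relative to exon-intron structure
#'
#' Offsets are 1-based distances from the nearest exon boundary. Intronic
#' offsets 1-2 are the canonical splice site; intronic 3-8 and exonic 1-3
#' the splice region; exonic > 3 is plain exonic; intronic 9-10 is
#' proximal intronic; and intronic > 10 is deep intronic. The five classes
#' partition every in-gene position.
#'
#' @param variants Data frame with `gene_id` and `pos`.
#' @param models A `gene_models` object.
#' @return Character vector of region classes (one per variant).
#' @export
classify_position <- function(variants, models) {
  stopifnot(inherits(models, "gene_models"))
  ex_by_gene <- split(models$exons, models$exons$gene_id)
  vapply(seq_len(nrow(variants)), function(i) {
    e <- ex_by_gene[[variants$gene_id[i]]]
    if (is.null(e)) stop("classify_position: unknown gene ",
                         variants$gene_id[i])
    pos <- variants$pos[i]
    if (pos < min(e$start) || pos > max(e$end)) {
      stop("classify_position: position ", pos, " outside gene span of ",
           variants$gene_id[i])
    }
    inside <- pos >= e$start & pos <= e$end
    if (any(inside)) {
      off <- min(pos - e$start[inside], e$end[inside] - pos) + 1L
      if (off <= 3L) "splice_region" else "exonic"
    } else {
      prev_end <- max(e$end[e$end < pos])
      next_start <- min(e$start[e$start > pos])
      off <- min(pos - prev_end, next_start - pos)
      if (off <= 2L) "canonical_splice_site"
      else if (off <= 8L) "splice_region"
      else if (off <= 10L) "intronic_proximal"
      else "deep_intronic"
    }
  }, character(1))
}

#' Classify a variant's predicted splicing effect
#'
#' Loss when max(donor loss, acceptor loss) >= `threshold`; gain when
#' max(donor gain, acceptor gain) >= `threshold`; classes are `loss_only`,
#' `gain_only` or `both`. At least one must hold for any variant that
#' passed the delta >= 0.2 screen; otherwise this errors.
#'
#' @param variants Data frame with `ds_ag`, `ds_al`, `ds_dg`, `ds_dl`.
#' @param threshold Effect threshold, reusing the screening cut
#'   (default 0.2).
#' @return Character vector of effect classes.
#' @export
classify_effect <- function(variants, threshold = 0.2) {
  loss <- pmax(variants$ds_al, variants$ds_dl) >= threshold
  gain <- pmax(variants$ds_ag, variants$ds_dg) >= threshold
  if (any(!loss & !gain)) {
    stop("classify_effect: variant with neither loss nor gain >= ",
         threshold, " violates the screen precondition", call. = FALSE)
  }
  ifelse(loss & gain, "both", ifelse(loss, "loss_only", "gain_only"))
}

#' Apply the Tier 1 / Tier 2 gene reporting rules
#'
#' `tier1_reportable`: Tier 1 gene with dominant inheritance, or recessive
#' inheritance with a homozygous genotype. `tier2_reportable`: Tier 2 gene
#' with pLI >= `pli_min`. Everything else: `none`. Tier 1 genes lacking an
#' inheritance annotation are an error.
#'
#' @param variants Data frame with `gene_id` and `genotype`
#'   ("het" / "hom").
#' @param models A `gene_models` object.
#' @param pli_min pLI cutoff for Tier 2 (default 0.9).
#' @return Character vector of tier calls.
#' @export
tier_filter <- function(variants, models, pli_min = 0.9) {
  g <- models$genes[match(variants$gene_id, models$genes$gene_id), ]
  bad <- g$tier == 1L & is.na(g$inheritance)
  if (any(bad, na.rm = TRUE)) {
    stop("tier_filter: Tier 1 gene without inheritance annotation: ",
         paste(unique(g$gene_id[which(bad)]), collapse = ", "), call. = FALSE)
  }
  tier1 <- g$tier == 1L &
    (g$inheritance == "AD" |
       (g$inheritance == "AR" & variants$genotype == "hom"))
  tier2 <- g$tier == 2L & g$pli >= pli_min
  out <- rep("none", nrow(variants))
  out[which(tier2)] <- "tier2_reportable"
  out[which(tier1)] <- "tier1_reportable"
  out
}

#' Prioritize model-selected variants
#'
#' Annotates each variant with its model score, region class, effect class
#' and tier call.
#'
#' @param variants Screened/feature-annotated variant data frame.
#' @param models A `gene_models` object.
#' @param scores Numeric model scores aligned with `variants` (optional).
#' @param pli_min pLI cutoff for Tier 2 reporting.
#' @param effect_threshold Delta threshold for [classify_effect()].
#' @return The variant data frame with `score`, `region_class`,
#'   `effect_class`, `tier_call` appended.
#' @export
prioritize_variants <- function(variants, models, scores = NULL,
                                pli_min = 0.9, effect_threshold = 0.2) {
  if (!is.null(scores)) variants$score <- scores
  variants$region_class <- classify_position(variants, models)
  variants$effect_class <- classify_effect(variants, effect_threshold)
  variants$tier_call <- tier_filter(variants, models, pli_min)
  variants
}
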