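#' Label screened variants by myocardial RNA confirmation
#'
#' A variant is `confirmed` when a significant splice outlier exists in the
#' same gene and the same carrier sample with a boundary (donor or acceptor
#' coordinate) within `window` bp of the variant position (inclusive);
#' `indeterminate` when such an event exists in the gene and sample but only
#' beyond the window; otherwise `unconfirmed`. The three labels partition
#' the screened set. Indeterminate variants must be excluded from model
#' training and evaluation.
#'
#' @param screened Screened variant data frame (columns `variant_id`,
#'   `gene_id`, `samples`, `pos`; every variant must have a carrier).
#' @param outliers A `splice_outliers` data frame; only rows with
#'   `significant == TRUE` are used.
#' @param window Matching window in bp, inclusive (default 100).
#' @return The input with columns `label` and `matched_event` (site_id of
#'   the closest confirming event, NA otherwise) appended.
#' @export
label_variants <- function(screened, outliers, window = 100) {
  if (any(is.na(screened$samples) | screened$samples == "")) {
    stop("label_variants: variant with zero carrier samples", call. = FALSE)
  }
  ev <- outliers[outliers$significant, , drop = FALSE]
  carrier <- sub(",.*", "", screened$samples)
  key_v <- paste(screened$gene_id, carrier)
  ev_by_key <- split(ev[, c("site_id", "donor", "acceptor")],
                     paste(ev$gene_id, ev$sample))

  label <- rep("unconfirmed", nrow(screened))
  matched <- rep(NA_character_, nrow(screened))
  hit <- which(key_v %in% names(ev_by_key))
  for (i in hit) {
    e <- ev_by_key[[key_v[i]]]
    dist <- pmin(abs(screened$pos[i] - e$donor),
                 abs(screened$pos[i] - e$acceptor))
    if (min(dist) <= window) {
      label[i] <- "confirmed"
      matched[i] <- e$site_id[which.min(dist)]
    } else {
      label[i] <- "indeterminate"
    }
  }
  screened$label <- label
  screened$matched_event <- matched
  screened
}

#' Univariable enrichment of features in confirmed vs unconfirmed variants
#'
#' Two-sided Mann-Whitney U tests for the continuous features (`max_delta`,
#' `dist_junction`, `median_tpm`) and two-sided Fisher's exact tests for the
#' binary ones (`is_snv`, `in_branchpoint`, `in_low_complexity`,
#' `in_repeat`). Indeterminate variants are excluded; rows with a missing
#' value for a feature are dropped for that feature only. A degenerate
#' (all-identical) feature yields p = 1 with a warning.
#'
#' @param labeled Output of [label_variants()] with feature columns.
#' @return Data frame with `feature`, `type`, `statistic`, `p`.
#' @export
univariate_enrichment <- function(labeled) {
  df <- labeled[labeled$label != "indeterminate", , drop = FALSE]
  grp <- df$label == "confirmed"
  if (sum(grp) < 2L || sum(!grp) < 2L) {
    stop("univariate_enrichment: need >= 2 confirmed and >= 2 unconfirmed")
  }
  cont <- c("max_delta", "dist_junction", "median_tpm")
  bin <- c("is_snv", "in_branchpoint", "in_low_complexity", "in_repeat")
  rows <- lapply(c(cont, bin), function(f) {
    x <- df[[f]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L) {
      warning("univariate_enrichment: feature '", f, "' is degenerate")
      return(data.frame(feature = f,
                        type = if (f %in% cont) "mwu" else "fisher",
                        statistic = NA_real_, p = 1))
    }
    if (f %in% cont) {
      t <- stats::wilcox.test(x[ok & grp], x[ok & !grp], exact = FALSE)
      data.frame(feature = f, type = "mwu",
                 statistic = unname(t$statistic), p = t$p.value)
    } else {
      tab <- table(factor(x[ok], c(FALSE, TRUE)),
                   factor(grp[ok], c(FALSE, TRUE)))
      t <- stats::fisher.test(tab)
      data.frame(feature = f, type = "fisher",
                 statistic = unname(t$estimate), p = t$p.value)
    }
  })
  do.call(rbind, rows)
}

#' Significant splicing events without a candidate DNA variant
#'
#' Reports significant events in genes of interest whose carrier sample has
#' no screened variant in the same gene within the matching window. Such
#' orphan events are reported for review and never fed to model training.
#'
#' @param outliers A `splice_outliers` data frame.
#' @param screened Screened variant data frame.
#' @param gene_set Character vector of genes of interest.
#' @param window Matching window in bp (default 100).
#' @return Subset of significant `outliers` rows that are orphans.
#' @export
orphan_events <- function(outliers, screened, gene_set, window = 100) {
  ev <- outliers[outliers$significant & outliers$gene_id %in% gene_set, ,
                 drop = FALSE]
  if (nrow(ev) == 0L) return(ev)
  carrier <- sub(",.*", "", screened$samples)
  v_by_key <- split(screened$pos, paste(screened$gene_id, carrier))
  key_e <- paste(ev$gene_id, ev$sample)
  orphan <- vapply(seq_len(nrow(ev)), function(i) {
    pos <- v_by_key[[key_e[i]]]
    if (is.null(pos)) return(TRUE)
    all(pmin(abs(pos - ev$donor[i]), abs(pos - ev$acceptor[i])) > window)
  }, logical(1))
  out <- ev[orphan, , drop = FALSE]
  rownames(out) <- NULL
  out
}
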