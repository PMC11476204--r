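#' Construct a junction count set
#'
#' The substrate of the psi5/psi3/theta splice metrics: per-sample split-read
#' counts per junction, and per-sample (split, nonsplit) counts per splice
#' site for the intron-retention metric.
#'
#' @param junctions Data frame with columns `junction_id`, `gene_id`,
#'   `chrom`, `donor`, `acceptor` and optionally `annotated` (default TRUE).
#'   Sites mapping to several genes may carry comma-separated `gene_id`.
#' @param split Integer matrix (junctions x samples) of split-read counts;
#'   rownames must match `junctions$junction_id`.
#' @param sites Data frame with `site_id`, `gene_id`, `chrom`, `donor`,
#'   `acceptor` (and optionally `junction_id`).
#' @param site_split,site_nonsplit Integer matrices (sites x samples).
#' @return A list of class `junction_count_set`.
#' @export
junction_count_set <- function(junctions, split,
                               sites = NULL, site_split = NULL,
                               site_nonsplit = NULL) {
  if (is.null(junctions$annotated)) junctions$annotated <- TRUE
  stopifnot(
    all(c("junction_id", "gene_id", "chrom", "donor", "acceptor") %in%
          names(junctions)),
    nrow(split) == nrow(junctions),
    all(junctions$donor < junctions$acceptor),
    all(split >= 0)
  )
  storage.mode(split) <- "integer"
  rownames(split) <- junctions$junction_id
  if (!is.null(sites)) {
    stopifnot(nrow(site_split) == nrow(sites),
              nrow(site_nonsplit) == nrow(sites),
              all(site_split >= 0), all(site_nonsplit >= 0))
    storage.mode(site_split) <- "integer"
    storage.mode(site_nonsplit) <- "integer"
    rownames(site_split) <- rownames(site_nonsplit) <- sites$site_id
  }
  structure(list(junctions = junctions, split = split, sites = sites,
                 site_split = site_split, site_nonsplit = site_nonsplit),
            class = "junction_count_set")
}

#' Filter junctions and sites by a minimal read-count requirement
#'
#' Retains exactly the junctions whose maximum split count across samples
#' reaches `min_count`, and the sites whose maximum total coverage
#' (split + nonsplit) does. `min_count = 0` is the identity.
#'
#' @param jcs A `junction_count_set`.
#' @param min_count Minimal read count required in at least one sample
#'   (default 15).
#' @return The filtered `junction_count_set`.
#' @export
filter_junctions <- function(jcs, min_count = 15) {
  stopifnot(inherits(jcs, "junction_count_set"))
  keep_j <- apply(jcs$split, 1L, max) >= min_count
  jcs$junctions <- jcs$junctions[keep_j, , drop = FALSE]
  jcs$split <- jcs$split[keep_j, , drop = FALSE]
  if (!is.null(jcs$sites)) {
    keep_s <- apply(jcs$site_split + jcs$site_nonsplit, 1L, max) >= min_count
    jcs$sites <- jcs$sites[keep_s, , drop = FALSE]
    jcs$site_split <- jcs$site_split[keep_s, , drop = FALSE]
    jcs$site_nonsplit <- jcs$site_nonsplit[keep_s, , drop = FALSE]
  }
  if (nrow(jcs$junctions) == 0L) {
    warning("filter_junctions: no junction passed the count filter")
  }
  jcs
}

#' Compute a splice metric (psi5, psi3 or theta) from junction counts
#'
#' * psi5 of a junction = its split count over the total split count of all
#'   junctions sharing the same donor (per chromosome);
#' * psi3 is symmetric over shared acceptors;
#' * theta of a site = split / (split + nonsplit).
#'
#' Sites with a zero denominator in a sample have undefined (NA) psi there.
#'
#' @param jcs A `junction_count_set`.
#' @param metric One of `"psi5"`, `"psi3"`, `"theta"`.
#' @return A list with `meta` (per-site data frame: `site_id`, `gene_id`,
#'   `metric`, `donor`, `acceptor`), `k` (numerator matrix sites x samples),
#'   `n` (denominator matrix) and `psi` (`k / n`, NA where `n == 0`).
#' @export
compute_psi <- function(jcs, metric = c("psi5", "psi3", "theta")) {
  stopifnot(inherits(jcs, "junction_count_set"))
  metric <- match.arg(metric)
  if (metric == "theta") {
    if (is.null(jcs$sites)) stop("compute_psi: no site-level counts")
    k <- jcs$site_split
    n <- jcs$site_split + jcs$site_nonsplit
    meta <- data.frame(site_id = jcs$sites$site_id,
                       gene_id = jcs$sites$gene_id,
                       metric = "theta",
                       donor = jcs$sites$donor,
                       acceptor = jcs$sites$acceptor,
                       stringsAsFactors = FALSE)
  } else {
    jn <- jcs$junctions
    key <- if (metric == "psi5") paste(jn$chrom, jn$donor)
           else paste(jn$chrom, jn$acceptor)
    grp <- match(key, unique(key))
    totals <- rowsum(jcs$split, grp, reorder = FALSE)
    k <- jcs$split
    n <- totals[as.character(grp), , drop = FALSE]
    rownames(n) <- rownames(k)
    meta <- data.frame(site_id = jn$junction_id,
                       gene_id = jn$gene_id,
                       metric = metric,
                       donor = jn$donor,
                       acceptor = jn$acceptor,
                       stringsAsFactors = FALSE)
  }
  psi <- k / n
  psi[n == 0] <- NA_real_
  list(meta = meta, k = k, n = n, psi = psi)
}
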