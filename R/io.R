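#' Read junction and site counts from long-format TSVs
#'
#' Inverse of the layout written by [write_cohort()]: `junctions.tsv` has
#' one row per junction x sample with a `split_count` column; `sites.tsv`
#' adds `nonsplit_count`. STAR `SJ.out.tab`-style input can be mapped to
#' this schema upstream (columns: chrom, donor, acceptor, per-sample
#' unique-read counts).
#'
#' @param junctions_tsv Path to the long-format junction table.
#' @param sites_tsv Optional path to the long-format site table.
#' @return A `junction_count_set`.
#' @export
read_junction_counts <- function(junctions_tsv, sites_tsv = NULL) {
  jl <- utils::read.delim(junctions_tsv, stringsAsFactors = FALSE)
  ids <- unique(jl$junction_id)
  samples <- unique(jl$sample)
  jn <- jl[match(ids, jl$junction_id),
           intersect(c("junction_id", "gene_id", "chrom", "donor",
                       "acceptor", "annotated"), names(jl))]
  split <- matrix(0L, length(ids), length(samples),
                  dimnames = list(ids, samples))
  split[cbind(match(jl$junction_id, ids), match(jl$sample, samples))] <-
    jl$split_count
  sites <- site_split <- site_nonsplit <- NULL
  if (!is.null(sites_tsv)) {
    sl <- utils::read.delim(sites_tsv, stringsAsFactors = FALSE)
    sids <- unique(sl$site_id)
    sites <- sl[match(sids, sl$site_id),
                intersect(c("site_id", "junction_id", "gene_id", "chrom",
                            "donor", "acceptor"), names(sl))]
    idx <- cbind(match(sl$site_id, sids), match(sl$sample, samples))
    site_split <- matrix(0L, length(sids), length(samples),
                         dimnames = list(sids, samples))
    site_nonsplit <- site_split
    site_split[idx] <- sl$split_count
    site_nonsplit[idx] <- sl$nonsplit_count
  }
  junction_count_set(jn, split, sites, site_split, site_nonsplit)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the cohort TSVs.
#' @return A list of class `sim_cohort` (without the generating config).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE)
  genes <- rd("genes.tsv")
  exons <- rd("exons.tsv")
  jcs <- read_junction_counts(file.path(dir, "junctions.tsv"),
                              file.path(dir, "sites.tsv"))
  ann <- jcs$junctions[jcs$junctions$annotated, , drop = FALSE]
  models <- structure(list(genes = genes, exons = exons,
                           junctions = ann[, c("junction_id", "gene_id",
                                               "chrom", "donor",
                                               "acceptor")]),
                      class = "gene_models")
  mat <- function(f) {
    d <- rd(f)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    m
  }
  tpm <- mat("tpm.tsv")
  structure(list(
    models = models, samples = rd("samples.tsv"),
    tpm = tpm, gene_counts = mat("gene_counts.tsv"),
    median_tpm = apply(tpm, 1L, stats::median),
    jcs = jcs, variants = rd("variants.tsv"), truth = rd("truth.tsv")
  ), class = "sim_cohort")
}
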