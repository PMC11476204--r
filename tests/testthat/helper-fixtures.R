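# Shared fixtures, all built in code.

# small, fast cohort configuration for property-style tests
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_case_samples = 30L, n_control_samples = 40L,
               n_genes = 80L, variants_per_sample = 30, mean_depth = 60)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# junction count set with two donors: donor A has two competing junctions
# with an outlier planted in `outlier_sample`; donor B is quiet.
planted_psi_fixture <- function(n_samples = 20L, depth = 100L,
                                cohort_psi = 0.95, outlier_psi = 0.2,
                                outlier_sample = n_samples) {
  samples <- sprintf("s%02d", seq_len(n_samples))
  jn <- data.frame(
    junction_id = c("jA1", "jA2", "jB1", "jB2"),
    gene_id = c("gA", "gA", "gB", "gB"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    donor = c(500L, 500L, 500L, 500L),
    acceptor = c(1500L, 1700L, 1500L, 1700L),
    stringsAsFactors = FALSE
  )
  split <- matrix(0L, 4L, n_samples, dimnames = list(jn$junction_id, samples))
  split["jA1", ] <- round(depth * cohort_psi)
  split["jA2", ] <- depth - round(depth * cohort_psi)
  split["jA1", outlier_sample] <- round(depth * outlier_psi)
  split["jA2", outlier_sample] <- depth - round(depth * outlier_psi)
  split["jB1", ] <- round(depth * 0.96)
  split["jB2", ] <- depth - round(depth * 0.96)
  junction_count_set(jn, split)
}

# theta-only fixture: one perturbed site, several quiet ones
planted_theta_fixture <- function(n_samples = 20L, depth = 100L,
                                  cohort_theta = 0.95, outlier_theta = 0.2,
                                  n_quiet = 5L, outlier_sample = n_samples) {
  samples <- sprintf("s%02d", seq_len(n_samples))
  ids <- c("site_hit", sprintf("site_q%d", seq_len(n_quiet)))
  genes <- c("gHit", sprintf("gQ%d", seq_len(n_quiet)))
  sites <- data.frame(
    site_id = ids, gene_id = genes,
    chrom = paste0("chr", seq_along(ids)),
    donor = 500L, acceptor = 1500L, stringsAsFactors = FALSE
  )
  site_split <- matrix(round(depth * cohort_theta), length(ids), n_samples,
                       dimnames = list(ids, samples))
  site_nonsplit <- matrix(depth - round(depth * cohort_theta),
                          length(ids), n_samples,
                          dimnames = list(ids, samples))
  site_split["site_hit", outlier_sample] <- round(depth * outlier_theta)
  site_nonsplit["site_hit", outlier_sample] <- depth - round(depth * outlier_theta)
  jn <- data.frame(junction_id = "jdummy", gene_id = "gHit", chrom = "chr1",
                   donor = 500L, acceptor = 1500L, stringsAsFactors = FALSE)
  split <- matrix(20L, 1L, n_samples, dimnames = list("jdummy", samples))
  junction_count_set(jn, split, sites, site_split, site_nonsplit)
}

# hand-enumerable gene models: five 3-exon genes covering the tier rules
toy_gene_models <- function() {
  mk_ex <- function(g, base) data.frame(
    gene_id = g, exon = 1:3,
    start = base + c(0L, 500L, 1000L),
    end = base + c(100L, 600L, 1100L)
  )
  genes <- data.frame(
    gene_id = c("GT1", "GT1R", "GT2", "GT2L", "GN"),
    chrom = paste0("chr", 1:5), strand = "+",
    tier = c(1L, 1L, 2L, 2L, 0L),
    inheritance = c("AD", "AR", NA, NA, NA),
    pli = c(0.99, 0.2, 0.95, 0.50, 0.10),
    n_exons = 3L, tx_start = 1000L, tx_end = 2100L,
    stringsAsFactors = FALSE
  )
  exons <- do.call(rbind, lapply(genes$gene_id, mk_ex, base = 1000L))
  junctions <- do.call(rbind, lapply(seq_len(5), function(i) data.frame(
    junction_id = sprintf("%s_j%d", genes$gene_id[i], 1:2),
    gene_id = genes$gene_id[i], chrom = genes$chrom[i],
    donor = c(1100L, 1600L), acceptor = c(1500L, 2000L),
    stringsAsFactors = FALSE
  )))
  structure(list(genes = genes, exons = exons, junctions = junctions),
            class = "gene_models")
}

# the ten-variant printed toy table; expected fates are hand-enumerated in
# test-acceptance.R
toy_variant_table <- function() {
  v <- data.frame(
    variant_id = sprintf("v%02d", 1:10),
    chrom = "chr1",
    pos = 1550L,
    ref = "A", alt = "C",
    gene_id = c("GT1", "GT1", "GT1", "GT1", "GT1",
                "GT1R", "GT1R", "GT2", "GT2L", "GN"),
    samples = c("s1", "s2", "s3", "s4,s5", "s6",
                "s7", "s8", "s9", "s1", "s2"),
    n_carriers = c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L),
    genotype = c("het", "het", "het", "het", "het",
                 "het", "hom", "het", "het", "het"),
    filter = c("PASS", "PASS", "LowQual", "PASS", "PASS",
               "PASS", "PASS", "PASS", "PASS", "PASS"),
    ds_ag = c(0.50, 0.19, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50),
    ds_al = 0.05, ds_dg = 0.10, ds_dl = 0.05,
    af_internal = 0.01,
    af_gnomad_v2 = c(0, 0, 0, 0, 2e-4, 5e-5, 0, 0, 0, 0),
    af_gnomad_v3_popmax = c(0, 0, 0, 0, 5e-5, 5e-5, 0, 0, 0, 0),
    in_branchpoint = FALSE, in_low_complexity = FALSE, in_repeat = FALSE,
    consequence = "intronic", is_canonical = TRUE,
    stringsAsFactors = FALSE
  )
  v$chrom <- toy_gene_models()$genes$chrom[
    match(v$gene_id, toy_gene_models()$genes$gene_id)]
  v
}

# expression_z stand-in built directly from a Z matrix
fake_expression_z <- function(z) {
  structure(list(z = z, size_factors = rep(1, ncol(z)),
                 retained_genes = rownames(z)),
            class = "expression_z")
}
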