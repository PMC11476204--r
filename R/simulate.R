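#' Simulate gene models with tier, inheritance and pLI annotations
#'
#' Each gene lives on its own synthetic chromosome on the + strand, with
#' non-overlapping sorted exons (1-based inclusive coordinates). Annotated
#' splice junctions are derived from adjacent exon pairs: the donor is the
#' last base of the upstream exon and the acceptor the first base of the
#' downstream exon, so donor < acceptor always holds.
#'
#' Tier 1 genes receive a dominant (AD) or recessive (AR) inheritance mode;
#' pLI is drawn from a bimodal mixture so that both constrained (pLI >= 0.9)
#' and unconstrained Tier 2 genes exist.
#'
#' @param config A [sim_config()].
#' @return A list of class `gene_models` with data frames `genes`, `exons`
#'   and `junctions`.
#' @export
simulate_gene_models <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  ng <- config$n_genes
  gene_id <- sprintf("G%04d", seq_len(ng))
  chrom <- sprintf("chr%d", seq_len(ng))

  n_tier1 <- round(config$frac_tier1 * ng)
  n_tier2 <- round(config$frac_tier2 * ng)
  tier <- rep(0L, ng)
  picked <- sample.int(ng, min(ng, n_tier1 + n_tier2))
  tier[picked[seq_len(min(n_tier1, length(picked)))]] <- 1L
  if (n_tier2 > 0 && length(picked) > n_tier1) {
    tier[picked[(n_tier1 + 1):length(picked)]] <- 2L
  }
  inheritance <- ifelse(tier == 1L,
                        sample(c("AD", "AR"), ng, replace = TRUE,
                               prob = c(0.6, 0.4)),
                        NA_character_)
  # bimodal pLI: ~35% of genes strongly LoF-intolerant
  hi <- stats::runif(ng) < 0.35
  pli <- ifelse(hi, stats::rbeta(ng, 12, 0.6), stats::rbeta(ng, 0.6, 4))

  exon_range <- seq(config$exons_per_gene[1], config$exons_per_gene[2])
  n_exons <- exon_range[sample.int(length(exon_range), ng, replace = TRUE)]
  exon_list <- vector("list", ng)
  for (g in seq_len(ng)) {
    ne <- n_exons[g]
    widths <- as.integer(round(stats::runif(ne, 50, 250)))
    introns <- as.integer(round(stats::runif(ne - 1L, 200, 2000)))
    starts <- ends <- integer(ne)
    pos <- 10000L
    for (e in seq_len(ne)) {
      starts[e] <- pos
      ends[e] <- pos + widths[e] - 1L
      if (e < ne) pos <- ends[e] + introns[e] + 1L
    }
    exon_list[[g]] <- data.frame(gene_id = gene_id[g], exon = seq_len(ne),
                                 start = starts, end = ends)
  }
  exons <- do.call(rbind, exon_list)

  genes <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = "+",
    tier = tier, inheritance = inheritance, pli = pli,
    n_exons = n_exons,
    tx_start = vapply(exon_list, function(e) min(e$start), integer(1)),
    tx_end = vapply(exon_list, function(e) max(e$end), integer(1)),
    stringsAsFactors = FALSE
  )

  jn <- lapply(seq_len(ng), function(g) {
    e <- exon_list[[g]]
    ne <- nrow(e)
    if (ne < 2L) return(NULL)
    data.frame(
      junction_id = sprintf("%s_j%d", gene_id[g], seq_len(ne - 1L)),
      gene_id = gene_id[g], chrom = chrom[g],
      donor = e$end[-ne], acceptor = e$start[-1L],
      stringsAsFactors = FALSE
    )
  })
  junctions <- do.call(rbind, jn)
  rownames(exons) <- rownames(genes) <- rownames(junctions) <- NULL

  structure(list(genes = genes, exons = exons, junctions = junctions),
            class = "gene_models")
}

#' Simulate per-sample gene expression (TPM and gene-level counts)
#'
#' Gene baselines are drawn once per gene as `N(mu, expr_gene_sd)` on the
#' natural-log scale and per-sample log-TPM adds `N(0, sigma)` noise; with
#' `sigma = 0` every sample shares the gene's TPM exactly. Gene-level counts
#' are negative-binomial with mean `count_depth * TPM`.
#'
#' @param models A `gene_models` object.
#' @param n_samples Number of samples.
#' @param config A [sim_config()].
#' @param sample_ids Optional sample names (default `R001...`).
#' @return List with matrices `tpm` and `counts` (genes x samples) and the
#'   per-gene baseline `log_tpm_baseline`.
#' @export
simulate_expression <- function(models, n_samples, config,
                                sample_ids = sprintf("R%03d", seq_len(n_samples))) {
  stopifnot(inherits(models, "gene_models"), n_samples >= 1L)
  ng <- nrow(models$genes)
  mu <- config$expr_lognormal_params[["mu"]]
  sigma <- config$expr_lognormal_params[["sigma"]]
  baseline <- stats::rnorm(ng, mu, config$expr_gene_sd)
  log_tpm <- matrix(baseline, ng, n_samples) +
    matrix(stats::rnorm(ng * n_samples, 0, sigma), ng, n_samples)
  tpm <- exp(log_tpm)
  counts <- matrix(
    stats::rnbinom(ng * n_samples, mu = config$count_depth * tpm,
                   size = config$nb_size),
    ng, n_samples
  )
  dimnames(tpm) <- dimnames(counts) <-
    list(models$genes$gene_id, sample_ids)
  list(tpm = tpm, counts = counts, log_tpm_baseline = baseline)
}

#' Simulate the screened variant table with latent causal truth
#'
#' Generates, for every sample, a Poisson number of DNA variants that have
#' already passed the SpliceAI delta >= 0.2 screen: four delta scores in
#' \[0, 1\] with maximum >= 0.2, region flags, gnomAD frequencies, and a
#' consequence annotation. A latent causal indicator is drawn from a
#' logistic model on (max delta, log median TPM, repeat flag), so causal
#' variants have stochastically larger delta scores and gene expression and
#' a lower repeat-region rate when the coefficients are (+, +, -). Causal
#' variants are positioned relative to a target junction: splice-site-loss
#' variants near an annotated junction boundary, cryptic-gain variants in
#' the interior of the target intron (the planted cryptic boundary is the
#' variant position itself). Case samples additionally receive
#' `case_excess_rate` extra causal variants in reportable Tier 1/2 genes.
#'
#' @param models A `gene_models` object.
#' @param samples Data frame with columns `sample_id`, `cohort`
#'   ("case"/"control") and `has_rna`.
#' @param median_tpm Named per-gene median TPM vector (discovery cohort).
#' @param config A [sim_config()].
#' @return List with data frames `variants` and `truth`.
#' @export
simulate_variants <- function(models, samples, median_tpm, config) {
  stopifnot(inherits(models, "gene_models"))
  genes <- models$genes
  junctions <- models$junctions
  ns <- nrow(samples)

  n_var <- stats::rpois(ns, config$variants_per_sample)
  carrier <- rep(samples$sample_id, n_var)
  nv <- length(carrier)
  gidx <- sample.int(nrow(genes), nv, replace = TRUE)

  # SpliceAI deltas: max delta from a right-skewed Beta, rescaled to [0.2, 1]
  maxd <- 0.2 + 0.8 * stats::rbeta(nv, 0.7, 4)
  channel <- sample.int(4L, nv, replace = TRUE)  # 1 AG, 2 AL, 3 DG, 4 DL
  # non-maximal channels are usually much smaller than the top score, so
  # most variants predict a single effect (gain or loss), few predict both
  deltas <- matrix(rep(maxd, 4L) * stats::rbeta(nv * 4L, 1, 4), nv, 4L)
  deltas[cbind(seq_len(nv), channel)] <- maxd

  flags <- config$flag_probs
  in_branchpoint <- stats::runif(nv) < flags[[1]]
  in_low_complexity <- stats::runif(nv) < flags[[2]]
  in_repeat <- stats::runif(nv) < flags[[3]]

  is_indel <- stats::runif(nv) < config$frac_indel
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  alt[is_indel] <- paste0(ref[is_indel], "T")

  ltpm <- log(pmax(median_tpm[genes$gene_id[gidx]], 1e-8))
  cf <- config$causal_logit_coefs
  eta <- cf[["intercept"]] + cf[["b_delta"]] * maxd +
    cf[["b_logtpm"]] * ltpm + cf[["b_repeat"]] * in_repeat
  causal <- stats::runif(nv) < stats::plogis(eta)

  # extra planted causal variants in reportable genes for case samples
  reportable <- genes$gene_id[(genes$tier == 1L &
                                 !is.na(genes$inheritance) &
                                 genes$inheritance == "AD") |
                                (genes$tier == 2L & genes$pli >= 0.9)]
  if (config$case_excess_rate > 0 && length(reportable) > 0) {
    case_ids <- samples$sample_id[samples$cohort == "case"]
    n_extra <- stats::rpois(length(case_ids), config$case_excess_rate)
    ne <- sum(n_extra)
    if (ne > 0) {
      carrier <- c(carrier, rep(case_ids, n_extra))
      gex <- match(sample(reportable, ne, replace = TRUE), genes$gene_id)
      gidx <- c(gidx, gex)
      mx <- 0.2 + 0.8 * stats::rbeta(ne, 5, 2)
      ch <- sample.int(4L, ne, replace = TRUE)
      dx <- matrix(rep(mx, 4L) * stats::rbeta(ne * 4L, 1, 4), ne, 4L)
      dx[cbind(seq_len(ne), ch)] <- mx
      deltas <- rbind(deltas, dx)
      maxd <- c(maxd, mx)
      in_branchpoint <- c(in_branchpoint, stats::runif(ne) < flags[[1]])
      in_low_complexity <- c(in_low_complexity, stats::runif(ne) < flags[[2]])
      in_repeat <- c(in_repeat, stats::runif(ne) < flags[[3]] / 2)
      r2 <- sample(bases, ne, replace = TRUE)
      ref <- c(ref, r2)
      alt <- c(alt, vapply(r2, function(r) sample(setdiff(bases, r), 1L), ""))
      is_indel <- c(is_indel, rep(FALSE, ne))
      causal <- c(causal, rep(TRUE, ne))
      nv <- nv + ne
    }
  }

  gene_of <- genes$gene_id[gidx]
  pos <- round(stats::runif(nv, genes$tx_start[gidx], genes$tx_end[gidx]))

  # causal variants: pick a target junction and reposition by mechanism
  target_junction <- rep(NA_character_, nv)
  mechanism <- rep(NA_character_, nv)
  ci <- which(causal)
  if (length(ci) > 0) {
    jn_by_gene <- split(seq_len(nrow(junctions)), junctions$gene_id)
    for (i in ci) {
      jrows <- jn_by_gene[[gene_of[i]]]
      j <- if (length(jrows) == 1L) jrows else sample(jrows, 1L)
      target_junction[i] <- junctions$junction_id[j]
      gain <- max(deltas[i, c(1L, 3L)]) >= max(deltas[i, c(2L, 4L)])
      mechanism[i] <- if (gain) "cryptic_gain" else "site_loss"
      donor <- junctions$donor[j]
      acceptor <- junctions$acceptor[j]
      if (gain) {
        lo <- donor + 10L
        hi <- acceptor - 10L
        pos[i] <- if (hi <= lo) donor + (acceptor - donor) %/% 2L else
          round(stats::runif(1, lo, hi))
      } else {
        endpoint <- if (stats::runif(1) < 0.5) donor else acceptor
        pos[i] <- endpoint + sample(c(-1L, 1L), 1L) * sample.int(40L, 1L)
      }
    }
  }

  # occasional second carrier (fails the internal-rarity screen)
  second <- stats::runif(nv) < config$frac_multicarrier & !causal
  extra_carrier <- ifelse(second,
                          sample(samples$sample_id, nv, replace = TRUE), NA)
  sample_str <- ifelse(second & extra_carrier != carrier,
                       paste(carrier, extra_carrier, sep = ","), carrier)
  n_carriers <- 1L + (second & extra_carrier != carrier)

  # position class drives the consequence annotation
  exon_hit <- logical(nv)
  ex_by_gene <- split(models$exons, models$exons$gene_id)
  for (g in unique(gene_of)) {
    rows <- which(gene_of == g)
    e <- ex_by_gene[[g]]
    exon_hit[rows] <- vapply(pos[rows], function(p)
      any(p >= e$start & p <= e$end), logical(1))
  }
  consequence <- ifelse(exon_hit,
                        sample(c("synonymous", "missense", "other"), nv,
                               replace = TRUE, prob = c(0.3, 0.5, 0.2)),
                        "intronic")

  af_gnomad_v2 <- ifelse(stats::runif(nv) < 0.7, 0,
                         10^stats::runif(nv, -6, -3))
  af_gnomad_v3 <- ifelse(stats::runif(nv) < 0.7, 0,
                         10^stats::runif(nv, -6, -3))
  # a slice of clearly-common variants exercises the gnomAD filter
  common <- stats::runif(nv) < 0.05 & !causal
  af_gnomad_v2[common] <- 10^stats::runif(nv, -3.5, -2)[common]

  variants <- data.frame(
    variant_id = sprintf("v%06d", seq_len(nv)),
    chrom = genes$chrom[gidx],
    pos = as.integer(pos),
    ref = ref, alt = alt,
    gene_id = gene_of,
    samples = sample_str,
    n_carriers = as.integer(n_carriers),
    genotype = sample(c("het", "hom"), nv, replace = TRUE,
                      prob = c(0.95, 0.05)),
    filter = ifelse(stats::runif(nv) < 0.97, "PASS", "LowQual"),
    ds_ag = deltas[, 1L], ds_al = deltas[, 2L],
    ds_dg = deltas[, 3L], ds_dl = deltas[, 4L],
    os_ag = sample(-50:50, nv, replace = TRUE),
    os_al = sample(-50:50, nv, replace = TRUE),
    os_dg = sample(-50:50, nv, replace = TRUE),
    os_dl = sample(-50:50, nv, replace = TRUE),
    af_internal = n_carriers / nrow(samples),
    af_gnomad_v2 = af_gnomad_v2,
    af_gnomad_v3_popmax = af_gnomad_v3,
    in_branchpoint = in_branchpoint,
    in_low_complexity = in_low_complexity,
    in_repeat = in_repeat,
    consequence = consequence,
    is_canonical = TRUE,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    variant_id = variants$variant_id,
    causal = causal,
    target_junction = target_junction,
    mechanism = mechanism,
    planted_dpsi = ifelse(causal, config$planted_delta_psi, 0),
    nmd = causal & config$nmd_shift != 0,
    clipped = FALSE,
    stringsAsFactors = FALSE
  )
  list(variants = variants, truth = truth)
}

#' Simulate baseline junction and splice-site counts for the RNA cohort
#'
#' Every annotated junction gets negative-binomial split-read counts whose
#' mean scales with the gene's per-sample TPM. A fraction of donors carries
#' a competing alternative junction: half with a substantial minor-isoform
#' share (these land in the 0.1 < expected psi < 0.9 band the outlier caller
#' excludes) and half with a small share. Each annotated junction also gets
#' a site-level (split, nonsplit) pair for the theta / intron-retention
#' metric, with a low baseline retention rate.
#'
#' @param models A `gene_models` object.
#' @param tpm TPM matrix (genes x RNA samples) from [simulate_expression()].
#' @param config A [sim_config()].
#' @return A `junction_count_set` (see [junction_count_set()]).
#' @export
simulate_junction_counts <- function(models, tpm, config) {
  stopifnot(inherits(models, "gene_models"))
  samples <- colnames(tpm)
  jn <- models$junctions
  jn$annotated <- TRUE
  jn$share <- 1

  n_alt <- round(config$alt_junction_frac * nrow(jn))
  if (n_alt > 0) {
    alt_of <- sample.int(nrow(jn), n_alt)
    big <- stats::runif(n_alt) < 0.5
    share <- ifelse(big, stats::runif(n_alt, 0.2, 0.5),
                    stats::runif(n_alt, 0.01, 0.05))
    alt <- data.frame(
      junction_id = paste0(jn$junction_id[alt_of], "_alt"),
      gene_id = jn$gene_id[alt_of], chrom = jn$chrom[alt_of],
      donor = jn$donor[alt_of],
      acceptor = jn$acceptor[alt_of] + sample(20:80, n_alt, replace = TRUE),
      annotated = FALSE, share = share,
      stringsAsFactors = FALSE
    )
    jn$share[alt_of] <- 1 - share
    jn <- rbind(jn, alt)
  }

  rel <- tpm[jn$gene_id, , drop = FALSE] /
    exp(config$expr_lognormal_params[["mu"]])
  mu <- config$mean_depth * rel * jn$share
  split <- matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_size),
                  nrow(jn), length(samples),
                  dimnames = list(jn$junction_id, samples))

  ann <- jn[jn$annotated, , drop = FALSE]
  sites <- data.frame(
    site_id = sub("_j", "_s", ann$junction_id),
    junction_id = ann$junction_id,
    gene_id = ann$gene_id, chrom = ann$chrom,
    donor = ann$donor, acceptor = ann$acceptor,
    stringsAsFactors = FALSE
  )
  retention <- stats::runif(nrow(sites), 0.01, 0.06)
  site_mu <- config$mean_depth * rel[jn$annotated, , drop = FALSE]
  site_split <- matrix(
    stats::rnbinom(length(site_mu), mu = site_mu * (1 - retention),
                   size = config$nb_size),
    nrow(sites), length(samples), dimnames = list(sites$site_id, samples))
  site_nonsplit <- matrix(
    stats::rnbinom(length(site_mu), mu = site_mu * retention,
                   size = config$nb_size),
    nrow(sites), length(samples), dimnames = list(sites$site_id, samples))

  junction_count_set(jn[, c("junction_id", "gene_id", "chrom", "donor",
                            "acceptor", "annotated")],
                     split, sites, site_split, site_nonsplit)
}

#' Plant splice effects (and NMD expression shifts) for causal variants
#'
#' For each causal variant whose carrier has RNA data, perturbs the carrier
#' sample only. Cryptic-gain variants re-allocate split reads from the
#' target junction to a new unannotated junction whose acceptor is the
#' variant position, preserving the per-donor split-read total. Site-loss
#' variants re-allocate site reads from split to nonsplit, reducing theta by
#' the planted amount while preserving the site total. When the full planted
#' shift would push psi below 0, the moved count is clipped and recorded in
#' `truth$clipped`. Genes of NMD-flagged variants have the carrier's gene
#' count scaled so its expression Z moves by approximately `nmd_shift`.
#'
#' @param variants,truth From [simulate_variants()].
#' @param jcs A `junction_count_set` of baseline counts.
#' @param gene_counts Gene-level count matrix (genes x RNA samples).
#' @param config A [sim_config()].
#' @return List with perturbed `jcs`, `gene_counts`, and updated `truth`.
#' @export
plant_splice_effects <- function(variants, truth, jcs, gene_counts, config) {
  dpsi <- config$planted_delta_psi
  rna_samples <- colnames(jcs$split)
  first_carrier <- sub(",.*", "", variants$samples)
  todo <- which(truth$causal & first_carrier %in% rna_samples)

  if (dpsi > 0 && length(todo) > 0) {
    for (i in todo) {
      sample <- first_carrier[i]
      jid <- truth$target_junction[i]
      j <- match(jid, jcs$junctions$junction_id)
      if (is.na(j)) next
      if (truth$mechanism[i] == "cryptic_gain") {
        donor <- jcs$junctions$donor[j]
        chrom <- jcs$junctions$chrom[j]
        same_donor <- which(jcs$junctions$chrom == chrom &
                              jcs$junctions$donor == donor)
        denom <- sum(jcs$split[same_donor, sample])
        move <- as.integer(round(dpsi * denom))
        avail <- jcs$split[j, sample]
        if (move > avail) {
          move <- avail
          truth$clipped[i] <- TRUE
        }
        cryptic_id <- paste0(jid, "_x", variants$variant_id[i])
        jcs$junctions <- rbind(jcs$junctions, data.frame(
          junction_id = cryptic_id, gene_id = jcs$junctions$gene_id[j],
          chrom = chrom, donor = donor, acceptor = variants$pos[i],
          annotated = FALSE, stringsAsFactors = FALSE))
        newrow <- matrix(0L, 1L, ncol(jcs$split),
                         dimnames = list(cryptic_id, colnames(jcs$split)))
        newrow[1L, sample] <- move
        jcs$split <- rbind(jcs$split, newrow)
        jcs$split[j, sample] <- avail - move
      } else {
        s <- match(jid, jcs$sites$junction_id)
        if (is.na(s)) next
        tot <- jcs$site_split[s, sample] + jcs$site_nonsplit[s, sample]
        move <- as.integer(round(dpsi * tot))
        avail <- jcs$site_split[s, sample]
        if (move > avail) {
          move <- avail
          truth$clipped[i] <- TRUE
        }
        jcs$site_split[s, sample] <- avail - move
        jcs$site_nonsplit[s, sample] <- jcs$site_nonsplit[s, sample] + move
      }
    }
  }

  nmd_rows <- which(truth$nmd & first_carrier %in% colnames(gene_counts))
  if (config$nmd_shift != 0 && length(nmd_rows) > 0) {
    lg <- log2(gene_counts + 1)
    sds <- apply(lg, 1L, stats::sd)
    for (i in nmd_rows) {
      g <- variants$gene_id[i]
      s <- first_carrier[i]
      factor <- 2^(config$nmd_shift * sds[g])
      gene_counts[g, s] <- as.integer(round(gene_counts[g, s] * factor))
    }
  }
  list(jcs = jcs, gene_counts = gene_counts, truth = truth)
}

#' Simulate a full case-control cohort with latent causal truth
#'
#' Runs the generator end to end: gene models, expression for the RNA (case)
#' cohort, variants for all samples, baseline junction counts, and planted
#' splice / NMD effects. A single RNG stream seeded from `config$seed` makes
#' the whole cohort reproducible.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `config`, `models`,
#'   `samples`, `tpm`, `gene_counts`, `median_tpm`, `jcs`, `variants`,
#'   `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  models <- simulate_gene_models(config)  # seeds the stream
  samples <- data.frame(
    sample_id = c(sprintf("CASE%04d", seq_len(config$n_case_samples)),
                  sprintf("CTRL%04d", seq_len(config$n_control_samples))),
    cohort = rep(c("case", "control"),
                 c(config$n_case_samples, config$n_control_samples)),
    stringsAsFactors = FALSE
  )
  samples$has_rna <- samples$cohort == "case"
  rna_ids <- samples$sample_id[samples$has_rna]

  expr <- simulate_expression(models, length(rna_ids), config,
                              sample_ids = rna_ids)
  median_tpm <- apply(expr$tpm, 1L, stats::median)
  vt <- simulate_variants(models, samples, median_tpm, config)
  jcs <- simulate_junction_counts(models, expr$tpm, config)
  planted <- plant_splice_effects(vt$variants, vt$truth, jcs,
                                  expr$counts, config)
  structure(list(
    config = config, models = models, samples = samples,
    tpm = expr$tpm, gene_counts = planted$gene_counts,
    median_tpm = median_tpm, jcs = planted$jcs,
    variants = vt$variants, truth = planted$truth
  ), class = "sim_cohort")
}

#' Write a simulated cohort to TSV files
#'
#' Emits `genes.tsv`, `exons.tsv`, `junctions.tsv` (long format), `sites.tsv`
#' (long format), `variants.tsv`, `truth.tsv`, `tpm.tsv` and
#' `gene_counts.tsv` under `dir`.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(cohort$models$genes, "genes.tsv")
  w(cohort$models$exons, "exons.tsv")
  jl <- cbind(cohort$jcs$junctions[rep(seq_len(nrow(cohort$jcs$junctions)),
                                       ncol(cohort$jcs$split)), ],
              sample = rep(colnames(cohort$jcs$split),
                           each = nrow(cohort$jcs$split)),
              split_count = as.vector(cohort$jcs$split))
  w(jl, "junctions.tsv")
  sl <- cbind(cohort$jcs$sites[rep(seq_len(nrow(cohort$jcs$sites)),
                                   ncol(cohort$jcs$site_split)), ],
              sample = rep(colnames(cohort$jcs$site_split),
                           each = nrow(cohort$jcs$site_split)),
              split_count = as.vector(cohort$jcs$site_split),
              nonsplit_count = as.vector(cohort$jcs$site_nonsplit))
  w(sl, "sites.tsv")
  w(cohort$variants, "variants.tsv")
  w(cohort$truth, "truth.tsv")
  w(data.frame(gene_id = rownames(cohort$tpm), cohort$tpm,
               check.names = FALSE), "tpm.tsv")
  w(data.frame(gene_id = rownames(cohort$gene_counts), cohort$gene_counts,
               check.names = FALSE), "gene_counts.tsv")
  w(cohort$samples, "samples.tsv")
  invisible(dir)
}
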