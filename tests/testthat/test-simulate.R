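test_that("gene model simulation is deterministic and respects tier fractions", {
  cfg <- sim_config(seed = 1, n_genes = 10)
  m1 <- simulate_gene_models(cfg)
  m2 <- simulate_gene_models(cfg)
  expect_identical(m1, m2)

  m0 <- simulate_gene_models(sim_config(seed = 2, n_genes = 40,
                                        frac_tier1 = 0))
  expect_false(any(m0$genes$tier == 1L))

  big <- simulate_gene_models(sim_config(seed = 3, n_genes = 200))
  expect_equal(sum(big$genes$tier == 1L), 20L)
  expect_equal(sum(big$genes$tier == 2L), 60L)
  # tier 1 genes always carry an inheritance mode; pLI spans both regimes
  expect_false(any(is.na(big$genes$inheritance[big$genes$tier == 1L])))
  t2 <- big$genes$pli[big$genes$tier == 2L]
  expect_true(any(t2 >= 0.9) && any(t2 < 0.9))
})

test_that("a gene with k exons yields k-1 ordered junctions", {
  m <- simulate_gene_models(sim_config(seed = 5, n_genes = 20,
                                       exons_per_gene = c(3L, 3L)))
  for (g in m$genes$gene_id) {
    jn <- m$junctions[m$junctions$gene_id == g, ]
    expect_equal(nrow(jn), 2L)
    expect_true(all(jn$donor < jn$acceptor))
  }
  # exons sorted and non-overlapping
  for (g in m$genes$gene_id) {
    e <- m$exons[m$exons$gene_id == g, ]
    expect_true(all(diff(e$start) > 0))
    expect_true(all(e$start[-1] > e$end[-nrow(e)]))
  }
})

test_that("configuration errors are caught", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(exons_per_gene = c(1L, 3L)), "exons")
  expect_error(sim_config(frac_tier1 = 1.2), "proportions")
  expect_error(sim_config(planted_delta_psi = 1.5), "planted_delta_psi")
})

test_that("expression generator matches its lognormal design", {
  cfg <- sim_config(seed = 7, n_genes = 150)
  m <- simulate_gene_models(cfg)

  # sigma = 0: within a gene every sample shares the TPM
  cfg0 <- cfg
  cfg0$expr_lognormal_params <- c(mu = 1.5, sigma = 0)
  e0 <- simulate_expression(m, 5, cfg0)
  expect_true(all(apply(e0$tpm, 1, function(x) diff(range(x))) < 1e-12))

  # reproducibility
  set.seed(99); ea <- simulate_expression(m, 5, cfg)
  set.seed(99); eb <- simulate_expression(m, 5, cfg)
  expect_identical(ea, eb)

  # with no between-gene spread the median of per-gene median TPM should
  # sit at exp(mu) within Monte-Carlo error (3 SE, SE of a median ~
  # 1.2533 * sigma_of_gene_medians / sqrt(n_genes))
  cfgm <- sim_config(seed = 8, n_genes = 400, expr_gene_sd = 0,
                     expr_lognormal_params = c(mu = 1.5, sigma = 0.25))
  mm <- simulate_gene_models(cfgm)
  em <- simulate_expression(mm, 50, cfgm)
  med <- apply(em$tpm, 1, median)
  se <- 1.2533 * sd(med) / sqrt(length(med))
  expect_lt(abs(median(med) - exp(1.5)), 3 * se)
  expect_true(all(em$tpm >= 0))
  expect_true(all(em$counts >= 0 & em$counts == round(em$counts)))
})

test_that("causal structure follows the logistic model's coefficients", {
  cfg <- small_config(seed = 11, variants_per_sample = 40)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  v <- co$variants
  expect_gte(sum(tr$causal), 20)
  maxd <- pmax(v$ds_ag, v$ds_al, v$ds_dg, v$ds_dl)
  ltpm <- log(co$median_tpm[v$gene_id])
  expect_gt(mean(maxd[tr$causal]), mean(maxd[!tr$causal]))
  expect_gt(mean(ltpm[tr$causal]), mean(ltpm[!tr$causal]))
  expect_lt(mean(v$in_repeat[tr$causal]), mean(v$in_repeat[!tr$causal]))

  # all deltas in [0,1] with max >= 0.2 (screened pool by construction)
  expect_true(all(maxd >= 0.2 & maxd <= 1))

  # probability-zero intercept: no causal variants
  cfg0 <- small_config(seed = 12)
  cfg0$causal_logit_coefs <- c(intercept = -1e6, b_delta = 10,
                               b_logtpm = 0.8, b_repeat = -1.5)
  co0 <- simulate_cohort(cfg0)
  expect_equal(sum(co0$truth$causal), 0L)
})

test_that("case_excess_rate = 0 gives exchangeable case/control causal counts", {
  cfg <- small_config(seed = 13)
  co <- simulate_cohort(cfg)
  carrier <- sub(",.*", "", co$variants$samples)
  cnt <- tapply(co$truth$causal, carrier, sum)
  cnt[setdiff(co$samples$sample_id, names(cnt))] <- 0
  is_case <- co$samples$cohort[match(names(cnt), co$samples$sample_id)] == "case"
  # same per-sample rate: Poisson two-sample comparison should be null
  p <- poisson.test(c(sum(cnt[is_case]), sum(cnt[!is_case])),
                    c(sum(is_case), sum(!is_case)))$p.value
  expect_gt(p, 0.001)
})

test_that("planted splice effects hit the carrier sample at the planted size", {
  cfg <- small_config(seed = 17)
  co <- simulate_cohort(cfg)
  rna <- co$samples$sample_id[co$samples$has_rna]
  carrier <- sub(",.*", "", co$variants$samples)
  idx <- which(co$truth$causal & carrier %in% rna &
                 co$truth$mechanism == "site_loss" & !co$truth$clipped)
  expect_gt(length(idx), 0)
  i <- idx[1]
  s <- match(co$truth$target_junction[i], co$jcs$sites$junction_id)
  sm <- carrier[i]
  th <- co$jcs$site_split[s, ] / (co$jcs$site_split[s, ] + co$jcs$site_nonsplit[s, ])
  others <- mean(th[setdiff(names(th), sm)], na.rm = TRUE)
  expect_lt(th[[sm]], others - 0.2)

  # planted_delta_psi = 0 leaves counts untouched
  cfg0 <- small_config(seed = 17)
  cfg0$planted_delta_psi <- 0
  cfg0$nmd_shift <- 0
  co0 <- simulate_cohort(cfg0)
  base <- simulate_cohort(cfg0)  # determinism double-check on the way
  expect_identical(co0$jcs$split, base$jcs$split)
})

test_that("cryptic-gain re-allocation preserves per-donor split totals", {
  cfg <- small_config(seed = 19)
  models <- simulate_gene_models(cfg)
  samples <- data.frame(sample_id = sprintf("R%03d", 1:20), cohort = "case",
                        has_rna = TRUE)
  expr <- simulate_expression(models, 20, cfg,
                              sample_ids = samples$sample_id)
  mt <- apply(expr$tpm, 1, median)
  vt <- simulate_variants(models, samples, mt, cfg)
  jcs <- simulate_junction_counts(models, expr$tpm, cfg)
  before <- rowsum(jcs$split,
                   paste(jcs$junctions$chrom, jcs$junctions$donor))
  planted <- plant_splice_effects(vt$variants, vt$truth, jcs,
                                  expr$counts, cfg)
  after <- rowsum(planted$jcs$split,
                  paste(planted$jcs$junctions$chrom,
                        planted$jcs$junctions$donor))
  expect_identical(before[rownames(before), ],
                   after[rownames(before), ])
})

test_that("cohort simulation is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 23)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # and TSV round trip is stable
  d1 <- file.path(tempdir(), "coA"); d2 <- file.path(tempdir(), "coB")
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
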