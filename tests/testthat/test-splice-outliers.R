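make_jcs <- function(split, donors, acceptors, genes = "g1",
                     chrom = "chr1") {
  n <- nrow(split)
  jn <- data.frame(junction_id = sprintf("j%d", seq_len(n)),
                   gene_id = rep_len(genes, n), chrom = rep_len(chrom, n),
                   donor = rep_len(donors, n),
                   acceptor = rep_len(acceptors, n),
                   stringsAsFactors = FALSE)
  colnames(split) <- sprintf("s%d", seq_len(ncol(split)))
  junction_count_set(jn, split)
}

test_that("junction filtering applies the >= 15 in at least one sample rule", {
  split <- rbind(c(14L, 14L, 14L), c(15L, 0L, 0L), c(100L, 2L, 3L))
  jcs <- make_jcs(split, donors = c(10L, 50L, 90L),
                  acceptors = c(20L, 60L, 100L))
  f <- filter_junctions(jcs, 15)
  expect_setequal(f$junctions$junction_id, c("j2", "j3"))
  f0 <- filter_junctions(jcs, 0)
  expect_equal(nrow(f0$junctions), 3L)
  expect_warning(filter_junctions(jcs, 1000), "no junction")
})

test_that("psi computations match hand arithmetic", {
  # donor shared by two junctions with counts 30 and 10
  split <- rbind(c(30L, 30L), c(10L, 10L))
  jcs <- make_jcs(split, donors = c(100L, 100L), acceptors = c(200L, 300L))
  psi5 <- compute_psi(jcs, "psi5")
  expect_equal(unname(psi5$psi[, 1]), c(0.75, 0.25))
  # different acceptors: psi3 of each junction is 1
  psi3 <- compute_psi(jcs, "psi3")
  expect_equal(unname(psi3$psi[, 1]), c(1, 1))

  # theta = split / (split + nonsplit) = 8 / 10
  sites <- data.frame(site_id = "st1", gene_id = "g1", chrom = "chr1",
                      donor = 100L, acceptor = 200L)
  jcs2 <- junction_count_set(jcs$junctions, split, sites,
                             matrix(8L, 1, 2), matrix(2L, 1, 2))
  th <- compute_psi(jcs2, "theta")
  expect_equal(unname(th$psi[1, ]), c(0.8, 0.8))

  # zero denominator is NA, not NaN-propagated
  split0 <- rbind(c(0L, 5L), c(0L, 5L))
  jcs0 <- make_jcs(split0, donors = c(100L, 100L), acceptors = c(200L, 300L))
  p0 <- compute_psi(jcs0, "psi5")
  expect_true(all(is.na(p0$psi[, 1])))
  expect_error(compute_psi(jcs, "psi9"))
})

test_that("psi5 sums to 1 over junctions sharing a donor (and psi3 per acceptor)", {
  set.seed(42)
  for (rep in 1:20) {
    n_j <- sample(3:8, 1)
    donors <- sample(c(100L, 200L, 300L), n_j, replace = TRUE)
    acceptors <- donors + sample(50:500, n_j)
    split <- matrix(rpois(n_j * 5, 20), n_j, 5)
    jcs <- make_jcs(split, donors, acceptors)
    for (metric in c("psi5", "psi3")) {
      ps <- compute_psi(jcs, metric)
      key <- if (metric == "psi5") ps$meta$donor else ps$meta$acceptor
      sums <- rowsum(ifelse(is.na(ps$psi), 0, ps$psi), key)
      pos <- rowsum(ps$n, key) > 0
      expect_true(all(abs(sums[pos] - 1) < 1e-12))
    }
  }
})

test_that("compute_psi agrees exactly with a nested-loop oracle", {
  oracle_psi5 <- function(jn, split) {
    out <- matrix(NA_real_, nrow(split), ncol(split))
    for (j in seq_len(nrow(split))) for (s in seq_len(ncol(split))) {
      denom <- 0
      for (j2 in seq_len(nrow(split))) {
        if (jn$chrom[j2] == jn$chrom[j] && jn$donor[j2] == jn$donor[j]) {
          denom <- denom + split[j2, s]
        }
      }
      if (denom > 0) out[j, s] <- split[j, s] / denom
    }
    out
  }
  set.seed(7)
  for (rep in 1:100) {
    n_j <- sample(2:10, 1)
    donors <- sample(c(10L, 20L, 30L, 40L), n_j, replace = TRUE)
    split <- matrix(rpois(n_j * 5L, 15), n_j, 5L)
    jcs <- make_jcs(split, donors, donors + 100L)
    got <- compute_psi(jcs, "psi5")$psi
    expect_equal(unname(got), oracle_psi5(jcs$junctions, split))
  }
})

test_that("method-of-moments null reproduces mean and variance of k/n", {
  k <- matrix(c(5L, 20L, 2L, 9L, 14L, 1L), 1)
  n <- matrix(c(20L, 25L, 20L, 12L, 20L, 18L), 1)
  psi_obj <- list(meta = data.frame(site_id = "x", gene_id = "g",
                                    metric = "psi5", donor = 1L,
                                    acceptor = 2L),
                  k = k, n = n, psi = k / n)
  null <- fit_null(psi_obj, min_samples = 3)
  phat <- as.vector(k / n)
  a <- null$alpha; b <- null$beta
  expect_equal(a / (a + b), mean(phat), tolerance = 1e-12)
  expect_equal(a * b / ((a + b)^2 * (a + b + 1)), var(phat),
               tolerance = 1e-12)
})

test_that("expected psi is leave-one-out, constant cohorts are their own expectation", {
  k <- matrix(c(9L, 9L, 0L), 1)
  n <- matrix(c(10L, 10L, 10L), 1)
  obj <- list(meta = data.frame(site_id = "x", gene_id = "g", metric = "psi5",
                                donor = 1L, acceptor = 2L),
              k = k, n = n, psi = k / n)
  null <- fit_null(obj, 3)
  expect_equal(unname(null$expected[1, 3]), 18 / 20)  # excludes own 0
  expect_equal(unname(null$expected[1, 1]), 9 / 20)

  kc <- matrix(rep(9L, 5), 1); nc <- matrix(rep(10L, 5), 1)
  objc <- list(meta = obj$meta, k = kc, n = nc, psi = kc / nc)
  nullc <- fit_null(objc, 3)
  expect_equal(unname(nullc$expected[1, ]), rep(0.9, 5))

  # sites with < 3 informative samples are skipped
  k2 <- rbind(c(5L, 5L, 5L), c(5L, 0L, 0L))
  n2 <- rbind(c(10L, 10L, 10L), c(10L, 0L, 0L))
  obj2 <- list(meta = data.frame(site_id = c("a", "b"), gene_id = "g",
                                 metric = "psi5", donor = 1:2,
                                 acceptor = 3:4),
               k = k2, n = n2, psi = ifelse(n2 > 0, k2 / n2, NA))
  null2 <- fit_null(obj2, 3)
  expect_equal(null2$skipped, "b")
  expect_equal(nrow(null2$meta), 1L)
})

test_that("betabinom_test doubles the smaller tail and is symmetric at the mode", {
  # against a direct dense-sum oracle
  dense_p <- function(k, n, a, b) {
    pmf <- exp(lchoose(n, 0:n) + lbeta(0:n + a, n - 0:n + b) - lbeta(a, b))
    lower <- sum(pmf[1:(k + 1)])
    upper <- sum(pmf[(k + 1):(n + 1)])
    min(1, 2 * min(lower, upper))
  }
  set.seed(1)
  for (i in 1:50) {
    n <- sample(5:80, 1); k <- sample(0:n, 1)
    a <- runif(1, 0.2, 50); b <- runif(1, 0.2, 50)
    expect_equal(betabinom_test(k, n, a, b), dense_p(k, n, a, b),
                 tolerance = 1e-9)
  }
  expect_true(is.na(betabinom_test(0, 0, 1, 1)))
})

test_that("a planted outlier is called and the boundary condition suppresses mid-psi sites", {
  jcs <- planted_theta_fixture()
  out <- splice_outliers(jcs)
  sig <- out[out$significant, ]
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$sample, "s20")
  expect_equal(sig$site_id, "site_hit")
  expect_lt(sig$psi_obs, 0.3)
  expect_gte(sig$psi_expected, 0.9)

  # expected psi ~0.5 everywhere: nothing can be significant
  mid <- planted_theta_fixture(cohort_theta = 0.5, outlier_theta = 0.0)
  out_mid <- splice_outliers(mid)
  expect_equal(sum(out_mid$significant), 0L)
})

test_that("multi-gene and gene-less sites are excluded from outlier output", {
  jcs <- planted_psi_fixture()
  jcs$junctions$gene_id[jcs$junctions$gene_id == "gB"] <- "gB,gC"
  out <- splice_outliers(jcs, min_count = 0)
  expect_false(any(grepl(",", out$gene_id)))
  jcs$junctions$gene_id[1:2] <- ""
  out2 <- splice_outliers(jcs, min_count = 0)
  expect_equal(nrow(out2), 0L)
})

test_that("FDR is a monotone transform of p within each sample", {
  co <- simulate_cohort(small_config(seed = 31))
  out <- splice_outliers(co$jcs)
  for (s in unique(out$sample)[1:5]) {
    d <- out[out$sample == s, ]
    o <- order(d$pvalue)
    expect_true(all(diff(d$fdr[o]) >= -1e-12))
  }
})

test_that("null simulations stay below the nominal FDR on average", {
  # data drawn from a common beta-binomial: no real outliers
  set.seed(55)
  n_rep <- 50
  frac <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    n_sites <- 30L; n_samp <- 20L
    p <- rbeta(n_sites * n_samp, 30 * 0.95, 30 * 0.05)
    depth <- matrix(rpois(n_sites * n_samp, 80), n_sites)
    k <- matrix(rbinom(n_sites * n_samp, as.vector(depth), p), n_sites)
    sites <- data.frame(site_id = sprintf("t%d", 1:n_sites),
                        gene_id = sprintf("g%d", 1:n_sites),
                        chrom = "chr1", donor = 100L, acceptor = 200L)
    jn <- data.frame(junction_id = "j1", gene_id = "g1", chrom = "chr1",
                     donor = 100L, acceptor = 200L)
    colnames(k) <- sprintf("s%d", 1:n_samp)
    jcs <- junction_count_set(jn, matrix(20L, 1, n_samp), sites,
                              k, depth - k)
    out <- splice_outliers(jcs, metrics = "theta", min_count = 0)
    frac[r] <- mean(out$significant)
  }
  expect_lte(mean(frac), 0.2)
})
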