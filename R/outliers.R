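#' Significance thresholds for splice-outlier calling
#'
#' Defaults are the discovery decision rule: FDR < 0.2, |Z| >= 1,
#' |delta psi| >= 0.2, and a leave-one-out expected psi/theta of <= 0.1 or
#' >= 0.9 (only near-constitutive or near-unused sites are interpretable).
#'
#' @param fdr BH false-discovery-rate cutoff (within-sample).
#' @param min_z Minimal absolute logit-scale Z-score.
#' @param min_dpsi Minimal absolute observed-minus-expected psi.
#' @param psi_lo,psi_hi Expected-psi band excluded from calling: events are
#'   kept only when expected psi <= `psi_lo` or >= `psi_hi`.
#' @return A validated list of class `outlier_thresholds`.
#' @export
outlier_thresholds <- function(fdr = 0.2, min_z = 1, min_dpsi = 0.2,
                               psi_lo = 0.1, psi_hi = 0.9) {
  th <- list(fdr = fdr, min_z = min_z, min_dpsi = min_dpsi,
             psi_lo = psi_lo, psi_hi = psi_hi)
  unitish <- c(fdr, min_dpsi, psi_lo, psi_hi)
  if (any(unitish < 0 | unitish > 1) || min_z < 0) {
    stop("outlier_thresholds: values outside their valid range", call. = FALSE)
  }
  structure(th, class = "outlier_thresholds")
}

#' Two-sided beta-binomial p-value
#'
#' `P = min(1, 2 * min(P(X <= k), P(X >= k)))` for `X ~ BetaBinomial(n, a, b)`
#' (the smaller tail is doubled and capped at 1).
#'
#' @param k,n Observed successes and trials (vectors).
#' @param a,b Beta parameters (vectors or scalars, recycled).
#' @return Vector of p-values.
#' @export
betabinom_test <- function(k, n, a, b) {
  m <- max(length(k), length(n), length(a), length(b))
  k <- rep_len(as.numeric(k), m); n <- rep_len(as.numeric(n), m)
  a <- rep_len(a, m); b <- rep_len(b, m)
  p <- rep(NA_real_, m)
  ok <- n > 0 & is.finite(a) & is.finite(b)
  if (!any(ok)) return(p)

  tail_sum <- function(which_idx, from, len) {
    # sum of pmf over `len` consecutive support points starting at `from`
    out <- numeric(length(which_idx))
    pos <- len > 0
    if (!any(pos)) return(out)
    wi <- which_idx[pos]
    idx <- rep(seq_along(wi), len[pos])
    i <- sequence(len[pos]) - 1L + rep(from[pos], len[pos])
    terms <- exp(lchoose(n[wi][idx], i) +
                   lbeta(i + a[wi][idx], n[wi][idx] - i + b[wi][idx]) -
                   lbeta(a[wi][idx], b[wi][idx]))
    out[pos] <- as.vector(rowsum(terms, idx, reorder = TRUE))
    out
  }

  pmf <- exp(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
  lower <- upper <- rep(NA_real_, m)
  # sum whichever tail is shorter; derive the other from the total
  lo_short <- ok & (k + 1 <= n - k + 1)
  hi_short <- ok & !lo_short
  wl <- which(lo_short)
  lower[wl] <- tail_sum(wl, rep(0, length(wl)), k[wl] + 1)
  upper[wl] <- pmin(1 - lower[wl] + pmf[wl], 1)
  wh <- which(hi_short)
  upper[wh] <- tail_sum(wh, k[wh], n[wh] - k[wh] + 1)
  lower[wh] <- pmin(1 - upper[wh] + pmf[wh], 1)
  lower <- pmin(lower, 1)
  upper <- pmin(upper, 1)
  p[ok] <- pmin(1, 2 * pmin(lower[ok], upper[ok]))
  p
}

#' Fit the per-site cohort null for a splice metric
#'
#' For every site with at least `min_samples` informative samples (defined
#' psi), fits a beta-binomial null by method of moments on the per-sample
#' proportions k/n: alpha and beta are chosen so the Beta mean and variance
#' match the sample mean and variance of k/n. Sites whose sample variance is
#' zero (or inconsistent with a Beta) get a near-degenerate concentration.
#' Each sample's p-value is computed against leave-one-out moments (`alpha_loo`,
#' `beta_loo`), so a true outlier cannot inflate the variance of its own
#' null; the all-sample `alpha`/`beta` are also returned. The leave-one-out
#' count-weighted expected psi is `(sum k - k_s) / (sum n - n_s)`, and the
#' Z-score is `logit((k+1)/(n+2))` standardized by the site's cohort mean
#' and SD.
#'
#' @param psi_obj Output of [compute_psi()].
#' @param min_samples Minimal informative samples per site (default 3).
#' @return List with `meta` (retained sites), `alpha`, `beta`, matrices
#'   `expected` and `z` aligned with `meta`, and `skipped` (site ids with
#'   too few informative samples).
#' @export
fit_null <- function(psi_obj, min_samples = 3L) {
  k <- psi_obj$k
  n <- psi_obj$n
  informative <- n > 0
  n_inf <- rowSums(informative)
  keep <- n_inf >= min_samples
  skipped <- psi_obj$meta$site_id[!keep]

  k <- k[keep, , drop = FALSE]
  n <- n[keep, , drop = FALSE]
  psi <- psi_obj$psi[keep, , drop = FALSE]
  meta <- psi_obj$meta[keep, , drop = FALSE]

  mom_ab <- function(m, v) {
    conc <- m * (1 - m) / v - 1
    conc[!is.finite(conc) | conc <= 0] <- 1e6
    conc <- pmin(conc, 1e6)
    list(alpha = pmax(m * conc, 1e-8), beta = pmax((1 - m) * conc, 1e-8))
  }
  m <- rowMeans(psi, na.rm = TRUE)
  v <- apply(psi, 1L, stats::var, na.rm = TRUE)
  ab <- mom_ab(m, v)
  alpha <- ab$alpha
  beta <- ab$beta

  # leave-one-out moments: each sample is tested against the null fitted
  # on the other samples, so an outlier cannot widen its own null
  psi0 <- psi
  psi0[is.na(psi0)] <- 0
  inf01 <- (n > 0) + 0
  ni <- rowSums(inf01)
  S1 <- rowSums(psi0)
  S2 <- rowSums(psi0^2)
  m_loo <- (S1 - psi0) / (ni - 1)
  v_loo <- (S2 - psi0^2 - (ni - 1) * m_loo^2) / (ni - 2)
  v_loo[v_loo < 0] <- 0
  ab_loo <- mom_ab(m_loo, v_loo)
  alpha_loo <- ab_loo$alpha
  beta_loo <- ab_loo$beta
  alpha_loo[n == 0] <- NA_real_
  beta_loo[n == 0] <- NA_real_

  K <- rowSums(k)
  N <- rowSums(n)
  expected <- (K - k) / (N - n)
  expected[(N - n) == 0] <- NA_real_
  expected[n == 0] <- NA_real_

  l <- stats::qlogis((k + 1) / (n + 2))
  l[n == 0] <- NA_real_
  lm <- rowMeans(l, na.rm = TRUE)
  lsd <- apply(l, 1L, stats::sd, na.rm = TRUE)
  z <- (l - lm) / lsd
  z[!is.finite(z)] <- 0
  z[n == 0] <- NA_real_

  list(meta = meta, alpha = alpha, beta = beta,
       alpha_loo = alpha_loo, beta_loo = beta_loo,
       k = k, n = n, psi = psi,
       expected = expected, z = z, skipped = skipped)
}

#' Call per-sample splice outliers against a fitted null
#'
#' Computes a two-sided beta-binomial p-value for every informative
#' sample x site pair, adjusts p-values by Benjamini-Hochberg within each
#' sample across its tested sites, and flags events as significant when all
#' four threshold conditions hold. Events whose site maps to zero genes or
#' to two or more genes (comma-separated `gene_id`) are dropped before
#' output. Row order is deterministic (metric, site coordinates, sample).
#'
#' @param null Output of [fit_null()].
#' @param thresholds An [outlier_thresholds()].
#' @return Data frame of class `splice_outliers` with columns `sample`,
#'   `gene_id`, `metric`, `site_id`, `donor`, `acceptor`, `psi_obs`,
#'   `psi_expected`, `delta_psi`, `zscore`, `pvalue`, `fdr`, `significant`.
#' @export
call_outliers <- function(null, thresholds = outlier_thresholds()) {
  stopifnot(inherits(thresholds, "outlier_thresholds"))
  nsite <- nrow(null$meta)
  samples <- colnames(null$k)
  if (nsite == 0L) return(empty_outliers())

  pv <- matrix(betabinom_test(as.vector(null$k), as.vector(null$n),
                              as.vector(null$alpha_loo),
                              as.vector(null$beta_loo)),
               nsite, length(samples), dimnames = dimnames(null$k))

  df <- data.frame(
    sample = rep(samples, each = nsite),
    gene_id = rep(null$meta$gene_id, length(samples)),
    metric = rep(null$meta$metric, length(samples)),
    site_id = rep(null$meta$site_id, length(samples)),
    donor = rep(null$meta$donor, length(samples)),
    acceptor = rep(null$meta$acceptor, length(samples)),
    psi_obs = as.vector(null$psi),
    psi_expected = as.vector(null$expected),
    delta_psi = as.vector(null$psi - null$expected),
    zscore = as.vector(null$z),
    pvalue = as.vector(pv),
    stringsAsFactors = FALSE
  )
  df <- df[!is.na(df$pvalue), , drop = FALSE]
  # gene-mapping exclusion: zero genes or multi-gene sites are dropped
  df <- df[df$gene_id != "" & !is.na(df$gene_id) &
             !grepl(",", df$gene_id, fixed = TRUE), , drop = FALSE]
  finalize_outliers(df, thresholds)
}

finalize_outliers <- function(df, thresholds) {
  if (nrow(df) == 0L) return(empty_outliers())
  # deterministic order: sample, then metric / coordinates break p-ties
  df <- df[order(df$sample, df$metric, df$donor, df$acceptor, df$site_id), ,
           drop = FALSE]
  df$fdr <- stats::ave(df$pvalue, df$sample,
                       FUN = function(p) stats::p.adjust(p, "BH"))
  df$significant <- !is.na(df$fdr) & df$fdr < thresholds$fdr &
    !is.na(df$zscore) & abs(df$zscore) >= thresholds$min_z &
    !is.na(df$delta_psi) & abs(df$delta_psi) >= thresholds$min_dpsi &
    !is.na(df$psi_expected) &
    (df$psi_expected <= thresholds$psi_lo |
       df$psi_expected >= thresholds$psi_hi)
  rownames(df) <- NULL
  class(df) <- c("splice_outliers", "data.frame")
  df
}

empty_outliers <- function() {
  df <- data.frame(sample = character(), gene_id = character(),
                   metric = character(), site_id = character(),
                   donor = integer(), acceptor = integer(),
                   psi_obs = numeric(), psi_expected = numeric(),
                   delta_psi = numeric(), zscore = numeric(),
                   pvalue = numeric(), fdr = numeric(),
                   significant = logical(), stringsAsFactors = FALSE)
  class(df) <- c("splice_outliers", "data.frame")
  df
}

#' Detect aberrant splicing events across all three metrics
#'
#' Convenience wrapper: filters junctions by minimal read count, computes
#' psi5, psi3 and theta, fits the per-site null for each metric, pools the
#' three result sets and applies the within-sample BH correction across all
#' tested sites of all metrics before flagging significance.
#'
#' @param jcs A `junction_count_set`.
#' @param thresholds An [outlier_thresholds()].
#' @param min_count Junction/site read-count filter (default 15).
#' @param min_samples Minimal informative samples per site (default 3).
#' @param metrics Metrics to run (default all three).
#' @return A `splice_outliers` data frame (see [call_outliers()]).
#' @export
splice_outliers <- function(jcs, thresholds = outlier_thresholds(),
                            min_count = 15, min_samples = 3L,
                            metrics = c("psi5", "psi3", "theta")) {
  jcs <- filter_junctions(jcs, min_count)
  parts <- lapply(metrics, function(metric) {
    if (metric == "theta" && is.null(jcs$sites)) return(NULL)
    if (metric != "theta" && nrow(jcs$junctions) == 0L) return(NULL)
    null <- fit_null(compute_psi(jcs, metric), min_samples)
    out <- call_outliers(null, thresholds)
    out$fdr <- NULL
    out$significant <- NULL
    out
  })
  df <- do.call(rbind, parts)
  if (is.null(df) || nrow(df) == 0L) return(empty_outliers())
  finalize_outliers(df, thresholds)
}
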