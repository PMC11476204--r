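sep_toy <- function(n = 200, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(max_delta = ifelse(y == 1, 0.9, 0.1) + rnorm(n, 0, 0.02))
  list(X = X, y = y)
}

test_that("feature sets match the four model definitions", {
  expect_equal(feature_columns(1), "max_delta")
  expect_false("max_delta" %in% feature_columns(2))
  expect_false("median_tpm" %in% feature_columns(2))
  expect_true("median_tpm" %in% feature_columns(3))
  expect_setequal(feature_columns(4),
                  c("dist_junction", "is_snv", "in_branchpoint",
                    "in_low_complexity", "in_repeat", "median_tpm",
                    "max_delta"))
})

test_that("training sets omit incomplete rows without imputing", {
  lab <- data.frame(
    variant_id = sprintf("v%d", 1:6),
    label = c("confirmed", "confirmed", "unconfirmed", "unconfirmed",
              "indeterminate", "unconfirmed"),
    max_delta = c(0.9, 0.8, 0.3, 0.2, 0.5, 0.4),
    dist_junction = c(5, 10, 100, NA, 7, 50),
    is_snv = TRUE, in_branchpoint = FALSE, in_low_complexity = FALSE,
    in_repeat = FALSE,
    median_tpm = c(4, NA, 2, 1, 3, 5)
  )
  ts1 <- make_training_set(lab, 1)
  expect_equal(ncol(ts1$X), 1L)
  expect_equal(length(ts1$y), 5L)  # indeterminate dropped, no NA in set 1
  ts3 <- make_training_set(lab, 3)
  # v2 (NA tpm) and v4 (NA dist) dropped
  expect_setequal(ts3$variant_id, c("v1", "v3", "v6"))
  expect_equal(attr(ts3, "n_omitted"), 2L)
  lab1 <- lab; lab1$label[lab1$label == "confirmed"] <- "unconfirmed"
  expect_error(make_training_set(lab1, 1), "both classes")
})

test_that("SMOTE interpolates on segments and stays in the bounding box", {
  # two-point minority: every synthetic point is (lambda, lambda)
  Xm <- rbind(c(0, 0), c(1, 1))
  s <- smote_oversample(Xm, k = 1, n_new = 50, seed = 3)
  expect_equal(nrow(s), 50L)
  expect_true(all(abs(s[, 1] - s[, 2]) < 1e-12))
  expect_true(all(s >= 0 & s <= 1))

  expect_equal(nrow(smote_oversample(Xm, 1, 0, seed = 1)), 0L)
  expect_error(smote_oversample(Xm[1, , drop = FALSE], 1, 5), "2 minority")

  # 10-point cloud: 100 synthetic points inside the bounding box
  set.seed(5)
  cloud <- cbind(runif(10, -3, 7), runif(10, 10, 20))
  s2 <- smote_oversample(cloud, k = 3, n_new = 100, seed = 8)
  expect_true(all(s2[, 1] >= min(cloud[, 1]) & s2[, 1] <= max(cloud[, 1])))
  expect_true(all(s2[, 2] >= min(cloud[, 2]) & s2[, 2] <= max(cloud[, 2])))

  # binary columns are copied from a parent, never interpolated
  Xb <- cbind(x = c(0, 1, 2, 3), flag = c(0, 1, 0, 1))
  s3 <- smote_oversample(Xb, k = 2, n_new = 200, seed = 9)
  expect_true(all(s3[, "flag"] %in% c(0, 1)))
})

test_that("forests are deterministic, separate the separable, and shuffle to chance", {
  toy <- sep_toy()
  cfg <- model_config(feature_set = 1, imbalance = "none", n_trees = 100,
                      seed = 4)
  f1 <- train_model(toy$X, toy$y, cfg)
  f2 <- train_model(toy$X, toy$y, cfg)
  s1 <- predict(f1, toy$X)
  expect_identical(s1, predict(f2, toy$X))
  expect_equal(rank_auc(s1, toy$y), 1.0)
  expect_error(train_model(toy$X, rep(1L, 200), cfg), "both classes")

  # permuted labels: mean out-of-fold AUC near 0.5 over 10 seeds
  aucs <- vapply(1:10, function(sd) {
    set.seed(100 + sd)
    yp <- sample(toy$y)
    cv <- cross_validate(list(X = toy$X, y = yp),
                         model_config(feature_set = 1, imbalance = "none",
                                      n_trees = 100, seed = sd))
    cv$pooled$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("rank AUC equals the Mann-Whitney statistic and the pROC oracle", {
  set.seed(6)
  for (i in 1:200) {
    n1 <- sample(3:20, 1); n0 <- sample(3:20, 1)
    y <- c(rep(1, n1), rep(0, n0))
    s <- sample(seq(0, 1, by = 0.05), n1 + n0, replace = TRUE)  # with ties
    u <- unname(wilcox.test(s[y == 1], s[y == 0], exact = FALSE)$statistic)
    expect_equal(rank_auc(s, y), u / (n1 * n0), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(7)
  y <- rbinom(100, 1, 0.4); s <- runif(100)
  expect_equal(rank_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
  expect_equal(rank_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  expect_true(is.na(rank_auc(runif(5), rep(1, 5))))
})

test_that("HA odds ratio matches closed form, including zero cells", {
  expect_equal(ha_odds_ratio(9, 1, 1, 9), (9.5 * 9.5) / (1.5 * 1.5))
  expect_equal(ha_odds_ratio(9, 1, 1, 9), 40.11, tolerance = 1e-3)
  expect_equal(ha_odds_ratio(0, 0, 10, 10), (0.5 * 10.5) / (0.5 * 10.5))
  expect_true(is.finite(ha_odds_ratio(0, 0, 0, 0)) &&
                ha_odds_ratio(0, 0, 0, 0) > 0)
})

test_that("evaluate_scores assembles the confusion-table metrics", {
  m <- evaluate_scores(c(0.9, 0.8, 0.6, 0.4, 0.1), c(1, 1, 0, 1, 0),
                       model_config())
  expect_equal(unname(m$confusion), c(2L, 1L, 1L, 1L))  # TP FP FN TN
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 1 / 2)
  expect_equal(m$or_ha, (2.5 * 1.5) / (1.5 * 1.5))
  expect_equal(m$fisher_p,
               fisher.test(matrix(c(2, 1, 1, 1), 2))$p.value)
  # above-one threshold: everything negative, metrics still finite
  m2 <- evaluate_scores(c(0.9, 0.1), c(1, 0),
                        model_config(vote_threshold = 1))
  expect_true(is.finite(m2$or_ha))
})

test_that("cross-validation separates cleanly and is reproducible", {
  toy <- sep_toy(300, seed = 9)
  cfg <- model_config(feature_set = 1, imbalance = "none", n_trees = 100,
                      seed = 11)
  cv1 <- cross_validate(list(X = toy$X, y = toy$y), cfg)
  cv2 <- cross_validate(list(X = toy$X, y = toy$y), cfg)
  expect_gte(cv1$pooled$auc, 0.95)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$oof_scores, cv2$oof_scores)
  expect_error(cross_validate(list(X = toy$X, y = c(rep(1L, 3),
                                                    rep(0L, 297))),
                              cfg),
               "fewer")
})

test_that("SMOTE before splitting leaks and inflates AUC vs SMOTE inside folds", {
  set.seed(31)
  n <- 400
  y <- rbinom(n, 1, 0.12)
  X <- cbind(f1 = y * 0.3 + rnorm(n), f2 = rnorm(n))
  cfg <- model_config(feature_set = 1, imbalance = "smote", n_trees = 150,
                      seed = 17, cv_folds = 5)
  clean <- cross_validate(list(X = X, y = y), cfg)$pooled$auc

  # deliberate bug: oversample first, then cross-validate
  minority <- which(y == 1)
  synth <- smote_oversample(X[minority, ], k = 3,
                            n_new = sum(y == 0) - length(minority),
                            seed = 17)
  X_leak <- rbind(X, synth)
  y_leak <- c(y, rep(1L, nrow(synth)))
  cfg_leak <- model_config(feature_set = 1, imbalance = "none",
                           n_trees = 150, seed = 17, cv_folds = 5)
  leaky <- cross_validate(list(X = X_leak, y = y_leak), cfg_leak)$pooled$auc
  expect_lte(clean, leaky)
})

test_that("feature importance is normalized and finds the informative feature", {
  toy <- sep_toy(200, seed = 12)
  cfg1 <- model_config(feature_set = 1, imbalance = "none", n_trees = 100)
  f <- train_model(toy$X, toy$y, cfg1)
  imp <- feature_importance(f)
  expect_equal(sum(imp), 1)
  expect_equal(names(imp), "max_delta")

  wins <- 0L
  for (sd in 1:10) {
    set.seed(300 + sd)
    n <- 200
    y <- rbinom(n, 1, 0.5)
    X <- cbind(max_delta = y * 0.5 + rnorm(n, 0, 0.2),
               noise1 = rnorm(n), noise2 = rnorm(n))
    cfg <- model_config(feature_set = 1, imbalance = "none",
                        n_trees = 100, seed = sd)
    fit <- train_model(X, y, cfg)
    if (names(which.max(feature_importance(fit))) == "max_delta") {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 9L)
})

test_that("bias-variance decomposition matches closed forms and its identity", {
  X <- cbind(x = rep(c(0, 1), each = 20))
  y <- rep(c(0L, 1L), each = 20)
  # constant predictor equal to the label on a pure-class toy
  perfect <- function(X_train, y_train) function(Xn) Xn[, "x"]
  d <- bias_variance_decomposition(X, y, model_config(seed = 2),
                                   n_reps = 10, predictor = perfect)
  expect_equal(d$bias2, 0); expect_equal(d$variance, 0); expect_equal(d$mse, 0)

  # constant 0.5 on balanced labels: bias2 = 0.25, variance = 0
  half <- function(X_train, y_train) function(Xn) rep(0.5, nrow(Xn))
  d2 <- bias_variance_decomposition(X, y, model_config(seed = 2),
                                    n_reps = 10, predictor = half)
  expect_equal(d2$bias2, 0.25); expect_equal(d2$variance, 0)
  expect_equal(d2$mse, 0.25)

  # identity holds for a real forest on noisy data
  set.seed(4)
  Xr <- cbind(a = rnorm(80), b = rnorm(80))
  yr <- rbinom(80, 1, plogis(Xr[, 1]))
  if (length(unique(yr)) == 2) {
    d3 <- bias_variance_decomposition(
      Xr, yr, model_config(feature_set = 1, imbalance = "none",
                           n_trees = 60, seed = 5), n_reps = 8)
    expect_equal(d3$mse, d3$bias2 + d3$variance, tolerance = 1e-6)
  }
})

test_that("randomForest agrees with ranger as an independent engine check", {
  skip_if_not_installed("randomForest")
  toy <- sep_toy(200, seed = 21)
  rf <- randomForest::randomForest(toy$X, factor(toy$y), ntree = 100)
  s_rf <- predict(rf, toy$X, type = "prob")[, "1"]
  cfg <- model_config(feature_set = 1, imbalance = "none", n_trees = 100,
                      seed = 3)
  s_rg <- predict(train_model(toy$X, toy$y, cfg), toy$X)
  expect_equal(rank_auc(s_rf, toy$y), rank_auc(s_rg, toy$y),
               tolerance = 0.02)
})
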