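#' Configuration for the splice-disruption classifiers
#'
#' Four nested feature sets mirror the model-comparison design:
#' 1. maximum SpliceAI delta score only;
#' 2. DNA variant features without delta scores (distance to the nearest
#'    annotated junction, SNV/indel, branchpoint / low-complexity / repeat
#'    flags);
#' 3. the DNA features plus median myocardial gene expression (TPM);
#' 4. everything (DNA features, expression, max delta).
#'
#' @param feature_set Integer 1-4.
#' @param imbalance `"weighted"` (class weights inversely proportional to
#'   class counts), `"smote"` (minority oversampled to parity inside the
#'   training data), or `"none"`.
#' @param n_trees Trees per forest (default 500).
#' @param smote_k SMOTE neighbor count (default 5).
#' @param vote_threshold Score threshold for the positive call (default 0.5).
#' @param seed Integer seed; forests and fold assignment are deterministic
#'   given it.
#' @param cv_folds Number of stratified cross-validation folds (default 5).
#' @return A validated list of class `model_config`.
#' @export
model_config <- function(feature_set = 4L,
                         imbalance = c("weighted", "smote", "none"),
                         n_trees = 500L, smote_k = 5L,
                         vote_threshold = 0.5, seed = 1L, cv_folds = 5L) {
  imbalance <- match.arg(imbalance)
  if (!feature_set %in% 1:4) stop("model_config: feature_set must be 1-4")
  if (cv_folds < 2L) stop("model_config: cv_folds must be >= 2")
  if (vote_threshold < 0 || vote_threshold > 1) {
    stop("model_config: vote_threshold must lie in [0, 1]")
  }
  structure(list(feature_set = as.integer(feature_set), imbalance = imbalance,
                 n_trees = as.integer(n_trees), smote_k = as.integer(smote_k),
                 vote_threshold = vote_threshold, seed = as.integer(seed),
                 cv_folds = as.integer(cv_folds)),
            class = "model_config")
}

#' Feature columns used by each model
#' @param feature_set Integer 1-4.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(feature_set) {
  dna <- c("dist_junction", "is_snv", "in_branchpoint",
           "in_low_complexity", "in_repeat")
  switch(as.character(feature_set),
         "1" = "max_delta",
         "2" = dna,
         "3" = c(dna, "median_tpm"),
         "4" = c(dna, "median_tpm", "max_delta"),
         stop("feature_set must be 1-4"))
}

#' Build the design matrix and labels from labeled variants
#'
#' Keeps confirmed and unconfirmed variants only (indeterminate excluded),
#' selects the feature set's columns, and omits rows with any missing value
#' (missing values are never imputed); the omitted count is stored in the
#' `"n_omitted"` attribute.
#'
#' @param labeled Output of [label_variants()] with feature columns.
#' @param feature_set Integer 1-4.
#' @return List with numeric-matrix `X`, integer `y` (1 = confirmed) and
#'   `variant_id`.
#' @export
make_training_set <- function(labeled, feature_set) {
  df <- labeled[labeled$label %in% c("confirmed", "unconfirmed"), ,
                drop = FALSE]
  cols <- feature_columns(feature_set)
  X <- as.matrix(as.data.frame(lapply(df[, cols, drop = FALSE], as.numeric)))
  colnames(X) <- cols
  complete <- stats::complete.cases(X)
  y <- as.integer(df$label == "confirmed")[complete]
  if (length(unique(y)) < 2L) {
    stop("make_training_set: need both classes present", call. = FALSE)
  }
  out <- list(X = X[complete, , drop = FALSE], y = y,
              variant_id = df$variant_id[complete])
  attr(out, "n_omitted") <- sum(!complete)
  out
}

#' SMOTE: synthetic minority oversampling
#'
#' Each synthetic row interpolates between a uniformly chosen minority point
#' `x` and one of its `k` nearest minority neighbors `x_nn` (Euclidean
#' distance on standardized continuous features): continuous features become
#' `x + lambda * (x_nn - x)` with `lambda ~ Uniform(0, 1)`; binary features
#' are copied from the nearer parent (`x` when `lambda < 0.5`, else
#' `x_nn`).
#'
#' @param X_minority Numeric matrix of minority-class rows (>= 2 rows).
#' @param k Neighbor count (`k <= nrow - 1`; reduced with a warning
#'   otherwise).
#' @param n_new Number of synthetic rows.
#' @param seed Optional integer seed.
#' @param binary_cols Columns treated as binary; default: columns whose
#'   values are all in {0, 1}.
#' @return Matrix with `n_new` synthetic rows.
#' @export
smote_oversample <- function(X_minority, k = 5L, n_new, seed = NULL,
                             binary_cols = NULL) {
  X <- as.matrix(X_minority)
  if (nrow(X) < 2L) {
    stop("smote_oversample: need at least 2 minority rows", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (n_new == 0L) return(X[0, , drop = FALSE])
  if (k > nrow(X) - 1L) {
    warning("smote_oversample: k reduced to ", nrow(X) - 1L)
    k <- nrow(X) - 1L
  }
  if (is.null(binary_cols)) {
    binary_cols <- which(apply(X, 2L, function(v) all(v %in% c(0, 1))))
  }
  cont <- setdiff(seq_len(ncol(X)), binary_cols)
  Xs <- X
  if (length(cont)) {
    Xs[, cont] <- apply(X[, cont, drop = FALSE], 2L, function(v) {
      s <- stats::sd(v)
      if (s > 0) (v - mean(v)) / s else v * 0
    })
  }
  d <- as.matrix(stats::dist(Xs))
  diag(d) <- Inf
  nn_raw <- apply(d, 1L, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1L) matrix(nn_raw, ncol = 1L) else t(nn_raw)

  base <- sample.int(nrow(X), n_new, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
  lambda <- stats::runif(n_new)
  new <- X[base, , drop = FALSE] +
    lambda * (X[pick, , drop = FALSE] - X[base, , drop = FALSE])
  if (length(binary_cols)) {
    parent <- ifelse(lambda < 0.5, base, pick)
    new[, binary_cols] <- X[parent, binary_cols, drop = FALSE]
  }
  rownames(new) <- NULL
  new
}

#' Train a splice-disruption random forest
#'
#' A bagged decision-tree ensemble with per-node feature subsampling
#' (ranger). `imbalance = "weighted"` applies class weights inversely
#' proportional to class counts; `imbalance = "smote"` oversamples the
#' minority class to parity before fitting. The returned score is the mean
#' tree probability of the positive class. Deterministic given
#' `config$seed`.
#'
#' @param X Numeric feature matrix.
#' @param y Integer labels (1 = positive/confirmed).
#' @param config A [model_config()].
#' @return A list of class `splice_rf` with the fitted forest and metadata.
#' @importFrom ranger ranger importance
#' @export
train_model <- function(X, y, config = model_config()) {
  if (length(unique(y)) < 2L) {
    stop("train_model: y must contain both classes", call. = FALSE)
  }
  if (config$imbalance == "smote") {
    minority <- as.integer(names(which.min(table(y))))
    n_new <- sum(y != minority) - sum(y == minority)
    if (sum(y == minority) < 2L) {
      stop("train_model: singleton minority class, SMOTE impossible",
           call. = FALSE)
    }
    if (n_new > 0L) {
      synth <- smote_oversample(X[y == minority, , drop = FALSE],
                                k = min(config$smote_k, sum(y == minority) - 1L),
                                n_new = n_new, seed = config$seed)
      X <- rbind(X, synth)
      y <- c(y, rep(minority, n_new))
    }
  }
  dat <- data.frame(X, check.names = FALSE)
  dat$.y <- factor(y, levels = c(0L, 1L))
  case_weights <- if (config$imbalance == "weighted") {
    # observations weighted inversely to their class count, applied to the
    # per-tree bootstrap so each tree sees a class-balanced sample
    w <- 1 / table(dat$.y)
    as.numeric(w[as.character(y)])
  } else NULL
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = config$n_trees, probability = TRUE,
    importance = "impurity", case.weights = case_weights,
    seed = config$seed, num.threads = 1L
  )
  structure(list(fit = fit, features = colnames(X), config = config),
            class = "splice_rf")
}

#' Score new rows with a fitted splice-disruption forest
#' @param object A `splice_rf`.
#' @param newdata Matrix or data frame containing the model's features.
#' @param ... Unused.
#' @return Numeric vector of positive-class scores in \[0, 1\].
#' @export
predict.splice_rf <- function(object, newdata, ...) {
  nd <- data.frame(as.data.frame(newdata)[, object$features, drop = FALSE],
                   check.names = FALSE)
  stats::predict(object$fit, data = nd, num.threads = 1L)$predictions[, "1"]
}

#' Normalized impurity-decrease feature importances
#' @param model A `splice_rf`.
#' @return Named non-negative vector summing to 1.
#' @export
feature_importance <- function(model) {
  imp <- ranger::importance(model$fit)
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) return(imp)
  imp / sum(imp)
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' `AUC = (sum of positive ranks - n1 (n1 + 1) / 2) / (n1 n0)` with ties
#' averaged. NA when only one class is present.
#'
#' @param scores Numeric scores.
#' @param y Labels (1 = positive).
#' @return AUC in \[0, 1\], or NA.
#' @export
rank_auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Haldane-Anscombe corrected odds ratio of a 2x2 table
#'
#' `((a + 0.5)(d + 0.5)) / ((b + 0.5)(c + 0.5))` — finite and positive for
#' every table, including tables with zero cells.
#'
#' @param a,b,c,d Cell counts: for a confusion table use
#'   `ha_odds_ratio(TP, FP, FN, TN)`.
#' @return The corrected odds ratio.
#' @export
ha_odds_ratio <- function(a, b, c, d) {
  ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
}

#' Evaluate scores against labels
#'
#' AUC by rank statistic; confusion counts at `vote_threshold` (score >=
#' threshold calls positive); sensitivity and specificity; Haldane-Anscombe
#' corrected odds ratio of the confusion table; and a two-sided Fisher's
#' exact p-value on the uncorrected confusion table.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param y Labels (1 = positive).
#' @param config A [model_config()] (for the threshold).
#' @return A list of class `eval_metrics`.
#' @export
evaluate_scores <- function(scores, y, config = model_config()) {
  stopifnot(length(scores) == length(y))
  y <- as.integer(y)
  pred <- as.integer(scores >= config$vote_threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  fisher_p <- stats::fisher.test(matrix(c(tp, fn, fp, tn), 2L))$p.value
  structure(list(
    auc = rank_auc(scores, y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
    or_ha = ha_odds_ratio(tp, fp, fn, tn),
    fisher_p = fisher_p
  ), class = "eval_metrics")
}

#' Stratified cross-validation of a splice-disruption model
#'
#' Folds are stratified by class with a fixed seed. SMOTE oversampling and
#' class weighting are applied strictly inside the training folds, never to
#' held-out data. Pooled metrics come from the concatenated out-of-fold
#' scores; a final model is refit on all data.
#'
#' @param labeled Output of [label_variants()] with feature columns, or a
#'   list `(X, y)` from [make_training_set()].
#' @param config A [model_config()].
#' @return List with `pooled` (`eval_metrics`), `per_fold`, `oof_scores`,
#'   `y`, `fold`, `final_model`.
#' @export
cross_validate <- function(labeled, config = model_config()) {
  ts <- if (is.list(labeled) && !is.data.frame(labeled) &&
            all(c("X", "y") %in% names(labeled))) labeled
        else make_training_set(labeled, config$feature_set)
  X <- ts$X
  y <- ts$y
  k <- config$cv_folds
  if (min(table(y)) < k) {
    stop("cross_validate: fewer members of a class than folds", call. = FALSE)
  }
  set.seed(config$seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  oof <- numeric(length(y))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    fit <- train_model(X[tr, , drop = FALSE], y[tr], cfg_f)
    oof[!tr] <- predict(fit, X[!tr, , drop = FALSE])
    per_fold[[f]] <- evaluate_scores(oof[!tr], y[!tr], config)
  }
  list(pooled = evaluate_scores(oof, y, config),
       per_fold = per_fold, oof_scores = oof, y = y, fold = fold,
       final_model = train_model(X, y, config))
}

#' Bias-variance decomposition of a model's squared error
#'
#' Refits the model on `n_reps` bootstrap resamples; each point is scored in
#' the replicates where it was held out (out-of-bag). Per point with scores
#' `s_1..s_m` and label `y`: `mse = mean((s - y)^2)`,
#' `bias2 = (mean(s) - y)^2`, `variance = mean((s - mean(s))^2)`, so
#' `mse = bias2 + variance` exactly. Aggregates are means over points with
#' at least one out-of-bag score.
#'
#' @param X,y Design matrix and labels.
#' @param config A [model_config()].
#' @param n_reps Number of bootstrap refits (default 20, >= 2).
#' @param predictor Optional function `(X_train, y_train) -> function(X)`;
#'   defaults to [train_model()]. Lets closed-form predictors be decomposed.
#' @return List with `bias2`, `variance`, `mse` and `n_points`.
#' @export
bias_variance_decomposition <- function(X, y, config = model_config(),
                                        n_reps = 20L, predictor = NULL) {
  stopifnot(n_reps >= 2L)
  n <- length(y)
  set.seed(config$seed)
  scores <- matrix(NA_real_, n, n_reps)
  for (r in seq_len(n_reps)) {
    boot <- sample.int(n, n, replace = TRUE)
    held <- setdiff(seq_len(n), boot)
    if (length(held) == 0L || length(unique(y[boot])) < 2L) next
    if (is.null(predictor)) {
      cfg_r <- config
      cfg_r$seed <- config$seed + r
      fit <- train_model(X[boot, , drop = FALSE], y[boot], cfg_r)
      scores[held, r] <- predict(fit, X[held, , drop = FALSE])
    } else {
      f <- predictor(X[boot, , drop = FALSE], y[boot])
      scores[held, r] <- f(X[held, , drop = FALSE])
    }
  }
  m <- rowSums(!is.na(scores))
  use <- which(m > 0)
  mean_s <- rowMeans(scores, na.rm = TRUE)
  bias2 <- (mean_s[use] - y[use])^2
  variance <- vapply(use, function(i) {
    s <- scores[i, !is.na(scores[i, ])]
    mean((s - mean(s))^2)
  }, numeric(1))
  mse <- vapply(use, function(i) {
    s <- scores[i, !is.na(scores[i, ])]
    mean((s - y[i])^2)
  }, numeric(1))
  list(bias2 = mean(bias2), variance = mean(variance), mse = mean(mse),
       n_points = length(use))
}
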