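#' Classifier configuration
#'
#' Hyperparameters for the extremely-randomized-trees ensemble used in the
#' diagnostic models.  Defaults favour reproducibility over tuning: 500
#' trees, default split rules, a fixed seed.  The configuration is recorded
#' in run metadata.
#'
#' @param num_trees Ensemble size.
#' @param seed Base random seed; fold i of a leave-one-out loop uses
#'   `seed + i`, making score vectors bit-identical across runs.
#' @param mtry Features sampled per split; `NULL` = ranger default
#'   (floor(sqrt(p))).
#' @param threshold Probability threshold for F1.
#' @return A `vlt_classifier_config` list.
#' @export
classifier_config <- function(num_trees = 500, seed = 1234, mtry = NULL,
                              threshold = 0.5) {
  structure(list(num_trees = num_trees, seed = seed, mtry = mtry,
                 threshold = threshold),
            class = "vlt_classifier_config")
}

# Extra-trees probability forest: random splits on unbagged data.
fit_extra_trees <- function(x, y, config, fold_seed) {
  ranger::ranger(x = x, y = y, probability = TRUE,
                 num.trees = config$num_trees,
                 mtry = if (is.null(config$mtry)) NULL else config$mtry,
                 splitrule = "extratrees", num.random.splits = 1,
                 replace = FALSE, sample.fraction = 1,
                 seed = fold_seed, num.threads = 1,
                 respect.unordered.factors = TRUE)
}

# Median imputation fitted on the training fold only.  Columns that are
# all-missing in a fold carry no information and are set to 0.
impute_median <- function(train, test) {
  med <- vapply(train, function(col) {
    m <- stats::median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, numeric(1))
  fill <- function(df) {
    for (j in seq_along(df)) {
      miss <- is.na(df[[j]])
      if (any(miss)) df[[j]][miss] <- med[j]
    }
    df
  }
  list(train = fill(train), test = fill(test))
}

#' Leave-one-out cross-validated classifier scores
#'
#' For each sample i, an extra-trees ensemble is trained on all other
#' samples (median imputation fitted within the training fold) and the
#' predicted probability of the positive class for sample i is recorded.
#' Deterministic given the seed in `config`.
#'
#' @param x Data frame of numeric predictors.
#' @param y Two-level factor of class labels.
#' @param positive Level treated as the positive (impaired) class; default
#'   the second level.
#' @param config A [classifier_config()].
#' @return Numeric vector of per-sample positive-class probabilities.
#' @export
loocv_scores <- function(x, y, positive = NULL, config = classifier_config()) {
  x <- as.data.frame(x)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("labels must have exactly two levels")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  if (is.null(positive)) positive <- levels(y)[2]
  n <- nrow(x)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      stop("training fold ", i, " is single-class; cannot fit")
    }
    imp <- impute_median(x[-i, , drop = FALSE], x[i, , drop = FALSE])
    fit <- fit_extra_trees(imp$train, ytr, config, config$seed + i)
    pr <- stats::predict(fit, data = imp$test)$predictions
    scores[i] <- pr[1, positive]
  }
  scores
}

delong_placements <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  m <- length(pos)
  n <- length(neg)
  if (m < 1L || n < 1L) stop("both classes must be present")
  # midrank identity: psi(x, y) = 1[x>y] + 0.5*1[x==y]
  all_r <- rank(c(pos, neg))
  rp <- rank(pos)
  rn <- rank(neg)
  v10 <- (all_r[seq_len(m)] - rp) / n          # per-positive placements
  v01 <- 1 - (all_r[m + seq_len(n)] - rn) / m  # per-negative placements
  auc <- mean(v10)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with DeLong variance and confidence interval
#'
#' The AUC is the midrank (Mann-Whitney) estimator; its variance is the
#' DeLong structural-components estimator S10/m + S01/n, and the confidence
#' interval is normal-theory on that variance, clipped to [0, 1].
#'
#' @param scores Numeric classifier scores.
#' @param labels Two-level factor.
#' @param positive Positive-class level; default the second level.
#' @param conf_level Confidence level.
#' @return A `vlt_roc` list: `auc`, `var_auc`, `ci_low`, `ci_high`, `m`
#'   (positives), `n` (negatives).
#' @export
roc_auc_delong <- function(scores, labels, positive = NULL,
                           conf_level = 0.95) {
  labels <- factor(labels)
  if (is.null(positive)) positive <- levels(labels)[2]
  if (length(unique(scores)) == 1L) {
    warning("constant scores: AUC 0.5 with zero variance")
    m <- sum(labels == positive)
    n <- sum(labels != positive)
    return(structure(list(auc = 0.5, var_auc = 0, ci_low = 0.5,
                          ci_high = 0.5, m = m, n = n),
                     class = "vlt_roc"))
  }
  pl <- delong_placements(scores, labels, positive)
  s10 <- if (pl$m > 1) stats::var(pl$v10) else 0
  s01 <- if (pl$n > 1) stats::var(pl$v01) else 0
  v <- s10 / pl$m + s01 / pl$n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc = pl$auc, var_auc = v,
                 ci_low = max(0, pl$auc - z * sqrt(v)),
                 ci_high = min(1, pl$auc + z * sqrt(v)),
                 m = pl$m, n = pl$n),
            class = "vlt_roc")
}

#' @export
print.vlt_roc <- function(x, digits = 3, ...) {
  cat(sprintf("AUC = %.*f  [%.*f, %.*f]  (DeLong; %d pos / %d neg)\n",
              digits, x$auc, digits, x$ci_low, digits, x$ci_high, x$m, x$n))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Two-sided test of equal AUC for two score vectors evaluated on the same
#' samples, using the paired DeLong covariance of the structural
#' components.  Identical score vectors give p = 1.
#'
#' @param scores1,scores2 Score vectors on the same samples.
#' @param labels Two-level factor.
#' @param positive Positive-class level; default the second level.
#' @return List: `auc1`, `auc2`, `auc_diff`, `var_diff`, `z`, `p`.
#' @export
delong_paired_test <- function(scores1, scores2, labels, positive = NULL) {
  stopifnot(length(scores1) == length(scores2),
            length(scores1) == length(labels))
  labels <- factor(labels)
  if (is.null(positive)) positive <- levels(labels)[2]
  p1 <- delong_placements(scores1, labels, positive)
  p2 <- delong_placements(scores2, labels, positive)
  d <- p1$auc - p2$auc
  s10 <- stats::var(cbind(p1$v10, p2$v10))
  s01 <- stats::var(cbind(p1$v01, p2$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / p1$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / p1$n
  if (v <= .Machine$double.eps) {
    z <- 0
    p <- 1
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc1 = p1$auc, auc2 = p2$auc, auc_diff = d, var_diff = v, z = z,
       p = p)
}

#' F1 score of the positive class at a fixed threshold
#'
#' @param scores Predicted positive-class probabilities.
#' @param labels Two-level factor.
#' @param positive Positive-class level; default the second level.
#' @param threshold Scores > threshold are predicted positive.
#' @return F1 (0 with a warning when nothing is predicted positive).
#' @export
f1_at_threshold <- function(scores, labels, positive = NULL,
                            threshold = 0.5) {
  labels <- factor(labels)
  if (is.null(positive)) positive <- levels(labels)[2]
  pred <- scores > threshold
  actual <- labels == positive
  tp <- sum(pred & actual)
  fp <- sum(pred & !actual)
  fn <- sum(!pred & actual)
  if (tp + fp == 0L) {
    warning("no samples predicted positive; F1 = 0")
    return(0)
  }
  2 * tp / (2 * tp + fp + fn)
}

MODEL_SUBTESTS <- c("immediate", "delayed", "recognition", "full")

subtest_core_features <- function(subtest) {
  switch(subtest,
         immediate = "total_immediate_recall",
         delayed = "delayed_recall",
         recognition = "recognition_true_positives",
         full = c("total_immediate_recall", "delayed_recall",
                  "recognition_true_positives"),
         stop("unknown subtest '", subtest, "'"))
}

#' Predictor set for one diagnostic model
#'
#' The model family per subtest: tier 1 uses the subtest's core clinical
#' score(s) only; tier 2 adds age; tier 3 adds the full verbal-memory
#' feature catalog.  Tier predictor sets are nested.
#'
#' @param subtest One of `"immediate"`, `"delayed"`, `"recognition"`,
#'   `"full"`.
#' @param tier 1, 2 or 3.
#' @param all_features Character vector of available feature names (used by
#'   tier 3); default the built-in catalog.
#' @return Character vector of predictor column names.
#' @export
model_predictors <- function(subtest, tier,
                             all_features = vlt_feature_names()) {
  subtest <- match.arg(subtest, MODEL_SUBTESTS)
  stopifnot(tier %in% 1:3)
  core <- subtest_core_features(subtest)
  if (tier == 1) return(core)
  if (tier == 2) return(union(core, "age"))
  union(union(core, "age"), all_features)
}

#' Run the full diagnostic model family
#'
#' Fits and scores the 4 subtests x 3 tiers model family with leave-one-out
#' cross-validation, reporting AUC with DeLong confidence intervals, F1 at
#' the configured threshold, and paired DeLong p-values between consecutive
#' tiers within each subtest.  Optionally reruns the family on a subset
#' (e.g. after excluding participants with dementia).
#'
#' @param feature_table Data frame containing an `age` column and the
#'   feature catalog columns.
#' @param labels Two-level factor (positive = impaired class, second level).
#' @param config A [classifier_config()].
#' @param sensitivity_exclude Optional logical vector marking rows to drop
#'   in a sensitivity rerun (`NULL` = no rerun).
#' @return A `vlt_model_family` list: `results` (one row per model),
#'   `scores` (named list of LOOCV score vectors), `pairwise` (tier
#'   comparisons), and optionally `sensitivity` (same structure on the
#'   subset).
#' @export
run_model_family <- function(feature_table, labels,
                             config = classifier_config(),
                             sensitivity_exclude = NULL) {
  labels <- factor(labels)
  feats <- intersect(vlt_feature_names(), names(feature_table))
  run_once <- function(tbl, labs) {
    results <- list()
    scores <- list()
    pairwise <- list()
    for (subtest in MODEL_SUBTESTS) {
      tier_scores <- list()
      for (tier in 1:3) {
        preds <- model_predictors(subtest, tier, all_features = feats)
        preds <- intersect(preds, names(tbl))
        sc <- loocv_scores(tbl[preds], labs, config = config)
        roc <- roc_auc_delong(sc, labs)
        f1 <- f1_at_threshold(sc, labs, threshold = config$threshold)
        key <- paste0(subtest, "_model", tier)
        tier_scores[[tier]] <- sc
        scores[[key]] <- sc
        results[[key]] <- data.frame(
          subtest = subtest, tier = tier, n_predictors = length(preds),
          auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
          f1 = f1, n_pos = roc$m, n_neg = roc$n, stringsAsFactors = FALSE)
      }
      for (cmp in list(c(1, 2), c(1, 3), c(2, 3))) {
        dt <- delong_paired_test(tier_scores[[cmp[1]]], tier_scores[[cmp[2]]],
                                 labs)
        pairwise[[paste0(subtest, "_m", cmp[1], "_vs_m", cmp[2])]] <-
          data.frame(subtest = subtest, tier_a = cmp[1], tier_b = cmp[2],
                     auc_a = dt$auc1, auc_b = dt$auc2, p = dt$p,
                     stringsAsFactors = FALSE)
      }
    }
    list(results = do.call(rbind, results),
         scores = scores,
         pairwise = do.call(rbind, pairwise))
  }
  out <- run_once(feature_table, labels)
  if (!is.null(sensitivity_exclude)) {
    keep <- !sensitivity_exclude
    out$sensitivity <- run_once(feature_table[keep, , drop = FALSE],
                                droplevels(labels[keep]))
  }
  out$config <- config
  class(out) <- "vlt_model_family"
  out
}

#' @export
print.vlt_model_family <- function(x, digits = 3, ...) {
  cat("Diagnostic model family (extra trees, LOOCV)\n")
  y <- x$results
  y$auc <- round(y$auc, digits); y$ci_low <- round(y$ci_low, digits)
  y$ci_high <- round(y$ci_high, digits); y$f1 <- round(y$f1, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' ROC curve points from scores
#'
#' @param scores Numeric scores.
#' @param labels Two-level factor.
#' @param positive Positive-class level; default second level.
#' @return Data frame of (fpr, tpr) stepping through all thresholds.
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (is.null(positive)) positive <- levels(labels)[2]
  o <- order(scores, decreasing = TRUE)
  pos <- labels[o] == positive
  tpr <- c(0, cumsum(pos) / sum(pos))
  fpr <- c(0, cumsum(!pos) / sum(!pos))
  data.frame(fpr = fpr, tpr = tpr)
}
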