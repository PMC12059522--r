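CONTRASTS <- list(T_vs_H = c(case = "T", control = "H"),
                  PT_vs_H = c(case = "PT", control = "H"))

#' Build a subject-level feature table for one contrast and variant
#'
#' Widens the long feature tibble into one row per subject: cancer subjects
#' contribute their case-ROI features (outcome 1), healthy subjects their
#' H-ROI features (outcome 0). Rows with any missing feature (e.g. an
#' unusable cluster) are excluded and counted.
#'
#' @param features Long feature tibble from [compute_features()] rows bound
#'   over a cohort (`subject`, `roi`, `variant`, `feature`, `value`).
#' @param contrast "T_vs_H" or "PT_vs_H".
#' @param variant Model variant name (see [compute_features()]).
#' @return Tibble: `subject`, `outcome` (0/1), one column per feature;
#'   attributes `n_excluded`, `contrast`, `variant`.
#' @export
build_feature_table <- function(features, contrast = c("T_vs_H", "PT_vs_H"),
                                variant = "two_cluster") {
  contrast <- match.arg(contrast)
  variant <- match.arg(variant, names(FEATURE_SETS))
  rois <- CONTRASTS[[contrast]]
  sub <- dplyr::filter(features, .data$variant == !!variant,
                       .data$roi %in% rois)
  if (nrow(sub) == 0) abort("no matching feature rows", class = "dkclust_validation_error")
  wide <- tidyr::pivot_wider(sub[, c("subject", "roi", "feature", "value")],
                             names_from = "feature", values_from = "value")
  wide$outcome <- as.integer(wide$roi == rois[["case"]])
  if (length(unique(wide$outcome)) < 2) {
    abort("feature table must contain both classes", class = "dkclust_validation_error")
  }
  feat_cols <- FEATURE_SETS[[variant]]
  complete <- stats::complete.cases(wide[, feat_cols])
  out <- wide[complete, c("subject", "outcome", feat_cols)]
  if (length(unique(out$outcome)) < 2) {
    abort("after exclusions only one class remains", class = "dkclust_validation_error")
  }
  attr(out, "n_excluded") <- sum(!complete)
  attr(out, "contrast") <- contrast
  attr(out, "variant") <- variant
  out
}

#' Fold-wise univariate feature selection
#'
#' Scores each feature by a two-sided Mann-Whitney test between classes and
#' keeps those with `p <= alpha / n` (Bonferroni over the variant's n
#' features). Kept features are sorted by ascending p, then greedily pruned:
#' a feature correlating (|Pearson rho| >= `rho_max`) with an already-kept
#' feature is dropped. If nothing survives the threshold, the single
#' lowest-p feature is kept with a warning (the selection must emit at
#' least one predictor).
#'
#' @param train Feature table rows (from [build_feature_table()]) of the
#'   training split.
#' @param alpha Base significance level before Bonferroni (default 0.05).
#' @param rho_max Correlation cap (default 0.8).
#' @return Character vector of kept feature names, ascending p.
#' @export
select_features <- function(train, alpha = 0.05, rho_max = 0.8) {
  feats <- setdiff(names(train), c("subject", "outcome"))
  if (min(table(train$outcome)) < 2) {
    abort("need >= 2 observations per class", class = "dkclust_validation_error")
  }
  pos <- train$outcome == 1
  p <- vapply(feats, function(f)
    mann_whitney(train[[f]][pos], train[[f]][!pos])$p_value, numeric(1))
  p[!is.finite(p)] <- 1  # constant features have no rank separation
  thr <- alpha / length(feats)
  kept <- feats[p <= thr]
  if (length(kept) == 0) {
    warn("no feature passed Bonferroni selection; falling back to the lowest-p feature")
    kept <- feats[which.min(p)]
  }
  kept <- kept[order(p[kept])]
  final <- kept[1]
  for (f in kept[-1]) {
    rho <- vapply(final, function(g) {
      r <- suppressWarnings(stats::cor(train[[f]], train[[g]]))
      if (is.na(r)) 0 else r
    }, numeric(1))
    if (all(abs(rho) < rho_max)) final <- c(final, f)
  }
  final
}

#' Area under the ROC curve
#'
#' Probability that a random positive scores above a random negative, ties
#' counted one half — computed from midranks, which is exactly the
#' Mann-Whitney U statistic divided by `n1 * n0`.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("both classes must be present", class = "dkclust_validation_error")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile interval for the AUC
#'
#' Resamples (score, label) pairs with replacement, recomputes the AUC per
#' replicate, and returns the 5th and 95th percentiles. Replicates that draw
#' a single class are redrawn.
#'
#' @param scores,labels As in [roc_auc()].
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return Named numeric: `lower` (5%), `upper` (95%).
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 1000, seed = 1L) {
  labels <- as.integer(as.logical(labels))
  n <- length(scores)
  withr::with_seed(seed, {
    aucs <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
      }
      aucs[i] <- roc_auc(scores[idx], labels[idx])
    }
  })
  q <- quantile(aucs, c(0.05, 0.95), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Classification metrics at the Youden-index threshold
#'
#' Scans the midpoints between adjacent distinct scores (plus the minimum
#' score, giving the all-positive assignment), picks the threshold
#' maximizing Youden's J = sensitivity + specificity - 1 (ties resolved
#' toward the lower threshold, i.e. higher sensitivity), and reports the
#' confusion-matrix metrics of the rule `score >= threshold`. When all
#' scores are equal the all-positive assignment at that degenerate threshold
#' is returned (J = 0).
#'
#' @param scores,labels As in [roc_auc()].
#' @return One-row tibble: `threshold`, `youden_j`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
youden_metrics <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("both classes must be present", class = "dkclust_validation_error")
  }
  s <- sort(unique(scores))
  cand <- if (length(s) > 1) c(min(s), (head(s, -1) + s[-1]) / 2) else min(s)
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sum(pred & labels == 1) / n1 + sum(!pred & labels == 0) / n0 - 1
  }, numeric(1))
  thr <- cand[which(j == max(j))][1]  # lowest threshold among ties
  pred <- scores >= thr
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(threshold = thr, youden_j = max(j),
                 accuracy = (tp + tn) / (n1 + n0),
                 precision = precision, recall = recall, f1 = f1)
}

# Stratified fold assignment, seeded; one observation per subject so folds
# never split a subject.
assign_folds <- function(outcome, folds, seed) {
  fold <- integer(length(outcome))
  withr::with_seed(seed, {
    for (cls in unique(outcome)) {
      idx <- sample(which(outcome == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  if (any(table(fold, outcome) == 0)) {
    abort("a fold lost one class; reduce folds or enlarge the cohort",
          class = "dkclust_stratification_error")
  }
  fold
}

#' Cross-validated Lasso-logistic classification
#'
#' Five-fold (by default) stratified cross-validation. Within each training
#' split: univariate Mann-Whitney selection with Bonferroni correction and
#' correlation pruning, z-score standardization fitted on the training data
#' only, then L1-penalized logistic regression. Held-out scores give
#' per-fold AUC and Youden-threshold metrics; pooled out-of-fold scores give
#' the a-posteriori bootstrap AUC interval. Per-fold coefficient magnitudes
#' are normalized to sum to 1, exposing each feature's relative weight.
#'
#' @param table Feature table from [build_feature_table()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed (folds and bootstrap).
#' @param lasso_strength Inverse regularization strength C (> 0, default 1);
#'   the penalty passed to the fit is `1 / (n_train * C)`.
#' @param alpha,rho_max Selection settings, see [select_features()].
#' @param n_boot Bootstrap replicates for the pooled AUC interval.
#' @return Object of class `dki_classification` with elements `per_fold`
#'   (tibble), `coefficients` (tibble fold/feature/weight), `pooled` (list:
#'   median + 5-95% fold percentiles per metric), `pooled_auc`, `auc_ci`,
#'   `scores` (pooled out-of-fold predictions), `settings`.
#' @export
crossval_classify <- function(table, folds = 5, seed = 1L, lasso_strength = 1,
                              alpha = 0.05, rho_max = 0.8, n_boot = 1000) {
  if (lasso_strength <= 0) abort("lasso_strength must be > 0",
                                 class = "dkclust_validation_error")
  feats <- setdiff(names(table), c("subject", "outcome"))
  fold <- assign_folds(table$outcome, folds, seed)
  oof <- rep(NA_real_, nrow(table))
  per_fold <- list()
  coefs <- list()
  for (f in seq_len(folds)) {
    tr <- table[fold != f, , drop = FALSE]
    te <- table[fold == f, , drop = FALSE]
    sel <- select_features(tr, alpha = alpha, rho_max = rho_max)
    mu <- vapply(sel, function(v) mean(tr[[v]]), numeric(1))
    sg <- vapply(sel, function(v) sd(tr[[v]]), numeric(1))
    sg[!is.finite(sg) | sg == 0] <- 1
    zs <- function(df) scale(as.matrix(df[, sel, drop = FALSE]),
                             center = mu, scale = sg)
    xtr <- zs(tr); xte <- zs(te)
    # glmnet needs >= 2 columns; pad a zero column for 1-feature models
    pad <- ncol(xtr) < 2
    if (pad) { xtr <- cbind(xtr, 0); xte <- cbind(xte, 0) }
    lam <- 1 / (nrow(tr) * lasso_strength)
    # small-cohort folds always trip glmnet's <8-per-class advisory
    fitg <- suppressWarnings(
      glmnet::glmnet(xtr, tr$outcome, family = "binomial", alpha = 1,
                     lambda = lam, standardize = FALSE))
    sc <- as.numeric(predict(fitg, newx = xte, type = "response"))
    oof[fold == f] <- sc
    w <- abs(as.numeric(stats::coef(fitg))[-1])
    if (pad) w <- w[seq_along(sel)]
    wn <- if (sum(w) > 0) w / sum(w) else w
    coefs[[f]] <- tibble::tibble(fold = f, feature = sel, weight = wn)
    ym <- youden_metrics(sc, te$outcome)
    per_fold[[f]] <- tibble::tibble(
      fold = f, n_test = nrow(te), auc = roc_auc(sc, te$outcome),
      selected = paste(sel, collapse = ","), ym
    )
  }
  per_fold <- dplyr::bind_rows(per_fold)
  metric_cols <- c("auc", "accuracy", "precision", "recall", "f1")
  pooled <- purrr::map(setNames(metric_cols, metric_cols), function(m)
    c(median = median(per_fold[[m]]),
      quantile(per_fold[[m]], c(0.05, 0.95), names = FALSE) |>
        setNames(c("ci5", "ci95"))))
  structure(
    list(per_fold = per_fold, coefficients = dplyr::bind_rows(coefs),
         pooled = pooled,
         pooled_auc = roc_auc(oof, table$outcome),
         auc_ci = bootstrap_auc_ci(oof, table$outcome, n_boot = n_boot,
                                   seed = derive_seed(seed, 1L, offset = 17L)),
         scores = tibble::tibble(subject = table$subject, fold = fold,
                                 outcome = table$outcome, score = oof),
         settings = list(folds = folds, seed = seed,
                         lasso_strength = lasso_strength, alpha = alpha,
                         rho_max = rho_max, n_boot = n_boot,
                         contrast = attr(table, "contrast"),
                         variant = attr(table, "variant"))),
    class = "dki_classification"
  )
}

#' @export
print.dki_classification <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<dki_classification> %s / %s: median fold AUC %.3f, pooled AUC %.3f (boot 5-95%% %.3f-%.3f)\n",
              s$contrast %||% "?", s$variant %||% "?",
              x$pooled$auc[["median"]], x$pooled_auc,
              x$auc_ci[["lower"]], x$auc_ci[["upper"]]))
  invisible(x)
}
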