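# Synthetic long-feature cohorts for classification tests.
make_cohort_features <- function(n_per_class = 12, variant = "two_cluster",
                                 shift = 3, seed = 1) {
  feats <- dkclust:::FEATURE_SETS[[variant]]
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_per_class * 2)) {
      case <- i > n_per_class
      roi <- if (case) "T" else "H"
      vals <- rnorm(length(feats), mean = if (case) shift else 0)
      rows[[i]] <- tibble::tibble(subject = sprintf("sub%02d", i), roi = roi,
                                  variant = variant, feature = feats,
                                  value = vals)
    }
  })
  dplyr::bind_rows(rows)
}

test_that("feature tables carry the variant's declared columns", {
  fl <- make_cohort_features(variant = "two_cluster")
  tab <- build_feature_table(fl, "T_vs_H", "two_cluster")
  expect_equal(ncol(tab) - 2, 12)  # subject + outcome + 12 features
  expect_setequal(unique(tab$outcome), c(0L, 1L))

  fl2 <- make_cohort_features(variant = "conventional")
  expect_equal(ncol(build_feature_table(fl2, "T_vs_H", "conventional")) - 2, 2)

  # rows with a missing cluster are excluded with a matching count
  fl$value[fl$subject == "sub15" & fl$feature == "K2"] <- NA
  tab2 <- build_feature_table(fl, "T_vs_H", "two_cluster")
  expect_equal(attr(tab2, "n_excluded"), 1)
  expect_false("sub15" %in% tab2$subject)

  only_h <- dplyr::filter(fl, roi == "H")
  expect_error(build_feature_table(only_h, "T_vs_H", "two_cluster"),
               class = "dkclust_validation_error")
})

test_that("univariate selection keeps separating, uncorrelated features", {
  withr::with_seed(8, {
    n <- 30
    informative <- c(rnorm(n, 0), rnorm(n, 4))
    train <- tibble::tibble(
      subject = sprintf("s%d", 1:(2 * n)),
      outcome = rep(0:1, each = n),
      good = informative,
      twin = 2 * informative + 1,          # rho = 1 with good
      flat = rep(1.7, 2 * n),              # identical across classes
      noise = rnorm(2 * n)
    )
  })
  kept <- select_features(train, alpha = 0.05, rho_max = 0.8)
  expect_true("flat" %in% setdiff(names(train)[-(1:2)], kept))
  expect_equal(sum(c("good", "twin") %in% kept), 1)  # exactly one of the pair

  # when nothing survives Bonferroni, the lowest-p feature is kept with a warning
  null_train <- withr::with_seed(9, tibble::tibble(
    subject = sprintf("s%d", 1:20), outcome = rep(0:1, each = 10),
    a = rnorm(20), b = rnorm(20)))
  expect_warning(kept0 <- select_features(null_train), "lowest-p")
  expect_length(kept0, 1)
})

test_that("selection threshold reproduces a hand-enumerated 4-feature case", {
  # x-class values chosen so exact Mann-Whitney p-values are enumerable:
  # f1 fully separated (p = 2/C(12,6) * ... smallest possible), f4 interleaved
  x1 <- c(1, 2, 3, 4, 5, 6); y1 <- c(7, 8, 9, 10, 11, 12)
  train <- tibble::tibble(
    subject = sprintf("s%d", 1:12), outcome = rep(c(0, 1), each = 6),
    f1 = c(x1, y1),                    # perfect separation
    f2 = c(y1, x1),                    # perfect separation, reversed
    f3 = c(1, 3, 5, 7, 9, 11, 2, 4, 6, 8, 10, 12),  # interleaved
    f4 = c(1, 2, 3, 4, 5, 7, 6, 8, 9, 10, 11, 12)   # near-separated
  )
  # exact p for full separation at n1 = n2 = 6: 2 / C(12,6) = 2/924
  p_sep <- mw_enum_oracle(x1, y1)$p
  expect_equal(p_sep, 2 / 924, tolerance = 1e-12)
  p_f4 <- mw_enum_oracle(train$f4[1:6], train$f4[7:12])$p
  thr <- 0.05 / 4
  expected_kept <- c("f1", "f2", "f4")[c(p_sep, p_sep, p_f4) <= thr]
  kept <- select_features(train, alpha = 0.05, rho_max = 0.999)
  expect_setequal(kept, expected_kept)
})

test_that("roc_auc counts concordant pairs with ties at one half", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "dkclust_validation_error")
})

test_that("roc_auc equals Mann-Whitney U / (n1 n2) on random instances", {
  withr::with_seed(14, {
    for (i in seq_len(100)) {
      n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
      scores <- c(rnorm(n1, 0.3), rnorm(n0))
      labels <- c(rep(1, n1), rep(0, n0))
      u <- unname(wilcox.test(scores[labels == 1], scores[labels == 0],
                              exact = FALSE)$statistic)
      expect_equal(roc_auc(scores, labels), u / (n1 * n0), tolerance = 1e-12)
    }
  })
})

test_that("bootstrap AUC interval is seed-stable and degenerate when separable", {
  scores <- c(rnorm(50, 5), rnorm(50, -5))
  labels <- rep(c(1, 0), each = 50)
  ci <- bootstrap_auc_ci(scores, labels, n_boot = 200, seed = 3)
  expect_equal(unname(ci), c(1, 1))
  sc2 <- withr::with_seed(2, rnorm(40)); lb2 <- rep(c(1, 0), 20)
  expect_identical(bootstrap_auc_ci(sc2, lb2, n_boot = 500, seed = 9),
                   bootstrap_auc_ci(sc2, lb2, n_boot = 500, seed = 9))
})

test_that("bootstrap percentiles match a duplicate implementation on 20 points", {
  scores <- withr::with_seed(21, rnorm(20))
  labels <- rep(c(1, 0), 10)
  ci <- bootstrap_auc_ci(scores, labels, n_boot = 300, seed = 77)
  # independent re-implementation with the same seeded resampling sequence
  aucs <- withr::with_seed(77, {
    out <- numeric(300)
    for (i in 1:300) {
      repeat {
        idx <- sample.int(20, 20, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
      }
      s <- scores[idx]; l <- labels[idx]
      pos <- s[l == 1]; neg <- s[l == 0]
      conc <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
      out[i] <- conc / (length(pos) * length(neg))
    }
    out
  })
  expect_equal(unname(ci), unname(quantile(aucs, c(0.05, 0.95))),
               tolerance = 1e-12)
})

test_that("Youden metrics are perfect on separable scores and match enumeration", {
  ym <- youden_metrics(c(0.9, 0.7, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(ym$accuracy, 1); expect_equal(ym$precision, 1)
  expect_equal(ym$recall, 1); expect_equal(ym$f1, 1)
  expect_equal(ym$youden_j, 1)

  scores <- c(0.9, 0.6, 0.4, 0.1); labels <- c(1, 0, 1, 0)
  ym2 <- youden_metrics(scores, labels)
  # brute force over all thresholds (all midpoints and extremes)
  cand <- c(0, sort(unique(scores)), 1,
            (head(sort(unique(scores)), -1) + sort(unique(scores))[-1]) / 2)
  best <- -Inf; best_metrics <- NULL
  for (t in sort(cand)) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
    j <- tp / 2 + tn / 2 - 1  # sens + spec - 1 with n1 = n0 = 2
    if (j > best) {
      best <- j
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- tp / 2
      best_metrics <- c(acc = (tp + tn) / 4, prec = prec, rec = rec)
    }
  }
  expect_equal(ym2$youden_j, best)
  expect_equal(ym2$accuracy, unname(best_metrics["acc"]))

  # all-equal scores: degenerate all-positive convention, J = 0
  ym3 <- youden_metrics(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(ym3$youden_j, 0)
  expect_equal(ym3$recall, 1)
  expect_equal(ym3$accuracy, 0.5)
})

test_that("cross-validation separates a strongly shifted cohort perfectly", {
  fl <- make_cohort_features(n_per_class = 15, shift = 6, seed = 4)
  tab <- build_feature_table(fl, "T_vs_H", "two_cluster")
  rep_ <- crossval_classify(tab, folds = 5, seed = 2, n_boot = 100)
  expect_equal(rep_$pooled$auc[["median"]], 1.0)
  expect_equal(rep_$pooled_auc, 1.0)
  expect_true(all(rep_$per_fold$auc == 1))
  # coefficient magnitudes normalized per fold
  sums <- dplyr::summarise(dplyr::group_by(rep_$coefficients, fold),
                           s = sum(weight))$s
  expect_true(all(abs(sums - 1) < 1e-8 | sums == 0))
})

test_that("label permutation drives pooled AUC to chance", {
  fl <- make_cohort_features(n_per_class = 100, shift = 3, seed = 6,
                             variant = "one_cluster")
  tab <- build_feature_table(fl, "T_vs_H", "one_cluster")
  tab$outcome <- withr::with_seed(10, sample(tab$outcome))
  rep_ <- suppressWarnings(
    crossval_classify(tab, folds = 5, seed = 3, n_boot = 100))
  expect_gte(rep_$pooled_auc, 0.4)
  expect_lte(rep_$pooled_auc, 0.6)
})

test_that("cross-validation is deterministic and leak-free", {
  fl <- make_cohort_features(n_per_class = 12, shift = 2, seed = 12)
  tab <- build_feature_table(fl, "T_vs_H", "two_cluster")
  r1 <- crossval_classify(tab, folds = 4, seed = 11, n_boot = 200)
  r2 <- crossval_classify(tab, folds = 4, seed = 11, n_boot = 200)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$auc_ci, r2$auc_ci)

  # selection for a fold is computed on its training rows only
  fold <- dkclust:::assign_folds(tab$outcome, 4, 11)
  f1_train <- tab[fold != 1, ]
  expect_equal(r1$per_fold$selected[1],
               paste(select_features(f1_train), collapse = ","))

  # stratification failure surfaces as an error
  tiny <- tab[c(1:3, 13:14), ]
  expect_error(crossval_classify(tiny, folds = 4, seed = 1),
               class = "dkclust_stratification_error")
})

test_that("tidy and glance expose per-fold and summary views", {
  fl <- make_cohort_features(n_per_class = 10, shift = 5, seed = 3)
  tab <- build_feature_table(fl, "T_vs_H", "two_cluster")
  rep_ <- crossval_classify(tab, folds = 5, seed = 2, n_boot = 100)
  td <- tidy(rep_)
  expect_equal(nrow(td), 5)
  gl <- glance(rep_)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$variant, "two_cluster")
  expect_true(gl$boot_ci5 <= gl$boot_ci95)
  p <- ggplot2::autoplot(rep_)
  expect_s3_class(p, "ggplot")
  p2 <- ggplot2::autoplot(rep_, what = "coefficients")
  expect_s3_class(p2, "ggplot")
})
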