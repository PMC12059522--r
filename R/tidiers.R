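#' Tidy a kurtosis fit
#'
#' @param x A `kurtosis_fit`.
#' @param ... Unused.
#' @return One-row tibble: `s0`, `d`, `k`, `residual_norm`, `converged`,
#'   `n_points`.
#' @exportS3Method generics::tidy
tidy.kurtosis_fit <- function(x, ...) {
  tibble::tibble(s0 = x$s0, d = x$d, k = x$k,
                 residual_norm = x$residual_norm,
                 converged = x$converged, n_points = x$n_points)
}

#' @rdname tidy.kurtosis_fit
#' @exportS3Method generics::glance
glance.kurtosis_fit <- function(x, ...) tidy.kurtosis_fit(x, ...)

#' Tidy a cross-validated classification report
#'
#' `tidy()` returns the per-fold metrics; `glance()` a one-row summary with
#' the fold-median metrics, the pooled out-of-fold AUC and its bootstrap
#' 5-95% interval.
#'
#' @param x A `dki_classification` from [crossval_classify()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.dki_classification <- function(x, ...) x$per_fold

#' @rdname tidy.dki_classification
#' @exportS3Method generics::glance
glance.dki_classification <- function(x, ...) {
  tibble::tibble(
    contrast = x$settings$contrast %||% NA_character_,
    variant = x$settings$variant %||% NA_character_,
    auc_median = x$pooled$auc[["median"]],
    auc_ci5 = x$pooled$auc[["ci5"]],
    auc_ci95 = x$pooled$auc[["ci95"]],
    pooled_auc = x$pooled_auc,
    boot_ci5 = x$auc_ci[["lower"]],
    boot_ci95 = x$auc_ci[["upper"]],
    accuracy_median = x$pooled$accuracy[["median"]],
    precision_median = x$pooled$precision[["median"]],
    recall_median = x$pooled$recall[["median"]],
    f1_median = x$pooled$f1[["median"]]
  )
}
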