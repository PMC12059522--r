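#' Plot one slice of a voxel-wise parametric map
#'
#' @param map Parametric-map tibble from [fit_voxelwise()] (optionally with
#'   a `cluster` column from [label_and_refit()]).
#' @param parameter Column to display: "d", "k" or "s0".
#' @param slice 0-based z slice; defaults to the most populated one.
#' @return A ggplot object.
#' @export
plot_parametric_map <- function(map, parameter = c("d", "k", "s0"), slice = NULL) {
  parameter <- match.arg(parameter)
  if (is.null(slice)) {
    slice <- as.integer(names(which.max(table(map$voxel_z))))
  }
  df <- dplyr::filter(map, .data$voxel_z == slice, .data$fit_ok)
  ggplot2::ggplot(df, ggplot2::aes(.data$voxel_x, .data$voxel_y,
                                   fill = .data[[parameter]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = toupper(parameter)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "voxel x", y = "voxel y",
                  title = sprintf("%s map, slice z = %d", toupper(parameter), slice)) +
    ggplot2::theme_minimal()
}

#' Plot the cluster label map of an ROI
#'
#' @param refit Result of [label_and_refit()].
#' @param slice 0-based z slice; defaults to the most populated one.
#' @return A ggplot object.
#' @export
plot_cluster_map <- function(refit, slice = NULL) {
  maps <- refit$maps
  if (is.null(slice)) {
    slice <- as.integer(names(which.max(table(maps$voxel_z))))
  }
  df <- dplyr::filter(maps, .data$voxel_z == slice)
  ggplot2::ggplot(df, ggplot2::aes(.data$voxel_x, .data$voxel_y,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_brewer(palette = "Set1", name = "Cluster") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "voxel x", y = "voxel y",
                  title = sprintf("Diffusion compartments, slice z = %d", slice)) +
    ggplot2::theme_minimal()
}

#' Scatter of within-cluster parameter dispersion across subjects
#'
#' Plots stdK against stdD per subject-ROI for one model variant — the view
#' in which healthy tissue concentrates near the origin while tumor and
#' peritumor compartments spread along the kurtosis axis.
#'
#' @param features Long feature tibble (cohort-level).
#' @param variant Variant supplying `stdD`/`stdK` (default "cluster2").
#' @return A ggplot object.
#' @export
plot_dispersion_scatter <- function(features, variant = "cluster2") {
  df <- features |>
    dplyr::filter(.data$variant == !!variant,
                  .data$feature %in% c("stdD", "stdK")) |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$stdK, .data$stdD, colour = .data$roi)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "SD of K (dimensionless)", y = "SD of D (mm²/s)",
                  colour = "ROI",
                  title = sprintf("Within-cluster dispersion (%s)", variant)) +
    ggplot2::theme_minimal()
}

#' Autoplot a classification report
#'
#' Draws the pooled out-of-fold ROC curve and annotates the fold-median AUC
#' with its bootstrap interval; `what = "coefficients"` instead shows the
#' per-fold normalized Lasso coefficient magnitudes.
#'
#' @param object A `dki_classification`.
#' @param what "roc" or "coefficients".
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dki_classification <- function(object, what = c("roc", "coefficients"), ...) {
  what <- match.arg(what)
  if (what == "coefficients") {
    return(
      ggplot2::ggplot(object$coefficients,
                      ggplot2::aes(.data$feature, .data$weight,
                                   fill = factor(.data$fold))) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::labs(x = NULL, y = "normalized |coefficient|", fill = "fold") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
    )
  }
  sc <- object$scores
  ord <- order(sc$score, decreasing = TRUE)
  tpr <- cumsum(sc$outcome[ord] == 1) / sum(sc$outcome == 1)
  fpr <- cumsum(sc$outcome[ord] == 0) / sum(sc$outcome == 0)
  df <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  lab <- sprintf("AUC %.2f (%.2f-%.2f)", object$pooled_auc,
                 object$auc_ci[["lower"]], object$auc_ci[["upper"]])
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::annotate("text", x = 0.65, y = 0.1, label = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
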