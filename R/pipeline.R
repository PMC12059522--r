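#' Pipeline configuration
#'
#' Bundles the phantom/cohort definition with fitting, clustering and
#' classification options. Every stochastic stage derives its seed from the
#' master `seed`, so a run is fully reproducible.
#'
#' @param n_healthy,n_ec Cohort sizes.
#' @param phantom A [phantom_config()].
#' @param k Number of diffusion compartments per ROI (default 2).
#' @param select_k If TRUE, also run the silhouette scan per ROI and record
#'   the selected k (the feature pipeline still uses `k`).
#' @param min_cluster_voxels Minimum usable cluster size.
#' @param contrasts Subset of `c("T_vs_H", "PT_vs_H")`.
#' @param variants Model variants to classify with.
#' @param folds,n_boot,lasso_strength,alpha,rho_max Classification options,
#'   see [crossval_classify()].
#' @param seed Master seed.
#' @param output_dir Optional directory; when set, features, statistics,
#'   reports and the manifest are written there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_healthy = 8, n_ec = 8,
                            phantom = phantom_config(),
                            k = 2, select_k = FALSE, min_cluster_voxels = 5,
                            contrasts = c("T_vs_H", "PT_vs_H"),
                            variants = c("conventional", "two_cluster",
                                         "one_cluster", "cluster1", "cluster2"),
                            folds = 5, n_boot = 1000, lasso_strength = 1,
                            alpha = 0.05, rho_max = 0.8,
                            seed = 1L, output_dir = NULL) {
  bad <- setdiff(variants, names(FEATURE_SETS))
  if (length(bad) > 0) {
    abort(sprintf("unknown model variant(s): %s", paste(bad, collapse = ", ")),
          class = "dkclust_config_error")
  }
  bad <- setdiff(contrasts, names(CONTRASTS))
  if (length(bad) > 0) {
    abort(sprintf("unknown contrast(s): %s", paste(bad, collapse = ", ")),
          class = "dkclust_config_error")
  }
  structure(list(n_healthy = n_healthy, n_ec = n_ec, phantom = phantom,
                 k = k, select_k = select_k,
                 min_cluster_voxels = min_cluster_voxels,
                 contrasts = contrasts, variants = variants, folds = folds,
                 n_boot = n_boot, lasso_strength = lasso_strength,
                 alpha = alpha, rho_max = rho_max, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Demo configurations
#'
#' `small` is a desk-fast setting: 8 healthy + 8 cancer subjects on a
#' 48 x 48 x 3 grid. `full` mirrors the study cohort structure: 20 healthy +
#' 18 cancer subjects on the default 64 x 64 x 5 grid.
#'
#' @param scale "small" or "full".
#' @param seed Master seed.
#' @return A [pipeline_config()].
#' @export
make_demo_config <- function(scale = c("small", "full"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "small") {
    pipeline_config(n_healthy = 8, n_ec = 8,
                    phantom = phantom_config(grid_shape = c(48, 48, 3)),
                    seed = seed)
  } else {
    pipeline_config(n_healthy = 20, n_ec = 18,
                    phantom = phantom_config(grid_shape = c(64, 64, 5)),
                    seed = seed)
  }
}

config_to_list <- function(config) {
  ph <- config$phantom
  tl <- purrr::map(ph$tissues, function(ts) {
    list(name = ts$name, s0_mean = ts$s0_mean, s0_sd = ts$s0_sd,
         compartments = purrr::map(ts$compartments, unclass))
  })
  c(unclass(config)[setdiff(names(config), "phantom")],
    list(phantom = list(grid_shape = as.integer(ph$grid_shape),
                        scheme = as.numeric(ph$scheme),
                        tissues = tl, roi_geometry = ph$roi_geometry,
                        noise_sigma = ph$noise_sigma,
                        n_directions = ph$n_directions, seed = ph$seed)))
}

config_from_list <- function(lst) {
  ph <- lst$phantom
  tissues <- purrr::map(ph$tissues, function(ts)
    tissue_spec(ts$name,
                purrr::map(ts$compartments, function(cs)
                  compartment_spec(cs$fraction, cs$d_mean, cs$d_sd,
                                   cs$k_mean, cs$k_sd)),
                s0_mean = ts$s0_mean, s0_sd = ts$s0_sd))
  names(tissues) <- vapply(tissues, `[[`, character(1), "name")
  phantom <- phantom_config(grid_shape = ph$grid_shape,
                            scheme = bvalue_scheme(ph$scheme),
                            tissues = tissues, roi_geometry = ph$roi_geometry,
                            noise_sigma = ph$noise_sigma,
                            n_directions = ph$n_directions, seed = ph$seed)
  args <- lst[setdiff(names(lst), "phantom")]
  do.call(pipeline_config, c(args, list(phantom = phantom)))
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a [pipeline_config()];
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  config_from_list(yaml::read_yaml(path))
}

# md5 of a canonical on-disk text rendering; used for the run manifest.
canonical_md5 <- function(obj) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  if (is.data.frame(obj)) {
    write.csv(format(obj, digits = 15), tf, row.names = FALSE)
  } else {
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), tf)
  }
  unname(tools::md5sum(tf))
}

process_subject_roi <- function(roi, config, cl_seed) {
  map <- fit_voxelwise(roi)
  roi_fit <- fit_roi_average(roi)
  norm <- normalize_decays(roi, map)
  sel <- if (isTRUE(config$select_k) && nrow(norm) > 4) {
    select_k(norm, seed = cl_seed)
  } else NULL
  assign <- cluster_decays(norm, k = config$k, seed = cl_seed)
  refit <- label_and_refit(roi, assign, min_voxels = config$min_cluster_voxels)
  list(map = map, roi_fit = roi_fit, norm = norm, refit = refit,
       selected_k = if (is.null(sel)) NA_integer_ else sel$best_k,
       n_dropped = attr(norm, "n_dropped"))
}

#' Run the full analysis pipeline
#'
#' Simulates the configured cohort, then per subject-ROI: voxel-wise and
#' ROI-averaged kurtosis fits, log-normalization, k-means compartment
#' clustering, per-cluster refitting and feature extraction; then the group
#' statistics on subject-mean parameters and the cross-validated
#' classification for every contrast and model variant. Fit failures in a
#' single subject-ROI are logged and skipped; configuration errors abort.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `dki_pipeline_run`: `subjects` (per-subject-ROI
#'   log tibble), `features` (long tibble), `snr` (per-subject tibble),
#'   `stats` (group-comparison tibble), `reports` (named list of
#'   [crossval_classify()] results), `manifest` (named md5 hashes +
#'   settings), `warnings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- generate_cohort(config$n_healthy, config$n_ec, config$phantom,
                            seed = config$seed)
  warnings <- character()
  features <- list(); subj_log <- list(); snr_rows <- list()
  for (si in seq_along(cohort)) {
    subj <- cohort[[si]]
    tissue_rois <- if (subj$group == "healthy") "H" else c("T", "PT")
    bladder <- extract_roi_signals(subj$dwi, subj$mask, "BLADDER")
    rois <- lapply(setNames(tissue_rois, tissue_rois), function(lab)
      extract_roi_signals(subj$dwi, subj$mask, lab))
    snr_rows[[si]] <- dplyr::mutate(estimate_snr(rois, bladder),
                                    subject = subj$id, .before = 1)
    for (ri in seq_along(tissue_rois)) {
      lab <- tissue_rois[ri]
      res <- tryCatch(
        process_subject_roi(rois[[lab]], config,
                            cl_seed = derive_seed(config$seed, si, offset = ri)),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        warnings <- c(warnings, sprintf("%s/%s: %s", subj$id, lab, conditionMessage(res)))
        next
      }
      fr <- purrr::map_dfr(config$variants, function(v)
        compute_features(v, roi_fit = res$roi_fit, roi_map = res$map,
                         refit = res$refit, subject = subj$id, roi_label = lab))
      features[[length(features) + 1]] <- fr
      subj_log[[length(subj_log) + 1]] <- tibble::tibble(
        subject = subj$id, group = subj$group, roi = lab,
        n_voxels = nrow(rois[[lab]]), n_dropped = res$n_dropped,
        selected_k = res$selected_k,
        d_mean = mean(res$map$d[res$map$fit_ok]),
        k_mean = mean(res$map$k[res$map$fit_ok])
      )
    }
  }
  features <- dplyr::bind_rows(features)
  subj_log <- dplyr::bind_rows(subj_log)
  snr_tab <- dplyr::bind_rows(snr_rows)

  param_df <- dplyr::select(subj_log, "subject", "roi",
                            D = "d_mean", K = "k_mean")
  stats_tab <- tryCatch(group_stats(param_df, alpha = config$alpha),
                        error = function(e) {
                          warnings <<- c(warnings, paste("group stats:", conditionMessage(e)))
                          tibble::tibble()
                        })

  reports <- list()
  for (ct in config$contrasts) {
    for (v in config$variants) {
      key <- paste(ct, v, sep = ".")
      rep_ <- tryCatch({
        tab <- build_feature_table(features, contrast = ct, variant = v)
        crossval_classify(tab, folds = config$folds,
                          seed = derive_seed(config$seed, 7777,
                                             offset = length(reports)),
                          lasso_strength = config$lasso_strength,
                          alpha = config$alpha, rho_max = config$rho_max,
                          n_boot = config$n_boot)
      }, error = function(e) e)
      if (inherits(rep_, "error")) {
        warnings <- c(warnings, sprintf("%s: %s", key, conditionMessage(rep_)))
      } else {
        reports[[key]] <- rep_
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dkclust")),
    seed = config$seed,
    n_subjects = length(cohort),
    hashes = list(
      features = canonical_md5(features),
      subjects = canonical_md5(subj_log),
      stats = canonical_md5(stats_tab),
      reports = canonical_md5(purrr::map(reports, function(r)
        c(r$pooled$auc, pooled_auc = r$pooled_auc, r$auc_ci)))
    ),
    warnings = warnings
  )

  run <- structure(
    list(subjects = subj_log, features = features, snr = snr_tab,
         stats = stats_tab, reports = reports, manifest = manifest,
         config = config, warnings = warnings),
    class = "dki_pipeline_run"
  )
  if (!is.null(config$output_dir)) write_pipeline_outputs(run, config$output_dir)
  run
}

write_pipeline_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$features, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(run$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  write.csv(run$stats, file.path(dir, "group_stats.csv"), row.names = FALSE)
  jsonlite::write_json(
    purrr::map(run$reports, function(r)
      list(per_fold = r$per_fold[, c("fold", "auc", "accuracy", "precision",
                                     "recall", "f1")],
           pooled = r$pooled, pooled_auc = r$pooled_auc, auc_ci = r$auc_ci)),
    file.path(dir, "reports.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.dki_pipeline_run <- function(x, ...) {
  cat(sprintf("<dki_pipeline_run> %d subjects, %d subject-ROIs, %d reports, %d warnings\n",
              x$manifest$n_subjects, nrow(x$subjects), length(x$reports),
              length(x$warnings)))
  invisible(x)
}
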