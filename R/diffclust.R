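#' Log-normalize voxel decays by the fitted Se(0)
#'
#' Each retained voxel's decay is divided by its own voxel-wise fitted signal
#' at b = 0 (Se(0), i.e. the fitted S0) and log-transformed:
#' `ln(S(b) / Se(0))`. This removes proton-density/coil-gain differences so
#' that clustering sees only decay shape. Rows with a failed fit or any
#' nonpositive signal are dropped; the dropped count is kept as an attribute.
#'
#' @param roi ROI signal tibble from [extract_roi_signals()].
#' @param map Voxel-wise parametric map from [fit_voxelwise()], aligned row
#'   by row with `roi`.
#' @return Tibble of log-normalized signals (columns `b500`, ...) plus the
#'   voxel coordinates and `row` (the originating row index in `roi`);
#'   attributes `n_dropped` and `scheme`.
#' @export
normalize_decays <- function(roi, map) {
  sig <- roi_signal_matrix(roi)
  if (nrow(sig) != nrow(map)) {
    abort("map is not aligned with the ROI matrix", class = "dkclust_validation_error")
  }
  keep <- map$fit_ok & is.finite(map$s0) & map$s0 > 0 &
    apply(sig, 1, function(r) all(is.finite(r) & r > 0))
  if (!any(keep)) {
    abort("no voxels survive normalization", class = "dkclust_empty_roi_error")
  }
  logn <- log(sig[keep, , drop = FALSE] / map$s0[keep])
  colnames(logn) <- colnames(sig)
  out <- tibble::as_tibble(cbind(
    tibble::tibble(row = which(keep),
                   voxel_x = roi$voxel_x[keep],
                   voxel_y = roi$voxel_y[keep],
                   voxel_z = roi$voxel_z[keep]),
    tibble::as_tibble(logn)
  ))
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "scheme") <- roi_scheme(roi)
  out
}

norm_decay_matrix <- function(norm) {
  as.matrix(norm[, grep("^b[0-9]+$", names(norm)), drop = FALSE])
}

# k-means++ seeding followed by Lloyd iterations; deterministic given the
# RNG state. Returns a stats::kmeans fit.
kmeanspp_once <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j, ] <- x[sample.int(n, 1), ]
      } else {
        centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
      }
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd")
}

run_kmeans <- function(x, k, seed, restarts = 10) {
  if (nrow(x) < k) {
    abort("fewer voxels than clusters", class = "dkclust_validation_error")
  }
  if (nrow(unique(as.data.frame(x))) < k) {
    abort("fewer distinct rows than clusters", class = "dkclust_degenerate_cluster_error")
  }
  withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- tryCatch(suppressWarnings(kmeanspp_once(x, k)), error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) {
      abort("k-means failed on degenerate data", class = "dkclust_degenerate_cluster_error")
    }
    best
  })
}

#' Choose the number of diffusion compartments by silhouette
#'
#' Runs seeded k-means for each candidate k on the log-normalized decays and
#' scores each partition by the mean silhouette width (Euclidean distance);
#' the k with the largest mean silhouette wins.
#'
#' @param norm Log-normalized decay tibble from [normalize_decays()].
#' @param candidates Candidate cluster counts, default 2:4.
#' @param seed Integer seed.
#' @return List with `best_k` and `silhouette_by_k` (tibble k, mean
#'   silhouette).
#' @export
select_k <- function(norm, candidates = 2:4, seed = 1L) {
  x <- norm_decay_matrix(norm)
  if (nrow(x) <= max(candidates)) {
    abort("need more voxels than the largest candidate k",
          class = "dkclust_validation_error")
  }
  dm <- stats::dist(x)
  sil <- vapply(candidates, function(k) {
    fit <- run_kmeans(x, k, seed = derive_seed(seed, k))
    mean(cluster::silhouette(fit$cluster, dm)[, "sil_width"])
  }, numeric(1))
  tab <- tibble::tibble(k = as.integer(candidates), mean_silhouette = sil)
  list(best_k = tab$k[which.max(tab$mean_silhouette)], silhouette_by_k = tab)
}

#' Cluster voxel decays into diffusion compartments
#'
#' Seeded k-means (k-means++ seeding, 10 restarts, Lloyd iterations,
#' Euclidean distance) on the log-normalized decay vectors. The pipeline
#' default is k = 2, reflecting the two main diffusive compartments the
#' silhouette analysis typically selects in endometrial tissue.
#'
#' @param norm Log-normalized decay tibble from [normalize_decays()].
#' @param k Number of clusters (default 2).
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts.
#' @return Object of class `cluster_assignment`: `k`, `labels` (per retained
#'   voxel), `centers`, `tot_withinss`, `rows` (row indices into the source
#'   ROI matrix).
#' @export
cluster_decays <- function(norm, k = 2, seed = 1L, restarts = 10) {
  x <- norm_decay_matrix(norm)
  fit <- run_kmeans(x, k, seed = seed, restarts = restarts)
  structure(
    list(k = k, labels = as.integer(fit$cluster), centers = fit$centers,
         tot_withinss = fit$tot.withinss, rows = norm$row, seed = seed),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d over %d voxels (within-SS %.4g)\n",
              x$k, length(x$labels), x$tot_withinss))
  invisible(x)
}

#' Refit clusters on original signals and order them by K/D
#'
#' Reruns the voxel-wise kurtosis fit per cluster on the original
#' (unnormalized) signals, then orders clusters by their mean-K / mean-D
#' ratio: the minimum-ratio cluster becomes Cluster 1, the maximum-ratio
#' cluster the last. Ties break toward the lower original cluster index.
#' Clusters with fewer usable voxels than `min_voxels` are flagged unusable
#' so downstream features are marked missing instead of unstable.
#'
#' @param roi ROI signal tibble the assignment came from.
#' @param assignment A `cluster_assignment` from [cluster_decays()].
#' @param min_voxels Minimum usable cluster size (default 5).
#' @param ... Passed to [fit_kurtosis()].
#' @return List with `maps` (parametric-map tibble with a `cluster` column of
#'   ordered labels), `label_order` (original index -> ordered label),
#'   `ratios` (mean K / mean D per ordered cluster), `usable` (logical per
#'   ordered cluster).
#' @export
label_and_refit <- function(roi, assignment, min_voxels = 5, ...) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  k <- assignment$k
  per <- vector("list", k)
  for (ci in seq_len(k)) {
    rows <- assignment$rows[assignment$labels == ci]
    sub <- roi[rows, , drop = FALSE]
    attr(sub, "scheme") <- roi_scheme(roi)
    per[[ci]] <- fit_voxelwise(sub, ...)
  }
  ratio <- vapply(per, function(m) {
    ok <- m$fit_ok
    if (!any(ok)) return(NA_real_)
    mean(m$k[ok]) / mean(m$d[ok])
  }, numeric(1))
  ord <- order(ratio)  # ties keep ascending original index (stable)
  label_order <- match(seq_len(k), ord)  # original index -> ordered label
  maps <- purrr::map_dfr(seq_len(k), function(pos) {
    m <- per[[ord[pos]]]
    m$cluster <- pos
    m
  })
  usable <- vapply(seq_len(k), function(pos) {
    sum(per[[ord[pos]]]$fit_ok) >= min_voxels
  }, logical(1))
  list(maps = maps, label_order = label_order,
       ratios = ratio[ord], usable = usable)
}

FEATURE_SETS <- list(
  conventional = c("D", "K"),
  one_cluster = c("D", "K", "stdD", "stdK", "KDratio"),
  cluster1 = c("D", "K", "stdD", "stdK", "KDratio"),
  cluster2 = c("D", "K", "stdD", "stdK", "KDratio"),
  two_cluster = c("D1", "K1", "stdD1", "stdK1", "KDratio1",
                  "D2", "K2", "stdD2", "stdK2", "KDratio2",
                  "Dratio", "Kratio")
)

cluster_stats <- function(map_rows) {
  ok <- map_rows$fit_ok
  if (sum(ok) == 0) return(c(D = NA_real_, K = NA_real_, stdD = NA_real_, stdK = NA_real_))
  c(D = mean(map_rows$d[ok]), K = mean(map_rows$k[ok]),
    stdD = sd(map_rows$d[ok]), stdK = sd(map_rows$k[ok]))
}

#' Compute the cluster-statistic feature sets
#'
#' Builds the feature vector of a model variant for one subject-ROI:
#' * `conventional` — (D, K) from the ROI-averaged fit;
#' * `one_cluster` — mean/SD of the voxel-wise fits over the whole ROI plus
#'   KDratio = K/D (5 features);
#' * `cluster1` / `cluster2` — the same 5 statistics over one ordered
#'   cluster;
#' * `two_cluster` — both clusters' 5 statistics plus Dratio = D1/D2 and
#'   Kratio = K1/K2 (12 features).
#' Means and SDs are taken over successfully fitted voxels only. Features of
#' an unusable cluster are emitted as NA.
#'
#' @param variant One of "conventional", "one_cluster", "cluster1",
#'   "cluster2", "two_cluster".
#' @param roi_fit ROI-average `kurtosis_fit` (conventional variant).
#' @param roi_map Whole-ROI parametric map (one_cluster variant).
#' @param refit Result of [label_and_refit()] (cluster variants).
#' @param subject,roi_label Provenance strings carried into the output.
#' @return Long tibble: `subject`, `roi`, `variant`, `feature`, `value`.
#' @export
compute_features <- function(variant, roi_fit = NULL, roi_map = NULL,
                             refit = NULL, subject = NA_character_,
                             roi_label = NA_character_) {
  variant <- match.arg(variant, names(FEATURE_SETS))
  vals <- switch(variant,
    conventional = {
      stopifnot(inherits(roi_fit, "kurtosis_fit"))
      c(D = roi_fit$d, K = roi_fit$k)
    },
    one_cluster = {
      stopifnot(is.data.frame(roi_map))
      st <- cluster_stats(roi_map)
      c(st, KDratio = unname(st["K"] / st["D"]))
    },
    cluster1 = single_cluster_features(refit, 1),
    cluster2 = single_cluster_features(refit, 2),
    two_cluster = {
      stopifnot(!is.null(refit))
      s1 <- cluster_stats(refit$maps[refit$maps$cluster == 1, ])
      s2 <- cluster_stats(refit$maps[refit$maps$cluster == 2, ])
      if (!isTRUE(refit$usable[1])) s1[] <- NA_real_
      if (!isTRUE(refit$usable[2])) s2[] <- NA_real_
      c(D1 = unname(s1["D"]), K1 = unname(s1["K"]),
        stdD1 = unname(s1["stdD"]), stdK1 = unname(s1["stdK"]),
        KDratio1 = unname(s1["K"] / s1["D"]),
        D2 = unname(s2["D"]), K2 = unname(s2["K"]),
        stdD2 = unname(s2["stdD"]), stdK2 = unname(s2["stdK"]),
        KDratio2 = unname(s2["K"] / s2["D"]),
        Dratio = unname(s1["D"] / s2["D"]), Kratio = unname(s1["K"] / s2["K"]))
    }
  )
  stopifnot(identical(names(vals), FEATURE_SETS[[variant]]))
  tibble::tibble(subject = subject, roi = roi_label, variant = variant,
                 feature = names(vals), value = unname(vals))
}

single_cluster_features <- function(refit, which_cluster) {
  stopifnot(!is.null(refit))
  st <- cluster_stats(refit$maps[refit$maps$cluster == which_cluster, ])
  if (!isTRUE(refit$usable[which_cluster])) st[] <- NA_real_
  c(st, KDratio = unname(st["K"] / st["D"]))
}
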