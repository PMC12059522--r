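test_that("log-normalization reduces noise-free rows to the decay exponent", {
  b <- as.numeric(paper_scheme())
  roi <- make_clean_roi(6, s0 = c(500, 1000, 1500, 500, 1000, 1500),
                        d = 1.1e-3, k = 0.9)
  map <- fit_voxelwise(roi)
  norm <- normalize_decays(roi, map)
  expected <- -b * 1.1e-3 + b^2 * (1.1e-3)^2 * 0.9 / 6
  for (i in 1:6) {
    expect_equal(as.numeric(sig_mat(norm)[i, ]), expected, tolerance = 1e-6)
  }
  # S0 cancellation: all rows identical despite different S0
  expect_lt(max(apply(sig_mat(norm), 2, sd)), 1e-8)
})

test_that("rows dropped by normalization match a brute-force recount", {
  roi <- simulate_recovery_roi(snr = 8, seed = 17, n = 120)
  map <- fit_voxelwise(roi)
  sig <- sig_mat(roi)
  expect_dropped <- sum(!(map$fit_ok & map$s0 > 0 &
                            apply(sig, 1, function(r) all(r > 0))))
  norm <- normalize_decays(roi, map)
  expect_equal(attr(norm, "n_dropped"), expect_dropped)
  expect_equal(nrow(norm) + attr(norm, "n_dropped"), nrow(roi))
  expect_true(all(is.finite(sig_mat(norm))))
})

# Build a normalized-decay tibble directly (bundle construction).
make_norm <- function(x) {
  colnames(x) <- paste0("b", seq_len(ncol(x)))
  out <- tibble::as_tibble(cbind(
    tibble::tibble(row = seq_len(nrow(x)), voxel_x = seq_len(nrow(x)) - 1L,
                   voxel_y = 0L, voxel_z = 0L),
    tibble::as_tibble(x)
  ))
  out
}

test_that("silhouette selects the constructed number of bundles", {
  withr::with_seed(31, {
    two <- rbind(matrix(rnorm(60 * 3, 0, 0.01), ncol = 3),
                 matrix(rnorm(60 * 3, 5, 0.01), ncol = 3))
    three <- rbind(matrix(rnorm(40 * 3, 0, 0.01), ncol = 3),
                   matrix(rnorm(40 * 3, 5, 0.01), ncol = 3),
                   matrix(rnorm(40 * 3, 10, 0.01), ncol = 3))
  })
  s2 <- select_k(make_norm(two), seed = 5)
  expect_equal(s2$best_k, 2L)
  expect_gt(s2$silhouette_by_k$mean_silhouette[s2$silhouette_by_k$k == 2], 0.9)
  s3 <- select_k(make_norm(three), seed = 5)
  expect_equal(s3$best_k, 3L)
  expect_error(select_k(make_norm(two[1:4, ]), candidates = 2:4),
               class = "dkclust_validation_error")
})

test_that("mean silhouette agrees with a from-scratch a/b recomputation", {
  x <- withr::with_seed(77, rbind(matrix(rnorm(15 * 4, 0, 1), ncol = 4),
                                  matrix(rnorm(15 * 4, 3, 1), ncol = 4)))
  norm <- make_norm(x)
  sel <- select_k(norm, candidates = 2, seed = 9)
  asg <- cluster_decays(norm, 2, seed = dkclust:::derive_seed(9, 2))
  expect_equal(sel$silhouette_by_k$mean_silhouette[1],
               silhouette_oracle(x, asg$labels), tolerance = 1e-10)
})

test_that("k-means partition matches the exhaustive bipartition oracle", {
  x <- withr::with_seed(41, matrix(rnorm(12, 0, 2), ncol = 2))  # 6 points, 2D
  norm <- make_norm(x)
  asg <- cluster_decays(norm, 2, seed = 13)
  # exhaustive search over all 2^5 nontrivial bipartitions
  best_sse <- Inf; best_split <- NULL
  for (code in 1:(2^5 - 1)) {
    grp <- c(0L, as.integer(intToBits(code)[1:5]))
    sse <- 0
    for (g in 0:1) {
      pts <- x[grp == g, , drop = FALSE]
      if (nrow(pts) == 0) next
      ctr <- colMeans(pts)
      sse <- sse + sum(sweep(pts, 2, ctr)^2)
    }
    if (sse < best_sse) { best_sse <- sse; best_split <- grp }
  }
  a <- asg$labels == asg$labels[1]
  b2 <- best_split == best_split[1]
  expect_true(identical(a, b2) || identical(a, !b2))
  expect_equal(asg$tot_withinss, best_sse, tolerance = 1e-9)
})

test_that("clustering is deterministic under a fixed seed and degenerate
           bundles split perfectly", {
  x <- rbind(matrix(1.5, 10, 4), matrix(-2, 8, 4))
  norm <- make_norm(x)
  asg <- cluster_decays(norm, 2, seed = 3)
  expect_equal(asg$tot_withinss, 0)
  expect_length(unique(asg$labels[1:10]), 1)
  expect_length(unique(asg$labels[11:18]), 1)
  asg2 <- cluster_decays(norm, 2, seed = 3)
  expect_identical(asg$labels, asg2$labels)
  expect_error(cluster_decays(make_norm(matrix(1, 6, 4)), 2, seed = 1),
               class = "dkclust_degenerate_cluster_error")
})

test_that("clusters are ordered by mean-K/mean-D with a deterministic tie-break", {
  # cluster A: K = 0.6, D = 1.5e-3 (ratio 400); B: K = 1.8, D = 0.5e-3 (3600)
  roi <- make_clean_roi(24, d = rep(c(1.5e-3, 0.5e-3), each = 12),
                        k = rep(c(0.6, 1.8), each = 12))
  map <- fit_voxelwise(roi)
  norm <- normalize_decays(roi, map)
  asg <- cluster_decays(norm, 2, seed = 19)
  refit <- label_and_refit(roi, asg)
  expect_equal(refit$ratios, c(400, 3600), tolerance = 1e-4)
  m1 <- refit$maps[refit$maps$cluster == 1, ]
  expect_equal(mean(m1$k), 0.6, tolerance = 1e-6)

  # equal ratios: ascending original cluster index wins
  roi_tie <- make_clean_roi(16, d = 1e-3, k = 0.9)
  map_tie <- fit_voxelwise(roi_tie)
  norm_tie <- normalize_decays(roi_tie, map_tie)
  asg_tie <- structure(list(k = 2, labels = rep(1:2, each = 8),
                            rows = norm_tie$row, seed = 1,
                            centers = NULL, tot_withinss = 0),
                       class = "cluster_assignment")
  refit_tie <- label_and_refit(roi_tie, asg_tie)
  expect_equal(refit_tie$label_order, c(1L, 2L))
})

test_that("small clusters are flagged unusable and surface as missing features", {
  roi <- make_clean_roi(20, d = c(rep(1.4e-3, 17), rep(0.5e-3, 3)),
                        k = c(rep(0.6, 17), rep(1.8, 3)))
  map <- fit_voxelwise(roi)
  norm <- normalize_decays(roi, map)
  asg <- cluster_decays(norm, 2, seed = 8)
  refit <- label_and_refit(roi, asg, min_voxels = 5)
  expect_identical(refit$usable, c(TRUE, FALSE))
  f <- compute_features("two_cluster", refit = refit, subject = "s", roi_label = "T")
  expect_true(all(is.na(f$value[f$feature %in% c("D2", "K2", "stdD2", "stdK2")])))
  expect_false(anyNA(f$value[f$feature %in% c("D1", "K1")]))
})

test_that("noise-free two-compartment ROIs recover both truths within 1%", {
  roi <- make_clean_roi(60, d = rep(c(1.0e-3, 0.5e-3), each = 30),
                        k = rep(c(0.9, 1.8), each = 30))
  map <- fit_voxelwise(roi)
  norm <- normalize_decays(roi, map)
  asg <- cluster_decays(norm, 2, seed = 77)
  refit <- label_and_refit(roi, asg)
  m1 <- refit$maps[refit$maps$cluster == 1, ]  # low K/D: (1.0e-3, 0.9)
  m2 <- refit$maps[refit$maps$cluster == 2, ]
  expect_lt(abs(mean(m1$d) - 1.0e-3) / 1.0e-3, 0.01)
  expect_lt(abs(mean(m1$k) - 0.9) / 0.9, 0.01)
  expect_lt(abs(mean(m2$d) - 0.5e-3) / 0.5e-3, 0.01)
  expect_lt(abs(mean(m2$k) - 1.8) / 1.8, 0.01)
})

test_that("feature sets have the declared sizes and identities", {
  withr::with_seed(51, {
    roi <- make_clean_roi(40, s0 = runif(40, 900, 1100),
                          d = rep(c(1.0e-3, 0.5e-3), each = 20) + rnorm(40, 0, 2e-5),
                          k = rep(c(0.9, 1.8), each = 20) + rnorm(40, 0, 0.05))
  })
  map <- fit_voxelwise(roi)
  roi_fit <- fit_roi_average(roi)
  norm <- normalize_decays(roi, map)
  asg <- cluster_decays(norm, 2, seed = 5)
  refit <- label_and_refit(roi, asg)

  two <- compute_features("two_cluster", refit = refit, subject = "s", roi_label = "T")
  expect_equal(nrow(two), 12)
  v <- setNames(two$value, two$feature)
  expect_equal(v[["KDratio1"]], v[["K1"]] / v[["D1"]])
  expect_equal(v[["KDratio2"]], v[["K2"]] / v[["D2"]])
  expect_equal(v[["Dratio"]], v[["D1"]] / v[["D2"]])
  expect_equal(v[["Kratio"]], v[["K1"]] / v[["K2"]])

  one <- compute_features("one_cluster", roi_map = map, subject = "s", roi_label = "T")
  expect_equal(nrow(one), 5)
  conv <- compute_features("conventional", roi_fit = roi_fit, subject = "s",
                           roi_label = "T")
  expect_equal(nrow(conv), 2)
  expect_equal(conv$value, c(roi_fit$d, roi_fit$k))
  c2 <- compute_features("cluster2", refit = refit, subject = "s", roi_label = "T")
  expect_equal(nrow(c2), 5)
})

test_that("cluster statistics equal hand-computed means and SDs on a toy map", {
  toy <- tibble::tibble(
    voxel_x = 0:9, voxel_y = 0L, voxel_z = 0L,
    s0 = 1000, d = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10) * 1e-4,
    k = c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.1, 1.2, 1.3, 1.4),
    residual_norm = 0, fit_ok = rep(c(TRUE, FALSE), each = 5)
  )
  f <- compute_features("one_cluster", roi_map = toy, subject = "s", roi_label = "H")
  v <- setNames(f$value, f$feature)
  expect_equal(v[["D"]], mean(c(1, 2, 3, 4, 5) * 1e-4))
  expect_equal(v[["K"]], mean(c(0.5, 0.6, 0.7, 0.8, 0.9)))
  expect_equal(v[["stdD"]], sd(c(1, 2, 3, 4, 5) * 1e-4))
  expect_equal(v[["stdK"]], sd(c(0.5, 0.6, 0.7, 0.8, 0.9)))
  expect_equal(v[["KDratio"]], v[["K"]] / v[["D"]])

  # zero dispersion: stdD = stdK = 0
  flat <- dplyr::mutate(toy, d = 1e-3, k = 0.8, fit_ok = TRUE)
  f0 <- compute_features("one_cluster", roi_map = flat, subject = "s", roi_label = "H")
  expect_equal(unname(f0$value[f0$feature %in% c("stdD", "stdK")]), c(0, 0))
})
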