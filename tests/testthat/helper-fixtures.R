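# Shared fixture builders; everything is generated in code at test time.

paper_scheme <- function() bvalue_scheme(c(500, 800, 1000, 1500, 2000, 2500))

sig_mat <- function(roi) as.matrix(roi[, grep("^b[0-9]+$", names(roi)), drop = FALSE])

# Wrap a plain signal matrix into the ROI-tibble shape the fitters expect.
make_roi_tibble <- function(sig, scheme = paper_scheme(), label = "T") {
  colnames(sig) <- paste0("b", as.numeric(scheme))
  out <- tibble::as_tibble(cbind(
    tibble::tibble(voxel_x = seq_len(nrow(sig)) - 1L, voxel_y = 0L, voxel_z = 0L),
    tibble::as_tibble(sig)
  ))
  attr(out, "scheme") <- scheme
  attr(out, "roi_label") <- label
  out
}

# Noise-free ROI with given per-voxel truths (vectors recycled to n).
make_clean_roi <- function(n, s0 = 1000, d = 1e-3, k = 0.8,
                           scheme = paper_scheme()) {
  b <- as.numeric(scheme)
  s0 <- rep_len(s0, n); d <- rep_len(d, n); k <- rep_len(k, n)
  sig <- t(vapply(seq_len(n), function(i) kurtosis_signal(s0[i], d[i], k[i], b),
                  numeric(length(b))))
  make_roi_tibble(sig, scheme)
}

# 300-voxel single-compartment Rician recovery experiment (3-direction
# averaging, per-direction sigma = s0 / snr).
simulate_recovery_roi <- function(snr, seed, n = 300, s0 = 1000,
                                  d = 1.4e-3, k = 0.6, n_dir = 3) {
  scheme <- paper_scheme()
  b <- as.numeric(scheme)
  clean <- kurtosis_signal(s0, d, k, b)
  sig <- withr::with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      rowMeans(vapply(seq_len(n_dir),
                      function(j) add_rician_noise(clean, s0 / snr),
                      numeric(length(b))))
    }, numeric(length(b))))
  })
  make_roi_tibble(sig, scheme)
}

# Small phantom grid for cohort-level tests.
small_phantom <- function(noise_sigma = 15, seed = 1L) {
  phantom_config(grid_shape = c(48, 48, 3), noise_sigma = noise_sigma, seed = seed)
}

# Independent exact Mann-Whitney oracle: enumerate all C(n1+n2, n1)
# placements of x-ranks, two-sided p = 2 * min(P(U <= u), P(U >= u)), capped.
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u_obs <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Hand silhouette: per-point (b - a) / max(a, b) from explicit loops.
silhouette_oracle <- function(x, labels) {
  n <- nrow(x)
  dmat <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(dmat[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(dmat[i, labels == l]), numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}
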