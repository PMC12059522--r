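#' Constrained kurtosis fit of one signal decay
#'
#' Least-squares fit of `S(b) = S0 exp(-b D + b^2 D^2 K / 6)` to one decay
#' vector under box constraints on D and K, via bound-constrained
#' quasi-Newton minimization of the sum of squared residuals with an
#' analytic gradient. Initial D comes from the log-linear slope over the two
#' smallest b-values, S0 from extrapolating that line to b = 0, K starts at
#' 1. On non-convergence the optimizer restarts from up to `max_restarts`
#' fixed quasi-random interior points, so the procedure is deterministic.
#'
#' @param signal Positive decay values, one per b-value.
#' @param scheme A [bvalue_scheme()] (or numeric b-values), length >= 4.
#' @param k_bounds Kurtosis box, default \[-0.7, 3.7\].
#' @param d_bounds Diffusivity box in mm^2/s, default \[0.01, 3\]e-3.
#' @param max_restarts Extra deterministic starts tried on failure.
#' @return Object of class `kurtosis_fit`: `s0`, `d`, `k`, `residual_norm`
#'   (sqrt of the summed squared residuals, signal units), `converged`,
#'   `n_points`.
#' @examples
#' b <- bvalue_scheme()
#' y <- kurtosis_signal(1000, 1e-3, 0.8, as.numeric(b))
#' fit_kurtosis(y, b)
#' @export
fit_kurtosis <- function(signal, scheme, k_bounds = c(-0.7, 3.7),
                         d_bounds = c(0.01e-3, 3e-3), max_restarts = 5) {
  b <- as.numeric(scheme)
  if (length(b) < 4) {
    abort("need at least 4 b-values for a 3-parameter fit",
          class = "dkclust_validation_error")
  }
  if (length(signal) != length(b)) {
    abort("signal and scheme lengths differ", class = "dkclust_validation_error")
  }
  if (anyNA(signal) || any(!is.finite(signal)) || any(signal <= 0)) {
    abort("signals must be finite and > 0", class = "dkclust_validation_error")
  }

  lower <- c(1e-9, d_bounds[1], k_bounds[1])
  upper <- c(Inf, d_bounds[2], k_bounds[2])

  obj <- function(p) {
    r <- p[1] * exp(-b * p[2] + (1 / 6) * b^2 * p[2]^2 * p[3]) - signal
    sum(r * r)
  }
  grad <- function(p) {
    e <- exp(-b * p[2] + (1 / 6) * b^2 * p[2]^2 * p[3])
    m <- p[1] * e
    r <- m - signal
    c(2 * sum(r * e),
      2 * sum(r * m * (-b + b^2 * p[2] * p[3] / 3)),
      2 * sum(r * m * b^2 * p[2]^2 / 6))
  }

  starts <- list(init_loglinear(signal, b, d_bounds, k_bounds),
                 init_kurtosis(signal, b, d_bounds))
  starts <- starts[!vapply(starts, is.null, logical(1))]
  # fixed interior fractions (low-discrepancy-ish), scaled to the boxes
  fr <- matrix(c(0.50, 0.50, 0.25, 0.75, 0.75, 0.25, 0.25, 0.25, 0.75, 0.75),
               ncol = 2, byrow = TRUE)
  s0_scale <- max(signal)
  for (i in seq_len(min(max_restarts, nrow(fr)))) {
    starts[[length(starts) + 1]] <- c(
      s0_scale * (1 + i / 4),
      d_bounds[1] + fr[i, 1] * diff(d_bounds),
      k_bounds[1] + fr[i, 2] * diff(k_bounds)
    )
  }

  best <- NULL
  converged <- FALSE
  for (p0 in starts) {
    res <- tryCatch(
      nlminb(p0, obj, gradient = grad, lower = lower, upper = upper,
             control = list(eval.max = 800, iter.max = 500,
                            rel.tol = 1e-10, x.tol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective) best <- res
    if (res$convergence == 0) {
      converged <- TRUE
      if (res$objective <= best$objective) best <- res
      break
    }
  }
  if (is.null(best)) {
    abort("kurtosis fit failed at every start", class = "dkclust_fit_error")
  }
  structure(
    list(s0 = best$par[1], d = best$par[2], k = best$par[3],
         residual_norm = sqrt(best$objective), converged = converged,
         n_points = length(b), k_bounds = k_bounds, d_bounds = d_bounds),
    class = "kurtosis_fit"
  )
}

# Log-linear least-squares start: ln S = ln S0 - b*D + b^2*(D^2 K / 6) is
# linear in (ln S0, D, D^2 K / 6), so a linear solve inverts noiseless data
# exactly and lands close on noisy data. Projected into the boxes.
init_loglinear <- function(signal, b, d_bounds, k_bounds) {
  X <- cbind(1, -b, b^2)
  th <- tryCatch(qr.solve(X, log(signal)), error = function(e) NULL)
  if (is.null(th) || any(!is.finite(th))) return(NULL)
  d0 <- min(max(th[2], d_bounds[1]), d_bounds[2])
  k0 <- min(max(6 * th[3] / d0^2, k_bounds[1]), k_bounds[2])
  c(exp(th[1]), d0, k0)
}

# Fallback start from the slope over the two smallest b-values.
init_kurtosis <- function(signal, b, d_bounds) {
  sl <- (log(signal[2]) - log(signal[1])) / (b[2] - b[1])
  d0 <- min(max(-sl, d_bounds[1] * 1.5), d_bounds[2] * 0.9)
  s00 <- exp(log(signal[1]) + d0 * b[1])
  c(s00, d0, 1.0)
}

#' @export
print.kurtosis_fit <- function(x, ...) {
  cat(sprintf("<kurtosis_fit> S0 = %.4g, D = %.4g mm^2/s, K = %.4g (%s, rnorm %.3g)\n",
              x$s0, x$d, x$k, if (x$converged) "converged" else "NOT converged",
              x$residual_norm))
  invisible(x)
}

#' Fit the ROI-averaged decay
#'
#' Fits the kurtosis representation to the voxel-mean signal of an ROI —
#' the conventional analysis whose (D, K) pair forms the two-feature model.
#'
#' @param roi An ROI signal tibble from [extract_roi_signals()].
#' @param ... Passed to [fit_kurtosis()].
#' @return A `kurtosis_fit`.
#' @export
fit_roi_average <- function(roi, ...) {
  sig <- roi_signal_matrix(roi)
  if (nrow(sig) == 0) abort("empty ROI", class = "dkclust_empty_roi_error")
  fit_kurtosis(colMeans(sig), roi_scheme(roi), ...)
}

#' Voxel-wise kurtosis fitting (parametric map)
#'
#' Fits every voxel decay of an ROI independently. Voxels with any
#' nonpositive intensity are excluded (`fit_ok = FALSE`, parameters NA)
#' rather than clipped, because downstream log-normalization requires
#' positivity; non-converged fits are likewise flagged, as are fits pinned
#' at the D or K box boundary — a pinned estimate is censored rather than
#' identified, so it would bias cluster statistics.
#'
#' @param roi An ROI signal tibble from [extract_roi_signals()].
#' @param ... Passed to [fit_kurtosis()].
#' @return A tibble (one row per ROI voxel, same order) with `voxel_x/y/z`,
#'   `s0`, `d`, `k`, `residual_norm`, `fit_ok`.
#' @export
fit_voxelwise <- function(roi, ...) {
  sig <- roi_signal_matrix(roi)
  if (nrow(sig) == 0) abort("empty ROI", class = "dkclust_empty_roi_error")
  scheme <- roi_scheme(roi)
  n <- nrow(sig)
  s0 <- d <- k <- rn <- rep(NA_real_, n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    y <- sig[i, ]
    if (any(!is.finite(y)) || any(y <= 0)) next
    f <- tryCatch(fit_kurtosis(y, scheme, ...), error = function(e) NULL)
    if (is.null(f)) next
    s0[i] <- f$s0; d[i] <- f$d; k[i] <- f$k; rn[i] <- f$residual_norm
    interior <- f$d > f$d_bounds[1] * (1 + 1e-8) && f$d < f$d_bounds[2] * (1 - 1e-8) &&
      f$k > f$k_bounds[1] + 1e-8 && f$k < f$k_bounds[2] - 1e-8
    ok[i] <- f$converged && interior
  }
  out <- tibble::tibble(
    voxel_x = roi$voxel_x, voxel_y = roi$voxel_y, voxel_z = roi$voxel_z,
    s0 = s0, d = d, k = k, residual_norm = rn, fit_ok = ok
  )
  attr(out, "roi_label") <- attr(roi, "roi_label")
  out
}

#' Estimate SNR from ROI signal and bladder noise
#'
#' Signal level is the median of S(b) over all voxels and b-values of the
#' listed tissue ROIs; noise level is the SD over bladder voxels of the
#' signal at the maximal b-value, where free-water urine has fully decayed
#' and only the magnitude-noise floor remains.
#'
#' @param roi_matrices List of ROI signal tibbles (H / T / PT).
#' @param bladder Bladder ROI signal tibble.
#' @return Tibble with `snr`, `signal_level`, `noise_level`, `b_noise`.
#' @export
estimate_snr <- function(roi_matrices, bladder) {
  if (inherits(roi_matrices, "data.frame")) roi_matrices <- list(roi_matrices)
  bl <- roi_signal_matrix(bladder)
  if (nrow(bl) == 0) abort("empty bladder ROI", class = "dkclust_empty_roi_error")
  bmax_col <- ncol(bl)
  noise <- sd(bl[, bmax_col])
  if (!is.finite(noise) || noise == 0) {
    abort("bladder signal has zero variance at the maximal b-value",
          class = "dkclust_degenerate_noise_error")
  }
  all_sig <- unlist(lapply(roi_matrices, function(r) as.numeric(roi_signal_matrix(r))))
  sig <- median(all_sig)
  tibble::tibble(snr = sig / noise, signal_level = sig, noise_level = noise,
                 b_noise = max(as.numeric(roi_scheme(bladder))))
}
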