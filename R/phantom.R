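#' Kurtosis signal representation
#'
#' The second-order cumulant expansion of the diffusion-weighted signal,
#' `S(b) = S0 * exp(-b*D + (1/6) * b^2 * D^2 * K)`, where D (mm^2/s) is the
#' apparent diffusivity and K (dimensionless) the apparent kurtosis.
#' Vectorized over any argument.
#'
#' @param s0 Signal at b = 0 (arbitrary units), > 0.
#' @param d Apparent diffusivity, mm^2/s.
#' @param k Apparent kurtosis, dimensionless.
#' @param b Diffusion weighting, s/mm^2, >= 0.
#' @return Signal in the units of `s0`.
#' @examples
#' kurtosis_signal(1000, 1e-3, 0.8, c(0, 500, 2500))
#' @export
kurtosis_signal <- function(s0, d, k, b) {
  if (anyNA(c(s0, d, k, b)) || any(!is.finite(c(s0, d, k, b)))) {
    abort("inputs must be finite", class = "dkclust_validation_error")
  }
  if (any(b < 0)) abort("b must be >= 0", class = "dkclust_validation_error")
  if (any(s0 <= 0)) abort("s0 must be > 0", class = "dkclust_validation_error")
  s0 * exp(-b * d + (1 / 6) * b^2 * d^2 * k)
}

#' Add Rician (magnitude-MRI) noise
#'
#' Each clean value A is replaced by `sqrt((A + n1)^2 + n2^2)` with n1, n2
#' independent zero-mean Gaussians of scale `sigma` — the noise model of a
#' magnitude image reconstructed from complex data. At A = 0 this is Rayleigh
#' noise. Uses the current R random-number state; seed with `set.seed()` or
#' `withr::with_seed()` for reproducibility.
#'
#' @param clean Numeric array of noise-free magnitudes.
#' @param sigma Gaussian noise scale per channel, in signal units, >= 0.
#' @return Array of noisy magnitudes, same shape as `clean`.
#' @export
add_rician_noise <- function(clean, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    abort("sigma must be a single number >= 0", class = "dkclust_validation_error")
  }
  if (sigma == 0) return(clean)
  n <- length(clean)
  noisy <- sqrt((clean + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  if (is.array(clean)) dim(noisy) <- dim(clean)
  noisy
}

#' Diffusion compartment specification
#'
#' One Gaussian-distributed (D, K) compartment inside a tissue. Sampled
#' values are truncated to the kurtosis-fit box (D in \[0.01, 3\]e-3 mm^2/s,
#' K in \[-0.7, 3.7\]) so that recovery tests are not boundary-pinned.
#'
#' @param fraction Proportion of tissue voxels drawn from this compartment.
#' @param d_mean,d_sd Diffusivity mean and SD, mm^2/s.
#' @param k_mean,k_sd Kurtosis mean and SD, dimensionless.
#' @return A list of class `compartment_spec`.
#' @export
compartment_spec <- function(fraction, d_mean, d_sd, k_mean, k_sd) {
  if (fraction < 0 || fraction > 1) {
    abort("fraction must be in [0, 1]", class = "dkclust_validation_error")
  }
  if (d_mean <= 0.01e-3 || d_mean >= 3e-3) {
    abort("d_mean must lie strictly inside (0.01, 3)e-3 mm^2/s",
          class = "dkclust_validation_error")
  }
  if (k_mean <= -0.7 || k_mean >= 3.7) {
    abort("k_mean must lie strictly inside (-0.7, 3.7)", class = "dkclust_validation_error")
  }
  if (d_sd < 0 || k_sd < 0) abort("SDs must be >= 0", class = "dkclust_validation_error")
  structure(list(fraction = fraction, d_mean = d_mean, d_sd = d_sd,
                 k_mean = k_mean, k_sd = k_sd),
            class = "compartment_spec")
}

#' Tissue specification for the phantom
#'
#' @param name One of "H", "T", "PT", "BLADDER".
#' @param compartments List of [compartment_spec()]; fractions must sum to 1.
#' @param s0_mean,s0_sd Baseline signal mean and SD, arbitrary units.
#' @return A list of class `tissue_spec`.
#' @export
tissue_spec <- function(name, compartments, s0_mean = 1000, s0_sd = 50) {
  name <- match.arg(name, c("H", "T", "PT", "BLADDER"))
  fr <- vapply(compartments, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) {
    abort("compartment fractions must sum to 1", class = "dkclust_validation_error")
  }
  structure(list(name = name, compartments = compartments,
                 s0_mean = s0_mean, s0_sd = s0_sd),
            class = "tissue_spec")
}

#' Default tissue parameter set
#'
#' Invented defaults constrained by the qualitative orderings the analysis
#' assumes: one compartment in healthy endometrium, two in tumor and
#' peritumor; higher K and lower D in tumor than healthy tissue; the largest
#' kurtosis dispersion in the peritumoral rim; free-water-like fast diffusion
#' in the bladder so it carries essentially no signal at b = 2500 s/mm^2.
#'
#' @return Named list of [tissue_spec()] objects.
#' @export
default_tissues <- function() {
  list(
    H = tissue_spec("H", list(
      compartment_spec(1, d_mean = 1.4e-3, d_sd = 0.10e-3, k_mean = 0.6, k_sd = 0.08)
    )),
    T = tissue_spec("T", list(
      compartment_spec(0.5, d_mean = 1.0e-3, d_sd = 0.08e-3, k_mean = 0.9, k_sd = 0.10),
      compartment_spec(0.5, d_mean = 0.5e-3, d_sd = 0.06e-3, k_mean = 1.8, k_sd = 0.15)
    )),
    PT = tissue_spec("PT", list(
      compartment_spec(0.5, d_mean = 1.2e-3, d_sd = 0.10e-3, k_mean = 0.9, k_sd = 0.45),
      compartment_spec(0.5, d_mean = 0.7e-3, d_sd = 0.10e-3, k_mean = 1.6, k_sd = 0.45)
    )),
    BLADDER = tissue_spec("BLADDER", list(
      compartment_spec(1, d_mean = 2.9e-3, d_sd = 0.05e-3, k_mean = 0.05, k_sd = 0.03)
    ))
  )
}

#' Default ROI geometry for a voxel grid
#'
#' The endometrial ROI (H in healthy subjects, T in cancer subjects) is an
#' ellipsoid in the left half of the grid; the peritumoral rim is a 2-voxel
#' in-plane ring around T; the bladder is a disjoint ellipsoid on the right.
#' All extents scale with the grid so small demo grids stay proportionate.
#'
#' @param grid_shape Integer triplet (nx, ny, nz).
#' @return Named list of geometry descriptors.
#' @export
default_roi_geometry <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  cz <- (nz + 1) / 2
  lesion <- list(type = "ellipsoid",
                 center = c(0.35 * nx, 0.5 * ny, cz),
                 semiaxes = c(0.11 * nx, 0.095 * ny, max(1.2, 0.25 * nz)))
  list(
    H = lesion,
    T = lesion,
    PT = list(type = "ring", around = "T", width = 2),
    BLADDER = list(type = "ellipsoid",
                   center = c(0.8 * nx, 0.5 * ny, cz),
                   semiaxes = c(0.09 * nx, 0.09 * ny, max(1.2, 0.25 * nz)))
  )
}

#' Phantom cohort configuration
#'
#' @param grid_shape Voxel grid (nx, ny, nz).
#' @param scheme A [bvalue_scheme()].
#' @param tissues Named list of [tissue_spec()]; see [default_tissues()].
#' @param roi_geometry Geometry list; see [default_roi_geometry()].
#' @param noise_sigma Per-channel Gaussian scale of the Rician noise, signal
#'   units. The default 15 puts the healthy-tissue SNR at the highest
#'   b-value near the minimum observed in vivo (about 7).
#' @param n_directions Diffusion directions acquired then averaged (>= 1).
#' @param seed Master seed for subject generation.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 5),
                           scheme = bvalue_scheme(),
                           tissues = default_tissues(),
                           roi_geometry = default_roi_geometry(grid_shape),
                           noise_sigma = 15,
                           n_directions = 3,
                           seed = 1L) {
  if (noise_sigma < 0) abort("noise_sigma must be >= 0", class = "dkclust_validation_error")
  if (n_directions < 1) abort("n_directions must be >= 1", class = "dkclust_validation_error")
  structure(list(grid_shape = as.integer(grid_shape),
                 scheme = if (inherits(scheme, "bvalue_scheme")) scheme else bvalue_scheme(scheme),
                 tissues = tissues, roi_geometry = roi_geometry,
                 noise_sigma = noise_sigma, n_directions = as.integer(n_directions),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Rasterize one geometry entry to an n x 3 matrix of 1-based voxel indices.
rasterize_roi <- function(geom, grid_shape, t_voxels = NULL) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  if (geom$type == "ellipsoid") {
    cc <- geom$center; ss <- geom$semiaxes
    g <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
    inside <- ((g$x - cc[1]) / ss[1])^2 + ((g$y - cc[2]) / ss[2])^2 +
      ((g$z - cc[3]) / ss[3])^2 <= 1
    as.matrix(g[inside, , drop = FALSE])
  } else if (geom$type == "ring") {
    if (is.null(t_voxels) || nrow(t_voxels) == 0) {
      abort("ring geometry needs the enclosed ROI's voxels", class = "dkclust_config_error")
    }
    w <- geom$width
    occupied <- array(FALSE, dim = grid_shape)
    occupied[t_voxels] <- TRUE
    ring <- array(FALSE, dim = grid_shape)
    # in-plane Chebyshev dilation, slice by slice
    for (i in seq_len(nrow(t_voxels))) {
      x <- t_voxels[i, 1]; y <- t_voxels[i, 2]; z <- t_voxels[i, 3]
      xs <- max(1, x - w):min(nx, x + w)
      ys <- max(1, y - w):min(ny, y + w)
      ring[xs, ys, z] <- TRUE
    }
    ring[occupied] <- FALSE
    which(ring, arr.ind = TRUE)
  } else {
    abort(sprintf("unknown ROI geometry type '%s'", geom$type),
          class = "dkclust_config_error")
  }
}

# Truncated-Gaussian draws inside [lo, hi] by rejection.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

D_BOUNDS <- c(0.01e-3, 3e-3)
K_BOUNDS <- c(-0.7, 3.7)

#' Generate one synthetic DWI subject
#'
#' Rasterizes the subject's ROIs (H + bladder for a healthy subject, T + PT +
#' bladder for a cancer subject), samples per-voxel ground-truth (S0, D, K)
#' from the tissue compartment mixtures (truncated to the fit box), evaluates
#' the noise-free kurtosis decay over the b-value scheme, adds independent
#' Rician noise per diffusion direction and averages the directions.
#'
#' @param config A [phantom_config()].
#' @param group "healthy" or "EC".
#' @param seed Integer seed for this subject.
#' @return List with elements `dwi` ([dwi_volume()]), `mask` ([roi_mask()]),
#'   and `truth` (tibble of per-voxel ground truth: 0-based coordinates,
#'   tissue, compartment index, s0, d, k; attribute `group`).
#' @export
generate_subject <- function(config, group = c("healthy", "EC"), seed = 1L) {
  group <- match.arg(group)
  stopifnot(inherits(config, "phantom_config"))
  roi_names <- if (group == "healthy") c("H", "BLADDER") else c("T", "PT", "BLADDER")
  gs <- config$grid_shape
  vox <- list()
  t_vox <- NULL
  for (nm in roi_names) {
    geom <- config$roi_geometry[[nm]]
    if (is.null(geom)) abort(sprintf("no geometry for ROI '%s'", nm),
                             class = "dkclust_config_error")
    vox[[nm]] <- rasterize_roi(geom, gs, t_voxels = t_vox)
    if (nm == "T") t_vox <- vox[[nm]]
  }
  occ <- array(0L, dim = gs)
  legend <- setNames(seq_along(roi_names), roi_names)
  for (nm in roi_names) {
    if (any(occ[vox[[nm]]] != 0L)) {
      abort(sprintf("ROI geometry overlap at '%s'", nm), class = "dkclust_config_error")
    }
    occ[vox[[nm]]] <- legend[[nm]]
  }
  mask <- roi_mask(occ, legend)

  b <- as.numeric(config$scheme)
  nb <- length(b)
  withr::with_seed(seed, {
    truth <- purrr::map_dfr(roi_names, function(nm) {
      v <- vox[[nm]]
      n <- nrow(v)
      spec <- config$tissues[[nm]]
      fr <- vapply(spec$compartments, `[[`, numeric(1), "fraction")
      comp <- sample.int(length(fr), n, replace = TRUE, prob = fr)
      d <- k <- numeric(n)
      for (ci in seq_along(fr)) {
        sel <- comp == ci
        if (!any(sel)) next
        cs <- spec$compartments[[ci]]
        d[sel] <- rtruncnorm(sum(sel), cs$d_mean, cs$d_sd, D_BOUNDS[1], D_BOUNDS[2])
        k[sel] <- rtruncnorm(sum(sel), cs$k_mean, cs$k_sd, K_BOUNDS[1], K_BOUNDS[2])
      }
      s0 <- rtruncnorm(n, spec$s0_mean, spec$s0_sd, 1e-6, Inf)
      tibble::tibble(voxel_x = v[, 1] - 1L, voxel_y = v[, 2] - 1L, voxel_z = v[, 3] - 1L,
                     tissue = nm, compartment = comp, s0 = s0, d = d, k = k)
    })
    # noise-free decays on labelled voxels, background stays zero
    clean <- array(0, dim = c(gs, nb))
    idx1 <- cbind(truth$voxel_x + 1L, truth$voxel_y + 1L, truth$voxel_z + 1L)
    for (j in seq_len(nb)) {
      clean[cbind(idx1, j)] <- kurtosis_signal(truth$s0, truth$d, truth$k, b[j])
    }
    signal <- if (config$noise_sigma > 0) {
      dirs <- lapply(seq_len(config$n_directions), function(i)
        add_rician_noise(clean, config$noise_sigma))
      Reduce(`+`, dirs) / config$n_directions
    } else {
      clean
    }
  })
  attr(truth, "group") <- group
  list(dwi = dwi_volume(signal, config$scheme), mask = mask, truth = truth)
}

# Deterministic per-subject seed below 2^31, derived from the master seed.
derive_seed <- function(master, index, offset = 0L) {
  as.integer((((as.double(master) %% 94906265) * 22695477) +
                index * 1000003 + offset * 7919) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Healthy subjects carry H + bladder ROIs, cancer (EC) subjects T + PT +
#' bladder. Per-subject seeds are derived deterministically from the master
#' seed so subjects are independent and individually reproducible.
#'
#' @param n_healthy,n_ec Subject counts (each >= 0, total >= 2 for a cohort;
#'   a single-subject call is allowed for fixtures).
#' @param config A [phantom_config()].
#' @param seed Master seed; defaults to `config$seed`.
#' @return List of subjects; each has `id`, `group`, `seed`, `dwi`, `mask`,
#'   `truth`.
#' @export
generate_cohort <- function(n_healthy, n_ec, config = phantom_config(),
                            seed = config$seed) {
  if (n_healthy < 0 || n_ec < 0 || n_healthy + n_ec < 1) {
    abort("need at least one subject", class = "dkclust_validation_error")
  }
  groups <- c(rep("healthy", n_healthy), rep("EC", n_ec))
  purrr::imap(groups, function(g, i) {
    s <- derive_seed(seed, i)
    subj <- generate_subject(config, group = g, seed = s)
    c(list(id = sprintf("sub%02d", i), group = g, seed = s), subj)
  })
}

#' Write a generated subject to disk
#'
#' DWI and mask go out as NIfTI with plain-text/JSON sidecars; the ground
#' truth as a CSV and a JSON manifest (seed, group, legend).
#'
#' @param subject An element of [generate_cohort()]'s result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dwi(subject$dwi, file.path(dir, "dwi.nii.gz"), file.path(dir, "dwi.bval"))
  write_mask(subject$mask, file.path(dir, "mask.nii.gz"), file.path(dir, "legend.json"))
  write.csv(subject$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(id = subject$id, group = attr(subject$truth, "group") %||% subject$group,
         seed = subject$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
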