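#' Diffusion-weighting scheme
#'
#' A set of b-values (s/mm^2), one per direction-averaged frame of a DWI
#' acquisition. Values must be strictly increasing and positive. The default
#' is the six-shell endometrial protocol (500, 800, 1000, 1500, 2000,
#' 2500) s/mm^2.
#'
#' @param values Numeric vector of b-values in s/mm^2.
#' @return A numeric vector of class `bvalue_scheme`.
#' @examples
#' bvalue_scheme()
#' bvalue_scheme(c(200, 700, 1400))
#' @export
bvalue_scheme <- function(values = c(500, 800, 1000, 1500, 2000, 2500)) {
  values <- as.numeric(values)
  if (length(values) < 1 || anyNA(values) || any(!is.finite(values))) {
    abort("b-values must be finite and non-missing", class = "dkclust_validation_error")
  }
  if (any(values <= 0)) {
    abort("all b-values must be > 0", class = "dkclust_validation_error")
  }
  if (is.unsorted(values, strictly = TRUE)) {
    abort("b-values must be strictly increasing", class = "dkclust_validation_error")
  }
  structure(values, class = "bvalue_scheme")
}

#' Direction-averaged 4D diffusion-weighted volume
#'
#' @param signal 4D nonnegative array indexed (x, y, z, b).
#' @param scheme A [bvalue_scheme()]; its length must match `dim(signal)[4]`.
#' @param voxel_size Voxel edge lengths in mm, length-3.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, scheme, voxel_size = c(1.17, 1.17, 5)) {
  if (length(dim(signal)) != 4) {
    abort("signal must be a 4D array (x, y, z, b)", class = "dkclust_format_error")
  }
  scheme <- if (inherits(scheme, "bvalue_scheme")) scheme else bvalue_scheme(scheme)
  if (dim(signal)[4] != length(scheme)) {
    abort(
      sprintf("signal has %d frames but scheme has %d b-values",
              dim(signal)[4], length(scheme)),
      class = "dkclust_format_error"
    )
  }
  if (anyNA(signal) || any(!is.finite(signal)) || any(signal < 0)) {
    abort("signal intensities must be finite and >= 0", class = "dkclust_validation_error")
  }
  structure(
    list(signal = signal, scheme = scheme, voxel_size = as.numeric(voxel_size)),
    class = "dwi_volume"
  )
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_volume> %d x %d x %d voxels, %d b-values (%s) s/mm^2\n",
              d[1], d[2], d[3], d[4], paste(as.numeric(x$scheme), collapse = ", ")))
  invisible(x)
}

#' Integer-labelled region-of-interest mask
#'
#' Background is 0; every nonzero label must appear in the legend. The legend
#' maps tissue names onto integer labels, e.g. `c(H = 1, BLADDER = 4)`.
#' Healthy-endometrium (H) labels never co-occur with tumor (T) or peritumor
#' (PT) labels in one subject: healthy subjects carry H, cancer subjects T/PT.
#'
#' @param labels 3D integer array of voxel labels.
#' @param legend Named integer vector, names in {H, T, PT, BLADDER}.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels, legend) {
  if (length(dim(labels)) != 3) {
    abort("labels must be a 3D array", class = "dkclust_format_error")
  }
  legend <- setNames(as.integer(legend), names(legend))
  if (is.null(names(legend)) || any(!nzchar(names(legend)))) {
    abort("legend must be a named integer vector", class = "dkclust_validation_error")
  }
  present <- setdiff(unique(as.integer(labels)), 0L)
  unknown <- setdiff(present, legend)
  if (length(unknown) > 0) {
    abort(sprintf("mask labels not in legend: %s", paste(unknown, collapse = ", ")),
          class = "dkclust_validation_error")
  }
  has <- names(legend)[legend %in% present]
  if ("H" %in% has && any(c("T", "PT") %in% has)) {
    abort("H must not co-occur with T/PT in one subject mask",
          class = "dkclust_validation_error")
  }
  structure(list(labels = labels, legend = legend), class = "roi_mask")
}

#' Read a DWI volume and its b-value sidecar
#'
#' Accepts a 4D NIfTI (already direction-averaged) or a 5D NIfTI whose fifth
#' axis indexes diffusion directions, which are averaged on load. b-values are
#' read from a plain-text sidecar (whitespace- or newline-separated, one value
#' per frame) or from a JSON file with a `bvalues` field. Frames are re-sorted
#' to ascending b if needed.
#'
#' @param image_path Path to a .nii / .nii.gz volume.
#' @param bval_path Path to the b-value sidecar (.bval text or .json).
#' @return A [dwi_volume()].
#' @export
load_dwi <- function(image_path, bval_path) {
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd == 5) {
    arr <- apply(arr, 1:4, mean)
  } else if (nd != 4) {
    abort(sprintf("expected a 4D (or 5D) image, got %dD", nd),
          class = "dkclust_format_error")
  }
  bvals <- read_bvals(bval_path)
  if (length(bvals) != dim(arr)[4]) {
    abort(sprintf("image has %d frames but sidecar lists %d b-values",
                  dim(arr)[4], length(bvals)),
          class = "dkclust_format_error")
  }
  ord <- order(bvals)
  vs <- RNifti::pixdim(img)[1:3]
  dwi_volume(arr[, , , ord, drop = FALSE], bvalue_scheme(bvals[ord]), voxel_size = vs)
}

read_bvals <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    bv <- j[["bvalues"]]
    if (is.null(bv)) abort("JSON sidecar lacks a 'bvalues' field", class = "dkclust_format_error")
    as.numeric(bv)
  } else {
    as.numeric(scan(path, what = numeric(), quiet = TRUE))
  }
}

#' Write a DWI volume as NIfTI plus a b-value sidecar
#'
#' @param dwi A [dwi_volume()].
#' @param image_path Output .nii / .nii.gz path.
#' @param bval_path Output text sidecar path (one b-value per line).
#' @return `image_path`, invisibly.
#' @export
write_dwi <- function(dwi, image_path, bval_path) {
  stopifnot(inherits(dwi, "dwi_volume"))
  img <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(img) <- c(dwi$voxel_size, 1)
  RNifti::writeNifti(img, image_path, datatype = "double")
  writeLines(format(as.numeric(dwi$scheme), trim = TRUE, scientific = FALSE), bval_path)
  invisible(image_path)
}

#' Write an ROI mask as NIfTI plus a JSON legend
#'
#' @param mask A [roi_mask()].
#' @param mask_path Output .nii / .nii.gz path.
#' @param legend_path Output JSON path mapping tissue name to integer label.
#' @return `mask_path`, invisibly.
#' @export
write_mask <- function(mask, mask_path, legend_path) {
  stopifnot(inherits(mask, "roi_mask"))
  RNifti::writeNifti(RNifti::asNifti(mask$labels), mask_path, datatype = "int16")
  jsonlite::write_json(as.list(mask$legend), legend_path, auto_unbox = TRUE)
  invisible(mask_path)
}

#' Read an ROI mask written by [write_mask()]
#'
#' @param mask_path NIfTI label volume.
#' @param legend_path JSON legend.
#' @return A [roi_mask()].
#' @export
load_mask <- function(mask_path, legend_path) {
  img <- RNifti::readNifti(mask_path)
  arr <- array(as.integer(img), dim = dim(img))
  leg <- unlist(jsonlite::read_json(legend_path, simplifyVector = TRUE))
  roi_mask(arr, leg)
}

#' Average per-direction DWI volumes
#'
#' Voxelwise arithmetic mean over a list of volumes sharing shape and scheme,
#' emulating the acquisition protocol's three-direction averaging.
#'
#' @param per_direction List of [dwi_volume()] objects.
#' @return A single averaged [dwi_volume()].
#' @export
average_directions <- function(per_direction) {
  if (length(per_direction) == 0) {
    abort("need at least one volume", class = "dkclust_validation_error")
  }
  ref <- per_direction[[1]]
  for (v in per_direction) {
    if (!identical(dim(v$signal), dim(ref$signal)) ||
        !isTRUE(all.equal(as.numeric(v$scheme), as.numeric(ref$scheme)))) {
      abort("volumes must share shape and b-value scheme", class = "dkclust_validation_error")
    }
  }
  avg <- Reduce(`+`, lapply(per_direction, `[[`, "signal")) / length(per_direction)
  dwi_volume(avg, ref$scheme, ref$voxel_size)
}

#' Extract per-voxel signal decays under one ROI label
#'
#' Returns one row per mask voxel carrying that tissue label, in a
#' deterministic scan order (rows sorted by ascending voxel_x, then voxel_y,
#' then voxel_z; coordinates are 0-based). Signal columns are named after the
#' b-values (`b500`, ..., `b2500`).
#'
#' @param dwi A [dwi_volume()].
#' @param mask A [roi_mask()] with the same spatial shape.
#' @param label Tissue name present in the mask legend ("H", "T", "PT",
#'   "BLADDER").
#' @return A tibble with columns `voxel_x`, `voxel_y`, `voxel_z` and one
#'   signal column per b-value; attributes `scheme` and `roi_label`.
#' @export
extract_roi_signals <- function(dwi, mask, label) {
  stopifnot(inherits(dwi, "dwi_volume"), inherits(mask, "roi_mask"))
  if (!label %in% names(mask$legend)) {
    abort(sprintf("label '%s' not in mask legend", label), class = "dkclust_lookup_error")
  }
  if (!identical(dim(mask$labels), dim(dwi$signal)[1:3])) {
    abort("mask and volume spatial shapes differ", class = "dkclust_format_error")
  }
  idx <- which(mask$labels == mask$legend[[label]], arr.ind = TRUE)
  if (nrow(idx) == 0) {
    abort(sprintf("ROI '%s' contains no voxels", label), class = "dkclust_empty_roi_error")
  }
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  nb <- length(dwi$scheme)
  sig <- matrix(NA_real_, nrow(idx), nb)
  for (j in seq_len(nb)) {
    sig[, j] <- dwi$signal[cbind(idx, j)]
  }
  colnames(sig) <- paste0("b", as.numeric(dwi$scheme))
  out <- tibble::as_tibble(cbind(
    tibble::tibble(voxel_x = idx[, 1] - 1L, voxel_y = idx[, 2] - 1L, voxel_z = idx[, 3] - 1L),
    tibble::as_tibble(sig)
  ))
  attr(out, "scheme") <- dwi$scheme
  attr(out, "roi_label") <- label
  out
}

# Pull the n_voxels x n_b signal matrix back out of an ROI tibble.
roi_signal_matrix <- function(roi) {
  as.matrix(roi[, grep("^b[0-9]+$", names(roi)), drop = FALSE])
}

roi_scheme <- function(roi) {
  sc <- attr(roi, "scheme")
  if (is.null(sc)) {
    sc <- bvalue_scheme(as.numeric(sub("^b", "", grep("^b[0-9]+$", names(roi), value = TRUE))))
  }
  sc
}
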