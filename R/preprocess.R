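# Minimal preprocessing: isotropic Gaussian smoothing, cohort brain mask,
# and per-voxel standardisation before ICA.

gaussian_kernel_matrix <- function(n, sigma) {
  # n x n convolution matrix for a truncated (zero-padded) Gaussian kernel
  if (sigma <= 0) return(diag(n))
  radius <- ceiling(4 * sigma)
  w <- exp(-(-radius:radius)^2 / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - radius):(i + radius)
    keep <- j >= 1 & j <= n
    K[i, j[keep]] <- w[keep]
  }
  K
}

# separable truncated-Gaussian smoothing of a 3D array, sigma in voxels
smooth_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  Ks <- lapply(1:3, function(a) gaussian_kernel_matrix(d[a], sigma_vox[a]))
  # axis 1
  m <- matrix(arr, d[1], d[2] * d[3])
  m <- Ks[[1]] %*% m
  arr <- array(m, d)
  # axis 2
  arr <- aperm(arr, c(2, 1, 3))
  m <- matrix(arr, d[2], d[1] * d[3])
  m <- Ks[[2]] %*% m
  arr <- aperm(array(m, d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  arr <- aperm(arr, c(3, 1, 2))
  m <- matrix(arr, d[3], d[1] * d[2])
  m <- Ks[[3]] %*% m
  aperm(array(m, d[c(3, 1, 2)]), c(2, 3, 1))
}

#' Spatially smooth a 4D volume with an isotropic Gaussian kernel
#'
#' Each 3D frame is convolved with a Gaussian of full width at half maximum
#' `fwhm_mm`, converted per axis to voxel units (sd = fwhm / (2 sqrt(2 ln 2))
#' / voxel size). The kernel is truncated at the volume edges (zero padding,
#' no wraparound), matching physical brain boundaries. `fwhm_mm = 0` is the
#' identity.
#'
#' @param v A [volume4d()].
#' @param fwhm_mm Kernel FWHM in millimetres (>= 0).
#' @return A smoothed [volume4d()].
#' @export
gaussian_smooth <- function(v, fwhm_mm) {
  stopifnot(inherits(v, "volume4d"))
  if (fwhm_mm < 0) stop_fn("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(v)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / v$voxel_size_mm
  d <- dim(v$data)
  out <- v$data
  for (t in seq_len(d[4]))
    out[, , , t] <- smooth_3d(v$data[, , , t], sigma_vox)
  volume4d(out, v$voxel_size_mm, v$TR, v$affine)
}

#' Compute a cohort brain mask from mean absolute signal
#'
#' A voxel enters the mask when its mean absolute signal across all runs and
#' timepoints exceeds `fraction` of the global mean absolute signal.
#'
#' @param cohort List of [volume4d()] runs on a common grid.
#' @param fraction Inclusion threshold as a fraction of the global mean
#'   (default 0.1).
#' @return Logical 3D array (the brain mask).
#' @export
compute_mask <- function(cohort, fraction = 0.1) {
  if (length(cohort) < 1) stop_fn("need at least one run")
  d <- dim(cohort[[1]]$data)[1:3]
  acc <- array(0, d)
  n <- 0
  for (v in cohort) {
    if (!identical(dim(v$data)[1:3], d))
      stop_fn("runs are on different grids", class = "fnoverlap_validation")
    acc <- acc + apply(abs(v$data), 1:3, mean)
    n <- n + 1
  }
  meanabs <- acc / n
  mask <- meanabs > fraction * mean(meanabs)
  if (!any(mask))
    stop_fn("empty brain mask; lower the mask fraction",
            class = "fnoverlap_validation")
  mask
}

#' Standardise in-mask voxel time series
#'
#' Extracts the in-mask voxels in fixed scan order (x fastest) as a
#' timepoints x voxels matrix, demeans each voxel, and (by default) scales
#' each to unit variance. Zero-variance voxels are set to all-zero columns
#' and reported via a warning.
#'
#' @param v A [volume4d()].
#' @param mask Logical 3D array.
#' @param variance_normalize Scale each voxel to unit sd (default TRUE).
#' @return Matrix (timepoints x in-mask voxels) with attributes `means`,
#'   `sds` and `mask` for exact inversion via [unstandardize()].
#' @export
standardize <- function(v, mask, variance_normalize = TRUE) {
  if (!any(mask)) stop_fn("mask is empty", class = "fnoverlap_validation")
  d <- dim(v$data)
  X <- t(matrix(v$data, prod(d[1:3]), d[4])[as.vector(mask), , drop = FALSE])
  mu <- colMeans(X)
  X <- sweep(X, 2, mu)
  sds <- apply(X, 2, stats::sd)
  if (variance_normalize) {
    zero <- sds == 0
    if (any(zero)) {
      warning(sum(zero), " zero-variance voxel(s) set to zero")
      sds[zero] <- 1
      X[, zero] <- 0
    }
    X <- sweep(X, 2, sds, "/")
  }
  attr(X, "means") <- mu
  attr(X, "sds") <- sds
  attr(X, "mask") <- mask
  attr(X, "variance_normalized") <- variance_normalize
  X
}

#' Invert [standardize()] using its stored means and scales
#' @param X Matrix returned by [standardize()].
#' @return Matrix on the original scale.
#' @export
unstandardize <- function(X) {
  mu <- attr(X, "means"); sds <- attr(X, "sds")
  out <- X
  if (isTRUE(attr(X, "variance_normalized")))
    out <- sweep(out, 2, sds, "*")
  sweep(out, 2, mu, "+")
}

#' Embed an in-mask voxel vector back into a 3D array
#' @param values Vector of in-mask voxel values (mask scan order, x fastest).
#' @param mask Logical 3D array.
#' @param fill Value outside the mask (default 0).
#' @return 3D array.
#' @export
unmask <- function(values, mask, fill = 0) {
  out <- array(fill, dim(mask))
  out[mask] <- values
  out
}
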