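# Array primitives shared across modules: separable Gaussian smoothing,
# binary morphology by axis-wise min-filters, and seeded RNG derivation.

#' Convert a Gaussian FWHM in mm to a kernel standard deviation in voxels
#'
#' @param fwhm Full width at half maximum, mm.
#' @param voxel_size Voxel edge length, mm.
#' @return Standard deviation in voxel units, `fwhm / (voxel_size * 2 sqrt(2 ln 2))`.
#' @export
fwhm_to_sigma <- function(fwhm, voxel_size) {
  fwhm / (voxel_size * 2 * sqrt(2 * log(2)))
}

# Dense banded Gaussian kernel matrix with row renormalisation so that a
# constant image is preserved exactly (boundary rows re-weight the truncated
# kernel). Truncation at 6 sigma keeps lost mass < 1e-8.
.gaussian_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  radius <- max(1L, ceiling(6 * sigma))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- ifelse(d <= radius, exp(-d^2 / (2 * sigma^2)), 0)
  K / rowSums(K)
}

# Multiply a kernel matrix into one axis of an n-d array.
.apply_axis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  a <- array(K %*% matrix(a, nrow = d[axis]), dim = d[perm])
  aperm(a, order(perm))
}

#' Smooth an image volume or 4D series with an isotropic Gaussian kernel
#'
#' Smoothing is separable: a 1D Gaussian (truncated at 6 sigma, boundary
#' renormalised) is applied along each of the three spatial axes. For a 4D
#' series each frame is smoothed independently; no temporal smoothing occurs.
#'
#' @param series 3D volume or 4D (X, Y, Z, T) array.
#' @param fwhm Kernel full width at half maximum, mm. `0` is the identity.
#' @param voxel_size Voxel edge length, mm (isotropic).
#' @return Array of the same shape.
#' @examples
#' v <- array(rnorm(8^3), c(8, 8, 8))
#' s <- smooth_gaussian(v, fwhm = 3, voxel_size = 2)
#' @export
smooth_gaussian <- function(series, fwhm, voxel_size) {
  stopifnot(fwhm >= 0, voxel_size > 0)
  d <- dim(series)
  if (!length(d) %in% c(3L, 4L)) abort("`series` must be a 3D or 4D array")
  if (fwhm == 0) return(series)
  sigma <- fwhm_to_sigma(fwhm, voxel_size)
  out <- series
  for (axis in 1:3) {
    out <- .apply_axis(out, .gaussian_kernel_matrix(d[axis], sigma), axis)
  }
  out
}

# One pass of a length-3 binary min-filter (erosion by a 3-voxel line) along
# `axis`, with FALSE padding outside the array. Erosion by a 3^k box is the
# composition of line erosions along each axis.
.erode_axis <- function(mask, axis) {
  n <- dim(mask)[axis]
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- (d <= 1) * 1
  counts <- .apply_axis(array(as.numeric(mask), dim(mask)), K, axis)
  counts > 3 - 1e-9
}

.erode_box <- function(mask, width, axes) {
  out <- mask
  if (width == 0) return(out)
  for (i in seq_len(width)) {
    for (axis in axes) out <- .erode_axis(out, axis)
  }
  out
}

#' Erode a binary mask slice-by-slice in the axial plane
#'
#' Each axial (X-Y) slice is eroded independently with a 3x3 square
#' structuring element, applied `width` times; voxels outside the array are
#' treated as background, so the mask shrinks at the volume border too.
#'
#' @param mask Logical 3D array.
#' @param width Number of erosion passes (voxels).
#' @return Logical 3D array.
#' @export
erode_mask_2d <- function(mask, width = 2L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, width >= 0)
  .erode_box(mask, width, axes = 1:2)
}

#' Erode a binary mask in 3D
#'
#' Full 3D erosion with a 3x3x3 box structuring element applied `width` times.
#'
#' @inheritParams erode_mask_2d
#' @return Logical 3D array.
#' @export
erode_mask_3d <- function(mask, width = 2L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, width >= 0)
  .erode_box(mask, width, axes = 1:3)
}

# Deterministic per-stage seed derivation from one root seed; keeps values
# inside the 32-bit integer range.
.derive_seed <- function(seed, stage, index = 0L) {
  stage_code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + stage_code * 1009 + index) %%
    2147483647)
}

# Default RAS affine for a volume centred on the world origin.
.default_affine <- function(dim3, voxel_size) {
  A <- diag(4)
  A[1:3, 1:3] <- diag(rep(voxel_size, 3))
  A[1:3, 4] <- -voxel_size * (dim3 - 1) / 2
  A
}

# World coordinates (requested orientation) of 1-based voxel indices.
.voxel_to_world <- function(ijk, affine, orientation = c("LPS", "RAS")) {
  orientation <- match.arg(orientation)
  ijk <- matrix(ijk, ncol = 3)
  xyz <- t(affine %*% rbind(t(ijk) - 1, 1))[, 1:3, drop = FALSE]
  if (orientation == "LPS") xyz[, 1:2] <- -xyz[, 1:2]
  colnames(xyz) <- c("x", "y", "z")
  xyz
}
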