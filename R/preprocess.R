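#' Min-max normalize a volume to [0, 1]
#'
#' Each voxel is mapped to `(v - min) / (max - min)` so the dimmest voxel
#' becomes 0 and the brightest becomes 1 — the per-channel normalization
#' that opens the quantification pipeline. A constant volume (e.g. a
#' blank EdU-negative channel) maps to all zeros rather than erroring, so
#' blank channels flow through the pipeline and yield an empty mask.
#'
#' @param volume 3D numeric array with finite values.
#' @return 3D array with values in `[0, 1]`.
#' @export
normalize_stack <- function(volume) {
  check_volume(volume)
  rng <- range(volume)
  if (rng[1L] == rng[2L]) return(array(0, dim = dim(volume)))
  (volume - rng[1L]) / (rng[2L] - rng[1L])
}

check_volume <- function(volume, arg = "volume") {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("`", arg, "` must be a 3D array (z, y, x)")
  if (length(volume) == 0L) stop("`", arg, "` is empty")
  if (any(!is.finite(volume))) stop("`", arg, "` contains non-finite values")
  invisible(TRUE)
}

#' 3D median filter
#'
#' Replaces each voxel by the median of its `window^3` cube neighborhood.
#' The default window of 3 is the standard 3x3x3 neighborhood. Borders
#' use symmetric (edge-mirrored) padding so the volume rim is not
#' artificially darkened before thresholding.
#'
#' @param volume 3D numeric array.
#' @param window odd positive integer edge length of the cube
#'   neighborhood.
#' @return filtered 3D array of the same dimensions.
#' @export
median_filter_3d <- function(volume, window = 3L) {
  check_volume(volume)
  window <- as.integer(window)
  if (length(window) != 1L || window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd positive integer")
  out <- cpp_median3d(as.numeric(volume), dim(volume), window)
  array(out, dim = dim(volume))
}

gaussian_kernel_1d <- function(kernel_size, sigma) {
  r <- (kernel_size - 1L) / 2L
  k <- exp(-(seq(-r, r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' 3D Gaussian filter
#'
#' Separable convolution with a 1D Gaussian truncated to `kernel_size`
#' taps per axis and renormalized to sum 1 (so constant volumes are
#' preserved). The 5x5x5 default kernel matches the pipeline definition;
#' sigma defaults to 0.5 voxels. Borders use symmetric padding.
#'
#' @param volume 3D numeric array.
#' @param kernel_size odd positive integer taps per axis.
#' @param sigma positive Gaussian standard deviation in voxels.
#' @return filtered 3D array of the same dimensions.
#' @export
gaussian_filter_3d <- function(volume, kernel_size = 5L, sigma = 0.5) {
  check_volume(volume)
  kernel_size <- as.integer(kernel_size)
  if (length(kernel_size) != 1L || kernel_size < 1L ||
      kernel_size %% 2L == 0L)
    stop("`kernel_size` must be an odd positive integer")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single positive number")
  k <- gaussian_kernel_1d(kernel_size, sigma)
  out <- cpp_gauss3d(as.numeric(volume), dim(volume), k)
  array(out, dim = dim(volume))
}
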