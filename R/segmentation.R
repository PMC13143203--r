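#' Per-channel segmentation parameters
#'
#' Bundles the pipeline constants for one channel. The Otsu scale factor
#' defaults to the published values: 0.5 for a nuclear (DAPI) channel and
#' 0.2 for a proliferation (EdU) channel — the same factors are applied to
#' every stack to keep segmentation consistent. Remaining defaults are
#' the pipeline's processing constants: 3x3x3 median window, 5-tap
#' Gaussian with sigma 0.5, erosion ball radius 3, reconstruction
#' connectivity 26.
#'
#' @param role `"nuclear"`, `"proliferation"` or `"other"`; selects the
#'   default `otsu_factor`.
#' @param otsu_factor multiplier in `(0, 1]` applied to the Otsu level
#'   before binarization.
#' @param median_window,gaussian_kernel odd positive filter sizes.
#' @param gaussian_sigma positive Gaussian sigma in voxels.
#' @param erosion_radius non-negative ball radius in voxels.
#' @param connectivity reconstruction neighborhood (6, 18 or 26).
#' @param threshold_source volume the Otsu level is computed on and the
#'   binarization applied to: `"reconstructed"` (default) or
#'   `"filtered"`.
#' @return An object of class `ChannelParams`.
#' @export
channel_params <- function(role = c("nuclear", "proliferation", "other"),
                           otsu_factor = NULL,
                           median_window = 3L,
                           gaussian_kernel = 5L,
                           gaussian_sigma = 0.5,
                           erosion_radius = 3L,
                           connectivity = 26L,
                           threshold_source = c("reconstructed",
                                                "filtered")) {
  role <- match.arg(role)
  threshold_source <- match.arg(threshold_source)
  if (is.null(otsu_factor))
    otsu_factor <- switch(role, nuclear = 0.5, proliferation = 0.2,
                          other = 0.5)
  otsu_factor <- as.numeric(otsu_factor)
  if (length(otsu_factor) != 1L || !is.finite(otsu_factor) ||
      otsu_factor <= 0 || otsu_factor > 1)
    stop("`otsu_factor` must lie in (0, 1]")
  stopifnot(median_window >= 1L, median_window %% 2L == 1L,
            gaussian_kernel >= 1L, gaussian_kernel %% 2L == 1L,
            gaussian_sigma > 0, erosion_radius >= 0L,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(role = role, otsu_factor = otsu_factor,
                 median_window = as.integer(median_window),
                 gaussian_kernel = as.integer(gaussian_kernel),
                 gaussian_sigma = as.numeric(gaussian_sigma),
                 erosion_radius = as.integer(erosion_radius),
                 connectivity = as.integer(connectivity),
                 threshold_source = threshold_source),
            class = "ChannelParams")
}

#' Otsu threshold level over a 256-bin histogram
#'
#' Values in `[0, 1]` are histogrammed into `bins` equal-width bins and
#' the cut maximizing the between-class variance is selected by
#' exhaustive search over all `bins - 1` boundaries. When several cuts
#' tie (to within double rounding), the mean of the tying boundaries is
#' returned, which makes the result deterministic and symmetric. A
#' constant volume returns level 0.
#'
#' @param volume 3D numeric array with values in `[0, 1]`.
#' @param bins number of histogram bins.
#' @return threshold level in `[0, 1)`.
#' @export
otsu_threshold <- function(volume, bins = 256L) {
  check_volume(volume)
  if (any(volume < 0 | volume > 1)) stop("values must lie within [0, 1]")
  bins <- as.integer(bins)
  stopifnot(bins >= 2L)
  if (min(volume) == max(volume)) return(0)
  idx <- pmin(floor(as.numeric(volume) * bins), bins - 1L)  # bin 0..bins-1
  counts <- as.numeric(tabulate(idx + 1L, nbins = bins))
  n <- sum(counts)
  mids <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(counts)[-bins]                 # class {bins < k}, k = 1..bins-1
  s0 <- cumsum(counts * mids)[-bins]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (sum(counts * mids) - s0) / w1, 0)
  sb <- ifelse(w0 > 0 & w1 > 0, w0 * w1 * (mu0 - mu1)^2, -Inf)
  best <- max(sb)
  ties <- which(sb >= best - 1e-12 * abs(best))
  mean(ties) / bins                           # boundary k/bins, averaged
}

#' Binarize a volume at a scaled threshold
#'
#' A voxel is labeled `TRUE` iff its value is strictly greater than
#' `otsu_level * factor` — the "modified Otsu" rule with a channel-
#' specific scale factor.
#'
#' @param volume 3D numeric array with values in `[0, 1]`.
#' @param otsu_level level from [otsu_threshold()].
#' @param factor channel scale factor in `(0, 1]`.
#' @return 3D logical array.
#' @export
binarize <- function(volume, otsu_level, factor) {
  check_volume(volume)
  if (any(volume < 0 | volume > 1)) stop("values must lie within [0, 1]")
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 ||
      factor > 1)
    stop("`factor` must lie in (0, 1]")
  volume > otsu_level * factor
}

#' Segment one channel of a stack
#'
#' Runs the full per-channel chain: min-max normalization, 3D median
#' filter, 3D Gaussian filter, erosion by a ball to form the marker,
#' morphological reconstruction of the filtered volume under that marker,
#' Otsu threshold on the reconstructed volume (or the filtered volume,
#' per `threshold_source`), and binarization at the factor-scaled level.
#' Channels are processed independently, so segmenting one channel never
#' depends on any other.
#'
#' @param stack a [volume_stack()].
#' @param channel channel name.
#' @param params a [channel_params()].
#' @return An object of class `ChannelSegmentation`: `mask` (3D logical),
#'   `otsu_level`, `effective_threshold` (`otsu_level * factor`),
#'   `params`, `channel`.
#' @export
segment_channel <- function(stack, channel, params = channel_params()) {
  stopifnot(inherits(stack, "VolumeStack"),
            inherits(params, "ChannelParams"))
  vol <- get_channel(stack, channel)
  norm <- normalize_stack(vol)
  filt <- median_filter_3d(norm, params$median_window)
  filt <- gaussian_filter_3d(filt, params$gaussian_kernel,
                             params$gaussian_sigma)
  marker <- erode_3d(filt, ball_element(params$erosion_radius))
  recon <- reconstruct_by_dilation(marker, filt, params$connectivity)
  source_vol <- if (params$threshold_source == "reconstructed") recon
                else filt
  # rounding in the separable convolution can leave values a few ulp
  # outside [0,1]; clamp before histogramming
  source_vol[source_vol < 0] <- 0
  source_vol[source_vol > 1] <- 1
  level <- otsu_threshold(source_vol)
  mask <- binarize(source_vol, level, params$otsu_factor)
  structure(list(mask = mask, otsu_level = level,
                 effective_threshold = level * params$otsu_factor,
                 params = params, channel = channel),
            class = "ChannelSegmentation")
}

#' @export
print.ChannelSegmentation <- function(x, ...) {
  cat(sprintf(
    "ChannelSegmentation '%s': %d / %d voxels positive\n  otsu level %.4f x factor %.2f -> threshold %.4f\n",
    x$channel, sum(x$mask), length(x$mask), x$otsu_level,
    x$params$otsu_factor, x$effective_threshold))
  invisible(x)
}
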