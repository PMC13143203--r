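#' EdU-positive to DAPI-positive voxel ratio
#'
#' The pipeline's proliferation readout: the number of `TRUE` voxels in
#' the EdU segmentation divided by the number of `TRUE` voxels in the
#' DAPI segmentation. Because tightly clustered nuclei cannot be
#' reliably separated, the ratio is a volume ratio — total EdU-labeled
#' nuclear volume over total nuclear volume — not a cell-count ratio.
#' No containment of EdU voxels within DAPI voxels is imposed.
#'
#' @param edu_mask,dapi_mask 3D logical arrays of identical dimensions;
#'   `dapi_mask` must contain at least one `TRUE` voxel.
#' @return non-negative ratio.
#' @export
edu_dapi_ratio <- function(edu_mask, dapi_mask) {
  if (!is.logical(edu_mask) || !is.logical(dapi_mask))
    stop("masks must be logical arrays")
  if (!identical(dim(edu_mask), dim(dapi_mask)))
    stop("mask dimensions differ")
  n_dapi <- sum(dapi_mask)
  if (n_dapi == 0L)
    stop("DAPI mask is empty; the ratio is undefined")
  sum(edu_mask) / n_dapi
}

#' Quantify proliferation in one organoid stack
#'
#' Segments the nuclear and proliferation channels independently with
#' [segment_channel()] and reports the EdU+/DAPI+ voxel ratio together
#' with voxel tallies and the full parameter snapshot (one stack = one
#' organoid; crop multi-organoid fields first).
#'
#' @param stack a [volume_stack()] with the two channels.
#' @param dapi,edu channel names.
#' @param dapi_params,edu_params [channel_params()] for each channel.
#' @param organoid_id identifier recorded in the report row.
#' @return one-row data frame: `organoid_id`, `edu_positive_voxels`,
#'   `dapi_positive_voxels`, `edu_dapi_ratio`, per-channel Otsu levels,
#'   factors and filter parameters, and `source`.
#' @export
quantify_stack <- function(stack, dapi = "DAPI", edu = "EdU",
                           dapi_params = channel_params("nuclear"),
                           edu_params = channel_params("proliferation"),
                           organoid_id = "organoid") {
  seg_d <- segment_channel(stack, dapi, dapi_params)
  seg_e <- segment_channel(stack, edu, edu_params)
  data.frame(
    organoid_id = organoid_id,
    edu_positive_voxels = sum(seg_e$mask),
    dapi_positive_voxels = sum(seg_d$mask),
    edu_dapi_ratio = edu_dapi_ratio(seg_e$mask, seg_d$mask),
    dapi_otsu_level = seg_d$otsu_level,
    edu_otsu_level = seg_e$otsu_level,
    dapi_factor = dapi_params$otsu_factor,
    edu_factor = edu_params$otsu_factor,
    median_window = dapi_params$median_window,
    gaussian_kernel = dapi_params$gaussian_kernel,
    gaussian_sigma = dapi_params$gaussian_sigma,
    erosion_radius = dapi_params$erosion_radius,
    connectivity = dapi_params$connectivity,
    threshold_source = dapi_params$threshold_source,
    source = stack$source,
    stringsAsFactors = FALSE)
}

#' Maximum intensity projection of one channel
#'
#' @param stack a [volume_stack()].
#' @param channel channel name.
#' @return 2D matrix `(y, x)` of per-pixel maxima over z.
#' @export
max_projection <- function(stack, channel) {
  vol <- get_channel(stack, channel)
  apply(vol, c(2L, 3L), max)
}

#' Area of a polygon ROI in square microns
#'
#' Shoelace area of the vertex polygon in pixel^2, divided by the squared
#' pixels-per-micron scale — the taste-bud profile area measurement for
#' outlines drawn on maximum projections.
#'
#' @param roi a [polygon_roi()].
#' @return area in um^2.
#' @export
polygon_area <- function(roi) {
  stopifnot(inherits(roi, "PolygonROI"))
  v <- roi$vertices
  n <- nrow(v)
  j <- c(2:n, 1L)
  px2 <- abs(sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L])) / 2
  px2 / roi$scale_px_per_um^2
}

#' Categorize per-organoid marker-positive cell counts
#'
#' Fractions of organoids containing 0, 1-9 or >= 10 immunopositive
#' cells, the categorization used for scoring taste-cell differentiation
#' across treatment conditions.
#'
#' @param counts vector of non-negative integer cell counts, one per
#'   organoid.
#' @return named numeric vector with fractions `"0"`, `"1-9"`, `">=10"`,
#'   summing to 1.
#' @export
categorize_marker_counts <- function(counts) {
  if (length(counts) == 0L) stop("`counts` is empty")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("`counts` must be non-negative integers")
  n <- length(counts)
  c("0" = sum(counts == 0) / n,
    "1-9" = sum(counts >= 1 & counts <= 9) / n,
    ">=10" = sum(counts >= 10) / n)
}

#' Per-mouse means and per-condition summary
#'
#' The mouse is the experimental unit: each mouse's unit counts (taste
#' bud profiles or organoids) are averaged first, then each condition is
#' summarized as mean +/- s.e.m. over its mouse means (sample sd over
#' sqrt of the number of mice; `NA` when a condition has a single mouse).
#'
#' @param table data frame with columns `mouse_id`, `condition`, `count`
#'   (one row per counted unit).
#' @return list with `mouse_means` (mouse_id, condition, mean_count,
#'   n_units) and `condition_summary` (condition, mean, sem, n_mice).
#' @export
per_mouse_average <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("mouse_id", "condition", "count") %in% names(table)))
  if (nrow(table) == 0L) stop("`table` is empty")
  mm <- stats::aggregate(count ~ mouse_id + condition, data = table,
                  FUN = mean)
  nu <- stats::aggregate(count ~ mouse_id + condition, data = table,
                  FUN = length)
  mouse_means <- data.frame(mouse_id = mm$mouse_id,
                            condition = mm$condition,
                            mean_count = mm$count,
                            n_units = nu$count,
                            stringsAsFactors = FALSE)
  cs <- split(mouse_means$mean_count, mouse_means$condition)
  condition_summary <- data.frame(
    condition = names(cs),
    mean = vapply(cs, mean, numeric(1)),
    sem = vapply(cs, function(x)
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_,
      numeric(1)),
    n_mice = vapply(cs, length, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(mouse_means = mouse_means, condition_summary = condition_summary)
}
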