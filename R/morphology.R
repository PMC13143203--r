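#' Discrete ball (sphere-shaped) structuring element
#'
#' The flat structuring element used for the pipeline's erosion step: all
#' integer voxel offsets `(dz, dy, dx)` with
#' `dz^2 + dy^2 + dx^2 <= radius^2`. Radius 0 is the origin alone;
#' radius 3 — the pipeline default — contains 123 voxels.
#'
#' @param radius non-negative integer radius in voxels.
#' @return An object of class `StructuringElement` with an integer offset
#'   matrix (`offsets`, columns dz/dy/dx) and the radius.
#' @export
ball_element <- function(radius) {
  radius <- as.integer(radius)
  if (length(radius) != 1L || is.na(radius) || radius < 0L)
    stop("`radius` must be a non-negative integer")
  g <- as.matrix(expand.grid(dz = -radius:radius, dy = -radius:radius,
                             dx = -radius:radius))
  keep <- rowSums(g^2) <= radius^2
  structure(list(offsets = g[keep, , drop = FALSE], radius = radius),
            class = "StructuringElement")
}

#' @export
print.StructuringElement <- function(x, ...) {
  cat(sprintf("StructuringElement: ball, radius %d, %d voxel offsets\n",
              x$radius, nrow(x$offsets)))
  invisible(x)
}

#' Flat grayscale erosion of a 3D volume
#'
#' Each voxel becomes the minimum of the volume over the structuring
#' element's offsets. Offsets falling outside the volume are ignored
#' (treated as +Inf), the standard flat-erosion convention on a finite
#' domain, so borders are not artificially darkened. Because the element
#' contains the origin the output is pointwise <= the input.
#'
#' @param volume 3D numeric array.
#' @param se a [ball_element()] (or any `StructuringElement` containing
#'   the origin).
#' @return eroded 3D array of the same dimensions.
#' @export
erode_3d <- function(volume, se) {
  check_volume(volume)
  if (!inherits(se, "StructuringElement") || nrow(se$offsets) == 0L)
    stop("`se` must be a non-empty StructuringElement")
  offsets <- se$offsets
  storage.mode(offsets) <- "integer"
  out <- cpp_erode3d(as.numeric(volume), dim(volume), offsets)
  array(out, dim = dim(volume))
}

#' Grayscale morphological reconstruction by dilation
#'
#' Iterates conditional dilation — dilate the marker by the connectivity
#' neighborhood, then take the pointwise minimum with the mask — to its
#' fixed point. With the eroded volume as marker and the filtered volume
#' as mask, this is the pipeline's contrast-enhancement step (opening by
#' reconstruction): peaks too small to contain the structuring element
#' are flattened while larger structures are restored exactly.
#'
#' @param marker 3D numeric array, pointwise `<=` `mask`. A marker
#'   exceeding the mask anywhere is clipped to the mask with a warning.
#' @param mask 3D numeric array of the same dimensions.
#' @param connectivity 3D neighborhood: 6 (faces), 18 (faces+edges) or 26
#'   (full cube, the default).
#' @return the reconstructed 3D array; satisfies
#'   `marker <= result <= mask`.
#' @export
reconstruct_by_dilation <- function(marker, mask, connectivity = 26L) {
  check_volume(marker, "marker")
  check_volume(mask, "mask")
  if (!identical(dim(marker), dim(mask)))
    stop("`marker` and `mask` dimensions differ")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  if (any(marker > mask)) {
    warning("marker exceeds mask; clipping marker to mask")
    marker <- pmin(marker, mask)
  }
  out <- cpp_reconstruct3d(as.numeric(marker), as.numeric(mask),
                           dim(marker), connectivity)
  array(out, dim = dim(marker))
}
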