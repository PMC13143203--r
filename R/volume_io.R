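#' Construct a multichannel volume stack
#'
#' A `VolumeStack` holds a 4D intensity array indexed
#' `(channel, z, y, x)` together with ordered channel names and optional
#' voxel-size metadata. It is the substrate of the quantification
#' pipeline: confocal z-stacks of organoids with (typically) a DAPI
#' nuclear channel and an EdU proliferation channel.
#'
#' @param data 4D numeric array, `dim = c(channels, z, y, x)`, finite and
#'   non-negative. Integer intensities are kept as loaded; no implicit
#'   8-bit rescaling happens before [normalize_stack()].
#' @param channel_names character vector of unique names, one per channel.
#' @param voxel_size_um optional numeric `(z, y, x)` voxel size in microns
#'   (e.g. 2 um optical sections); `NULL` when unknown.
#' @param source provenance string (file path or generator description).
#' @return An object of class `VolumeStack`.
#' @seealso [read_stack()], [get_channel()], [segment_channel()]
#' @export
volume_stack <- function(data, channel_names, voxel_size_um = NULL,
                         source = "") {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (channel, z, y, x)")
  if (any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and >= 0")
  if (any(dim(data)[2:4] < 1L)) stop("each spatial dimension must be >= 1")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(data)[1L])
    stop("channel_names length must equal the channel count")
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (!is.null(voxel_size_um)) {
    voxel_size_um <- as.numeric(voxel_size_um)
    stopifnot(length(voxel_size_um) == 3L, all(voxel_size_um > 0))
  }
  structure(
    list(data = data, channel_names = channel_names,
         voxel_size_um = voxel_size_um, source = as.character(source)[1L]),
    class = "VolumeStack")
}

#' @export
print.VolumeStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("VolumeStack: %d channel(s) [%s], %d x %d x %d (z,y,x)\n",
              d[1L], paste(x$channel_names, collapse = ", "),
              d[2L], d[3L], d[4L]))
  if (!is.null(x$voxel_size_um))
    cat(sprintf("  voxel size (z,y,x): %s um\n",
                paste(format(x$voxel_size_um), collapse = " x ")))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Extract one channel of a stack as a 3D array
#'
#' @param stack a [volume_stack()].
#' @param channel channel name (or 1-based index).
#' @return 3D numeric array `dim = c(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "VolumeStack"))
  if (is.character(channel)) {
    idx <- match(channel, stack$channel_names)
    if (is.na(idx)) stop("no channel named '", channel, "'")
  } else idx <- as.integer(channel)
  if (idx < 1L || idx > dim(stack$data)[1L]) stop("channel index out of range")
  array(stack$data[idx, , , , drop = FALSE], dim = dim(stack$data)[2:4])
}

# Parse SizeZ/SizeC/DimensionOrder out of an OME-XML ImageDescription, if
# present. Returns NULL for plain TIFFs.
parse_ome_layout <- function(description) {
  if (is.null(description) || !any(grepl("<OME", description, fixed = TRUE)))
    return(NULL)
  doc <- tryCatch(xml2::read_xml(paste(description, collapse = "")),
                  error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  list(size_z = as.integer(xml2::xml_attr(px, "SizeZ")),
       size_c = as.integer(xml2::xml_attr(px, "SizeC")),
       dimension_order = xml2::xml_attr(px, "DimensionOrder"),
       physical_z = as.numeric(xml2::xml_attr(px, "PhysicalSizeZ")),
       physical_y = as.numeric(xml2::xml_attr(px, "PhysicalSizeY")),
       physical_x = as.numeric(xml2::xml_attr(px, "PhysicalSizeX")))
}

#' Read a multichannel z-stack from a (OME-)TIFF file
#'
#' Pages of a plain multi-page TIFF are interpreted with the channel index
#' varying fastest within each z-slice (array order `(z, c, y, x)`),
#' overridable via `page_order`. For OME-TIFF the layout (`SizeZ`,
#' `SizeC`, `DimensionOrder`, physical voxel size) is taken from the
#' embedded OME-XML. Integer intensities are preserved exactly as stored;
#' no rescaling to `[0, 1]` occurs on load.
#'
#' @param path TIFF or OME-TIFF file.
#' @param channel_map named integer vector mapping channel names to 1-based
#'   channel indices in the file, e.g. `c(DAPI = 1, EdU = 2)`. The
#'   returned stack orders channels as listed here.
#' @param n_channels number of channels in the file; defaults to the OME
#'   metadata when present, else `max(channel_map)`.
#' @param page_order `"zc"` (z slowest, channel fastest; the default for
#'   plain TIFF) or `"cz"` (channel slowest). Ignored when OME metadata
#'   pins the order.
#' @return A [volume_stack()].
#' @export
read_stack <- function(path, channel_map, n_channels = NULL,
                       page_order = c("zc", "cz")) {
  page_order <- match.arg(page_order)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(names(channel_map)) || any(!nzchar(names(channel_map))))
    stop("`channel_map` must be a named vector (name -> channel index)")
  channel_map <- vapply(channel_map, as.integer, integer(1))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) stop("not a readable TIFF: ", path,
                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  ome <- parse_ome_layout(attr(pages[[1L]], "description"))
  voxel <- NULL
  if (!is.null(ome)) {
    if (!is.na(ome$size_c)) n_channels <- ome$size_c
    if (!is.na(ome$dimension_order))
      # In XYCZT-style orders C before Z means channel varies fastest.
      page_order <- if (regexpr("C", ome$dimension_order) <
                        regexpr("Z", ome$dimension_order)) "zc" else "cz"
    if (!any(is.na(c(ome$physical_z, ome$physical_y, ome$physical_x))))
      voxel <- c(ome$physical_z, ome$physical_y, ome$physical_x)
  }
  if (is.null(n_channels)) n_channels <- max(channel_map)
  n_channels <- as.integer(n_channels)
  if (any(channel_map < 1L | channel_map > n_channels))
    stop("channel index out of range: file has ", n_channels, " channel(s)")
  n_pages <- length(pages)
  if (n_pages %% n_channels != 0L)
    stop("page count ", n_pages, " is not a multiple of ", n_channels,
         " channels")
  nz <- n_pages %/% n_channels
  dims <- dim(pages[[1L]])[1:2]
  arr <- array(0, dim = c(length(channel_map), nz, dims[1L], dims[2L]))
  for (k in seq_along(channel_map)) {
    ci <- channel_map[k]
    for (z in seq_len(nz)) {
      page <- if (page_order == "zc") (z - 1L) * n_channels + ci
              else (ci - 1L) * nz + z
      pg <- pages[[page]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # drop extra samples
      arr[k, z, , ] <- pg
    }
  }
  volume_stack(arr, names(channel_map), voxel_size_um = voxel, source = path)
}

#' Write a stack to a multi-page TIFF
#'
#' Integer-valued stacks are written at `bits` bits per sample and round
#' trip losslessly through [read_stack()]; real-valued stacks are written
#' as 32-bit float. Pages are ordered z slowest, channel fastest
#' (`page_order = "zc"` in [read_stack()]).
#'
#' @param stack a [volume_stack()].
#' @param path output file.
#' @param bits bits per sample for integer data (8 or 16).
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "VolumeStack"), bits %in% c(8L, 16L))
  d <- dim(stack$data)
  integerish <- all(stack$data == round(stack$data))
  maxval <- 2^bits - 1
  if (integerish && max(stack$data) > maxval)
    stop("integer intensities exceed ", bits, "-bit range")
  if (!integerish && max(stack$data) > 1)
    stop("real-valued stacks must lie in [0, 1] for float TIFF storage; ",
         "quantize to integers first")
  pages <- vector("list", d[1L] * d[2L])
  p <- 0L
  for (z in seq_len(d[2L])) for (ch in seq_len(d[1L])) {
    p <- p + 1L
    pg <- matrix(stack$data[ch, z, , ], nrow = d[3L])
    pages[[p]] <- if (integerish) pg / maxval else pg
  }
  if (integerish) tiff::writeTIFF(pages, path, bits.per.sample = bits)
  else tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write / read a binary segmentation mask
#'
#' Masks are stored as single-channel 8-bit multi-page TIFFs with values
#' 0/1; the round trip is lossless.
#'
#' @param mask 3D logical array `(z, y, x)`.
#' @param path file path.
#' @return `read_mask()` returns a 3D logical array.
#' @export
write_mask <- function(mask, path) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D logical array")
  d <- dim(mask)
  pages <- lapply(seq_len(d[1L]), function(z)
    matrix(as.numeric(mask[z, , ]) / 255, nrow = d[2L]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1L]])[1:2]
  out <- array(FALSE, dim = c(length(pages), d[1L], d[2L]))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]] > 0
  out
}

#' Write / read a quantification report
#'
#' One CSV row per organoid. Numeric columns are serialized at full
#' double precision (17 significant digits) so that reports round trip
#' exactly.
#'
#' @param records data frame of quantification records (see
#'   [quantify_stack()]), one row per organoid.
#' @param path CSV file path.
#' @return `read_report()` returns the records as a data frame.
#' @export
write_report <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data frame")
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Polygon region of interest with a pixel scale
#'
#' Represents a taste-bud profile outline drawn on a maximum projection:
#' an ordered vertex list in pixel coordinates plus the pixels-per-micron
#' scale set from the image scale bar.
#'
#' @param vertices numeric matrix (n >= 3 rows) of `(x, y)` pixel
#'   coordinates, or a list of length-2 vertices.
#' @param scale_px_per_um positive pixels-per-micron scale.
#' @param label identifier for the outlined profile.
#' @return An object of class `PolygonROI`.
#' @export
polygon_roi <- function(vertices, scale_px_per_um, label = "") {
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, unlist))
  vertices <- matrix(as.numeric(vertices), ncol = 2L,
                     dimnames = list(NULL, c("x", "y")))
  if (nrow(vertices) < 3L) stop("a polygon needs at least 3 vertices")
  if (any(!is.finite(vertices))) stop("vertices must be finite")
  scale_px_per_um <- as.numeric(scale_px_per_um)
  if (length(scale_px_per_um) != 1L || !is.finite(scale_px_per_um) ||
      scale_px_per_um <= 0)
    stop("`scale_px_per_um` must be a single positive number")
  if (!polygon_is_simple(vertices))
    stop("polygon is self-intersecting; only simple outlines are valid")
  structure(list(vertices = vertices, scale_px_per_um = scale_px_per_um,
                 label = as.character(label)[1L]),
            class = "PolygonROI")
}

# Simple-polygon check: no two non-adjacent edges intersect.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  seg <- function(i) rbind(v[i, ], v[if (i == n) 1L else i + 1L, ])
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  on_seg <- function(a, b, c)
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  intersects <- function(p1, p2, q1, q2) {
    o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
    o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
    if (o1 != o2 && o3 != o4) return(TRUE)
    (o1 == 0 && on_seg(p1, p2, q1)) || (o2 == 0 && on_seg(p1, p2, q2)) ||
    (o3 == 0 && on_seg(q1, q2, p1)) || (o4 == 0 && on_seg(q1, q2, p2))
  }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    # skip adjacent edges (they share a vertex)
    if (j == i + 1L || (i == 1L && j == n)) next
    si <- seg(i); sj <- seg(j)
    if (intersects(si[1, ], si[2, ], sj[1, ], sj[2, ])) return(FALSE)
  }
  TRUE
}

#' Read / write polygon ROIs as JSON
#'
#' ROIs are stored as a JSON object with `vertices` (list of `[x, y]`
#' pairs), `scale_px_per_um` and `label`.
#'
#' @param roi a [polygon_roi()].
#' @param path JSON file path.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "PolygonROI"))
  jsonlite::write_json(
    list(vertices = unname(lapply(seq_len(nrow(roi$vertices)),
                                  function(i) roi$vertices[i, ])),
         scale_px_per_um = roi$scale_px_per_um,
         label = roi$label),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  polygon_roi(x$vertices, x$scale_px_per_um, x$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration (YAML or JSON)
#'
#' A configuration names each channel of interest and its per-channel
#' parameters ([channel_params()]): role, Otsu scale factor, filter sizes,
#' structuring-element radius and reconstruction connectivity. Unset
#' fields take the pipeline defaults (factors 0.5 nuclear / 0.2
#' proliferation, median window 3, Gaussian 5 with sigma 0.5, erosion
#' radius 3, connectivity 26).
#'
#' @param path `.yaml`/`.yml` or `.json` file with a top-level `channels`
#'   mapping of channel name to parameter list, and optionally `seed`.
#' @return list with elements `channels` (named list of
#'   [channel_params()]) and `seed`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$channels) || length(raw$channels) == 0L)
    stop("config must define at least one entry under `channels`")
  channels <- lapply(raw$channels, function(p) do.call(channel_params, p))
  list(channels = channels, seed = raw$seed %||% NULL)
}
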