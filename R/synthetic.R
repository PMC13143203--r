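# Run `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards so generators are pure in their seed.
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed)) stop("`seed` must be an integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a two-channel organoid z-stack with known ground truth
#'
#' Emulates a confocal stack of a densely nucleated organoid: `n_nuclei`
#' non-overlapping hard spheres of equal radius are packed uniformly at
#' random into the volume (rejection sampling), rendered at `amplitude`
#' into the DAPI channel; an exact-count random subset
#' (`round(n_nuclei * edu_fraction)`) is rendered identically into the
#' EdU channel. Both channels are Gaussian-blurred (`blur_sigma`,
#' emulating the microscope PSF), offset by `background` and corrupted
#' with additive Gaussian noise of sd `(amplitude - background) / snr`,
#' then clipped at 0.
#'
#' Hard spheres (rather than soft blobs) make the ground-truth voxel
#' volume unambiguous: with equal radii, the EdU+/DAPI+ volume ratio of
#' the truth equals the labeled fraction, which is what end-to-end
#' recovery tests exploit. The defaults emulate imaging at roughly
#' 0.33 um/voxel (a ~4 um-radius nucleus spans 12 voxels) with a
#' sub-voxel PSF and high signal-to-noise.
#'
#' @param shape `(z, y, x)` volume dimensions in voxels.
#' @param n_nuclei number of nuclei to pack.
#' @param nucleus_radius sphere radius in voxels.
#' @param edu_fraction fraction of nuclei labeled EdU+, in `[0, 1]`.
#' @param snr signal-to-noise ratio `(amplitude - background) / noise sd`.
#' @param background additive background level.
#' @param amplitude foreground intensity of a rendered nucleus.
#' @param blur_sigma PSF Gaussian sigma in voxels.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param max_tries rejection-sampling budget for packing; exceeding it
#'   raises an error (infeasible packing).
#' @return list with `stack` (a [volume_stack()] with channels
#'   `DAPI`, `EdU`) and `truth` (class `SyntheticTruth`: `centers`
#'   matrix in `(z, y, x)` voxel coordinates, `radii`, `edu_labels`,
#'   `background`, `amplitude`, `noise_sd`, `blur_sigma`, `shape`,
#'   `seed`).
#' @export
simulate_organoid_stack <- function(shape = c(72L, 176L, 176L),
                                    n_nuclei = 60L,
                                    nucleus_radius = 12,
                                    edu_fraction = 0.3,
                                    snr = 50,
                                    background = 0.02,
                                    amplitude = 1,
                                    blur_sigma = 0.5,
                                    seed = 1L,
                                    max_tries = 200000L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), n_nuclei >= 1L,
            nucleus_radius > 0, edu_fraction >= 0, edu_fraction <= 1,
            snr > 0, background >= 0, amplitude > background,
            blur_sigma > 0)
  if (any(shape < 2 * nucleus_radius + 1))
    stop("volume cannot accommodate a sphere of radius ", nucleus_radius)
  with_seed(seed, {
    centers <- matrix(NA_real_, nrow = n_nuclei, ncol = 3L,
                      dimnames = list(NULL, c("z", "y", "x")))
    r <- nucleus_radius
    accepted <- 0L
    for (i in seq_len(max_tries)) {
      cand <- stats::runif(3L, min = r + 1, max = shape - r)
      ok <- accepted == 0L ||
        all(colSums((t(centers[seq_len(accepted), , drop = FALSE]) -
                       cand)^2) >= (2 * r)^2)
      if (ok) {
        accepted <- accepted + 1L
        centers[accepted, ] <- cand
        if (accepted == n_nuclei) break
      }
    }
    if (accepted < n_nuclei)
      stop("infeasible packing: placed ", accepted, " of ", n_nuclei,
           " nuclei in ", max_tries, " attempts")
    n_edu <- round(n_nuclei * edu_fraction)
    edu_labels <- rep(FALSE, n_nuclei)
    if (n_edu > 0L) edu_labels[sample.int(n_nuclei, n_edu)] <- TRUE
    dapi <- array(0, dim = shape)
    edu <- array(0, dim = shape)
    for (i in seq_len(n_nuclei)) {
      c0 <- centers[i, ]
      zr <- max(1L, floor(c0[1L] - r)):min(shape[1L], ceiling(c0[1L] + r))
      yr <- max(1L, floor(c0[2L] - r)):min(shape[2L], ceiling(c0[2L] + r))
      xr <- max(1L, floor(c0[3L] - r)):min(shape[3L], ceiling(c0[3L] + r))
      dz2 <- (zr - c0[1L])^2
      dy2 <- (yr - c0[2L])^2
      dx2 <- (xr - c0[3L])^2
      inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r^2
      sub <- dapi[zr, yr, xr]
      sub[inside] <- amplitude
      dapi[zr, yr, xr] <- sub
      if (edu_labels[i]) {
        sub <- edu[zr, yr, xr]
        sub[inside] <- amplitude
        edu[zr, yr, xr] <- sub
      }
    }
    noise_sd <- (amplitude - background) / snr
    ksize <- 2L * max(1L, ceiling(3 * blur_sigma)) + 1L
    finish <- function(img) {
      img <- gaussian_filter_3d(img, ksize, blur_sigma)
      img <- img + background +
        array(stats::rnorm(length(img), sd = noise_sd), dim = shape)
      img[img < 0] <- 0
      img
    }
    dapi <- finish(dapi)
    edu <- finish(edu)
    data4 <- array(0, dim = c(2L, shape))
    data4[1L, , , ] <- dapi
    data4[2L, , , ] <- edu
    stack <- volume_stack(data4, c("DAPI", "EdU"),
                          source = sprintf("simulate_organoid_stack(seed=%d)",
                                           as.integer(seed)))
    truth <- structure(
      list(centers = centers, radii = rep(r, n_nuclei),
           edu_labels = edu_labels, background = background,
           amplitude = amplitude, noise_sd = noise_sd,
           blur_sigma = blur_sigma, shape = shape,
           seed = as.integer(seed)),
      class = "SyntheticTruth")
    list(stack = stack, truth = truth)
  })
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(
    "SyntheticTruth: %d nuclei (radius %s), %d EdU+ (%.2f), %d x %d x %d, seed %d\n",
    nrow(x$centers), format(x$radii[1L]), sum(x$edu_labels),
    mean(x$edu_labels), x$shape[1L], x$shape[2L], x$shape[3L], x$seed))
  invisible(x)
}

#' Ground-truth voxel mask of a synthetic stack
#'
#' Rasterizes the truth's spheres (all nuclei, or the EdU-labeled
#' subset) into a logical volume, for overlap scoring against pipeline
#' masks.
#'
#' @param truth a `SyntheticTruth`.
#' @param which `"dapi"` (all nuclei) or `"edu"` (labeled subset).
#' @return 3D logical array.
#' @export
truth_mask <- function(truth, which = c("dapi", "edu")) {
  which <- match.arg(which)
  stopifnot(inherits(truth, "SyntheticTruth"))
  mask <- array(FALSE, dim = truth$shape)
  sel <- if (which == "dapi") seq_len(nrow(truth$centers))
         else which(truth$edu_labels)
  for (i in sel) {
    c0 <- truth$centers[i, ]
    r <- truth$radii[i]
    zr <- max(1L, floor(c0[1L] - r)):min(truth$shape[1L], ceiling(c0[1L] + r))
    yr <- max(1L, floor(c0[2L] - r)):min(truth$shape[2L], ceiling(c0[2L] + r))
    xr <- max(1L, floor(c0[3L] - r)):min(truth$shape[3L], ceiling(c0[3L] + r))
    inside <- outer(outer((zr - c0[1L])^2, (yr - c0[2L])^2, `+`),
                    (xr - c0[3L])^2, `+`) <= r^2
    sub <- mask[zr, yr, xr]
    sub[inside] <- TRUE
    mask[zr, yr, xr] <- sub
  }
  mask
}

#' Serialize / read a synthetic ground-truth manifest as JSON
#'
#' @param truth a `SyntheticTruth`.
#' @param path JSON file path.
#' @return `read_truth()` returns the `SyntheticTruth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  jsonlite::write_json(
    list(centers = truth$centers, radii = truth$radii,
         edu_labels = truth$edu_labels, background = truth$background,
         amplitude = truth$amplitude, noise_sd = truth$noise_sd,
         blur_sigma = truth$blur_sigma, shape = truth$shape,
         seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(centers = matrix(x$centers, ncol = 3L,
                          dimnames = list(NULL, c("z", "y", "x"))),
         radii = x$radii, edu_labels = x$edu_labels,
         background = x$background, amplitude = x$amplitude,
         noise_sd = x$noise_sd, blur_sigma = x$blur_sigma,
         shape = as.integer(x$shape), seed = as.integer(x$seed)),
    class = "SyntheticTruth")
}

#' Simulate a brief-access lickometer session
#'
#' One testing day of up to `n_blocks` trial blocks; each block presents
#' water and the four tastant concentrations once each, in random order,
#' and lick counts are Poisson draws around the per-bottle mean rates.
#'
#' @param mean_licks named non-negative vector of mean lick counts per
#'   5 s presentation; must include `"water"`, remaining names are the
#'   concentration labels (four, for the standard panel).
#' @param n_blocks number of trial blocks (default 8).
#' @param day day index recorded on every trial.
#' @param seed integer seed.
#' @return data frame of trials with columns `day`, `block`, `bottle`,
#'   `licks`, suitable for [lick_ratio()] and [thirst_metric()].
#' @export
simulate_lick_session <- function(mean_licks, n_blocks = 8L, day = 1L,
                                  seed = 1L) {
  if (is.null(names(mean_licks)) || !"water" %in% names(mean_licks))
    stop("`mean_licks` must be named and include 'water'")
  if (any(mean_licks < 0)) stop("mean lick counts must be >= 0")
  n_blocks <- as.integer(n_blocks)
  stopifnot(n_blocks >= 1L)
  with_seed(seed, {
    rows <- lapply(seq_len(n_blocks), function(b) {
      order <- sample(names(mean_licks))
      data.frame(day = as.integer(day), block = b, bottle = order,
                 licks = stats::rpois(length(order), mean_licks[order]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Housekeeping Ct values sit at `housekeeping_ct` plus noise for every
#' sample; target-gene Ct values sit at `target_base_ct` plus noise in
#' the control group and are shifted by `-log2_effect` (one PCR cycle
#' per doubling) in the treated group, so [ddct_fold_change()] recovers
#' `2^log2_effect` up to noise.
#'
#' @param log2_effects named numeric vector of log2 fold changes, one
#'   per target gene.
#' @param n_per_group samples per group (>= 1).
#' @param ct_noise_sd Gaussian sd added to every Ct (0 for exact tables).
#' @param housekeeping housekeeping gene name (default `"Rpl19"`).
#' @param housekeeping_ct,target_base_ct baseline Ct values.
#' @param seed integer seed.
#' @return data frame with columns `sample_id`, `group` (`"control"` /
#'   `"treated"`), `gene`, `ct`.
#' @export
simulate_ct_table <- function(log2_effects, n_per_group = 3L,
                              ct_noise_sd = 0.1,
                              housekeeping = "Rpl19",
                              housekeeping_ct = 20,
                              target_base_ct = 26,
                              seed = 1L) {
  if (is.null(names(log2_effects)) || any(!nzchar(names(log2_effects))))
    stop("`log2_effects` must be a named vector (gene -> log2 fold)")
  n_per_group <- as.integer(n_per_group)
  stopifnot(n_per_group >= 1L, ct_noise_sd >= 0)
  base_ct <- rep_len(target_base_ct, length(log2_effects))
  with_seed(seed, {
    samples <- data.frame(
      sample_id = c(sprintf("ctrl_%d", seq_len(n_per_group)),
                    sprintf("trt_%d", seq_len(n_per_group))),
      group = rep(c("control", "treated"), each = n_per_group),
      stringsAsFactors = FALSE)
    rows <- list(data.frame(
      sample_id = samples$sample_id, group = samples$group,
      gene = housekeeping,
      ct = housekeeping_ct + stats::rnorm(nrow(samples), sd = ct_noise_sd),
      stringsAsFactors = FALSE))
    for (g in seq_along(log2_effects)) {
      shift <- ifelse(samples$group == "treated", -log2_effects[g], 0)
      rows[[g + 1L]] <- data.frame(
        sample_id = samples$sample_id, group = samples$group,
        gene = names(log2_effects)[g],
        ct = base_ct[g] + shift +
          stats::rnorm(nrow(samples), sd = ct_noise_sd),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
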