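# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain R loops and dense enumeration only.

# symmetric padding lookup: index k (possibly out of range) -> valid index
sym_idx <- function(k, n) {
  while (k < 1 || k > n) {
    if (k < 1) k <- 1 - k
    if (k > n) k <- 2 * n + 1 - k
  }
  k
}

naive_median3d <- function(v, window = 3L) {
  d <- dim(v)
  r <- window %/% 2
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    vals <- numeric(0)
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r)
      vals <- c(vals, v[sym_idx(z + dz, d[1]), sym_idx(y + dy, d[2]),
                        sym_idx(x + dx, d[3])])
    out[z, y, x] <- sort(vals)[(length(vals) + 1) %/% 2]
  }
  out
}

naive_gauss3d <- function(v, kernel_size = 5L, sigma = 0.5) {
  d <- dim(v)
  r <- (kernel_size - 1L) / 2L
  k1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k3 <- outer(outer(k1, k1), k1)  # dense (z, y, x) kernel
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    acc <- 0
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r)
      acc <- acc + k3[dz + r + 1, dy + r + 1, dx + r + 1] *
        v[sym_idx(z + dz, d[1]), sym_idx(y + dy, d[2]),
          sym_idx(x + dx, d[3])]
    out[z, y, x] <- acc
  }
  out
}

naive_ball_offsets <- function(radius) {
  out <- NULL
  for (dz in -radius:radius) for (dy in -radius:radius)
    for (dx in -radius:radius)
      if (dz^2 + dy^2 + dx^2 <= radius^2)
        out <- rbind(out, c(dz, dy, dx))
  out
}

naive_erode3d <- function(v, offsets) {
  d <- dim(v)
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    m <- Inf
    for (o in seq_len(nrow(offsets))) {
      zz <- z + offsets[o, 1]; yy <- y + offsets[o, 2]
      xx <- x + offsets[o, 3]
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] ||
          xx < 1 || xx > d[3]) next
      m <- min(m, v[zz, yy, xx])
    }
    out[z, y, x] <- m
  }
  out
}

conn_offsets <- function(connectivity) {
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    s <- abs(dz) + abs(dy) + abs(dx)
    if (s == 0) next
    if (connectivity == 6 && s > 1) next
    if (connectivity == 18 && s > 2) next
    out <- rbind(out, c(dz, dy, dx))
  }
  out
}

naive_dilate <- function(a, connectivity = 26) {
  d <- dim(a)
  off <- conn_offsets(connectivity)
  out <- a
  for (o in seq_len(nrow(off))) {
    dz <- off[o, 1]; dy <- off[o, 2]; dx <- off[o, 3]
    zr <- max(1, 1 - dz):min(d[1], d[1] - dz)
    yr <- max(1, 1 - dy):min(d[2], d[2] - dy)
    xr <- max(1, 1 - dx):min(d[3], d[3] - dx)
    out[zr, yr, xr] <- pmax(out[zr, yr, xr],
                            a[zr + dz, yr + dy, xr + dx])
  }
  out
}

# reconstruction by dilation: iterate dilate-then-clip to a fixed point
naive_reconstruct <- function(marker, mask, connectivity = 26) {
  cur <- marker
  repeat {
    nxt <- pmin(naive_dilate(cur, connectivity), mask)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# exhaustive Otsu over all bin boundaries; ties -> mean of boundaries
naive_otsu <- function(v, bins = 256L) {
  if (min(v) == max(v)) return(0)
  idx <- pmin(floor(v * bins), bins - 1)  # bin of each voxel, 0-based
  mid <- (idx + 0.5) / bins               # bin midpoint of each voxel
  sb <- rep(-Inf, bins - 1)
  for (k in 1:(bins - 1)) {               # boundary at k / bins
    lo <- mid[idx < k]; hi <- mid[idx >= k]
    if (length(lo) == 0 || length(hi) == 0) next
    sb[k] <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }
  best <- max(sb)
  winners <- which(sb >= best - 1e-12 * abs(best))
  mean(winners) / bins
}

# Monte-Carlo polygon area in um^2 by grid rasterization
raster_polygon_area <- function(vertices, scale_px_per_um, n_grid = 400L) {
  xs <- range(vertices[, 1]); ys <- range(vertices[, 2])
  gx <- seq(xs[1], xs[2], length.out = n_grid)
  gy <- seq(ys[1], ys[2], length.out = n_grid)
  cell <- diff(xs) * diff(ys) / (n_grid^2)
  inside <- 0L
  n <- nrow(vertices)
  for (px in gx) for (py in gy) {
    cross <- 0L
    for (i in 1:n) {
      j <- if (i == n) 1L else i + 1L
      x1 <- vertices[i, 1]; y1 <- vertices[i, 2]
      x2 <- vertices[j, 1]; y2 <- vertices[j, 2]
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (px < xint) cross <- cross + 1L
      }
    }
    if (cross %% 2L == 1L) inside <- inside + 1L
  }
  inside * cell / scale_px_per_um^2
}

rand_volume <- function(seed, max_dim = 8L, integer_valued = FALSE) {
  set.seed(seed)
  d <- sample(2:max_dim, 3L, replace = TRUE)
  v <- if (integer_valued) array(sample(0:9, prod(d), TRUE), d)
       else array(runif(prod(d)), d)
  v
}
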