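# Independent voxelization oracles for the box metrics: each axis of the
# patient frame is rasterized on a regular grid of cell centers and volumes
# are obtained by counting cells, never by the closed-form interval algebra
# under test.

axis_cells <- function(a, b, d, h) {
  lo_a <- a$center[d] - a$size[d] / 2; hi_a <- a$center[d] + a$size[d] / 2
  lo_b <- b$center[d] - b$size[d] / 2; hi_b <- b$center[d] + b$size[d] / 2
  lo <- min(lo_a, lo_b) - h
  hi <- max(hi_a, hi_b) + h
  centers <- seq(lo + h / 2, hi, by = h)
  list(
    in_a = centers > lo_a & centers < hi_a,
    in_b = centers > lo_b & centers < hi_b,
    in_enc = centers > min(lo_a, lo_b) & centers < max(hi_a, hi_b)
  )
}

raster_volumes <- function(a, b, h = 0.05, dims = 1:3) {
  counts <- vapply(dims, function(d) {
    cc <- axis_cells(a, b, d, h)
    c(na = sum(cc$in_a), nb = sum(cc$in_b), ni = sum(cc$in_a & cc$in_b),
      ne = sum(cc$in_enc))
  }, numeric(4))
  list(va = prod(counts["na", ]), vb = prod(counts["nb", ]),
       vi = prod(counts["ni", ]), venc = prod(counts["ne", ]))
}

raster_iou3d <- function(a, b, h = 0.05) {
  v <- raster_volumes(a, b, h)
  v$vi / (v$va + v$vb - v$vi)
}

raster_giou3d <- function(a, b, h = 0.05) {
  v <- raster_volumes(a, b, h)
  vu <- v$va + v$vb - v$vi
  v$vi / vu - (v$venc - vu) / v$venc
}

raster_projected_iou <- function(a, b, plane, h = 0.05) {
  dims <- switch(plane, axial = c(1L, 2L), sagittal = c(2L, 3L),
                 coronal = c(1L, 3L))
  v <- raster_volumes(a, b, h, dims = dims)
  v$vi / (v$va + v$vb - v$vi)
}

# Exhaustive Otsu oracle: try all 256-bin split points and maximize the
# between-class variance directly from the definition.
otsu_exhaustive <- function(image, n_bins = 256L) {
  breaks <- seq(min(image), max(image), length.out = n_bins + 1L)
  bin <- findInterval(image, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  vals <- mids[bin]
  best <- -Inf; best_k <- NA_integer_
  for (k in 1:(n_bins - 1L)) {
    thr <- breaks[k + 1L]
    g0 <- vals[bin <= k]; g1 <- vals[bin > k]
    if (!length(g0) || !length(g1)) next
    w0 <- length(g0) / length(vals); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (bcv > best + 1e-15) { best <- bcv; best_k <- k }
  }
  breaks[best_k + 1L]
}

random_box <- function(size_range = c(6, 14), center_range = c(-4, 4)) {
  box3d(stats::runif(3, center_range[1], center_range[2]),
        stats::runif(3, size_range[1], size_range[2]))
}
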