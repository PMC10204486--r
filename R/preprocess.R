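#' Maximum intensity projection of an oriented slice stack
#'
#' @param stack a `scout_stack` (one orientation of a `scout_series`) or a
#'   3D array with slices along the third dimension.
#' @return A 2D numeric matrix: the pixel-wise maximum across slices.
#' @export
mip <- function(stack) {
  img <- if (inherits(stack, "scout_stack")) stack$img else stack
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3] < 1L) {
    stop("stack must contain at least one slice", call. = FALSE)
  }
  apply(img, c(1, 2), max)
}

#' Otsu binarization of an intensity image
#'
#' Finds the threshold maximizing the between-class intensity variance over a
#' 256-bin histogram spanning the image range; ties break toward the lowest
#' maximizing threshold. The mask is `image > threshold`, so an
#' already-binary image is a fixed point.
#'
#' @param image 2D numeric matrix with at least two distinct values.
#' @param n_bins histogram bins (256 by default).
#' @return A list with `threshold` (intensity value) and `mask` (0/1 integer
#'   matrix of the same shape).
#' @export
otsu_binarize <- function(image, n_bins = 256L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  rng <- range(image)
  if (rng[1] == rng[2]) {
    stop("constant image: no threshold separates foreground from background",
         call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(
    findInterval(image, breaks, rightmost.closed = TRUE, all.inside = TRUE),
    nbins = n_bins
  )
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  total <- sum(counts)

  # cumulative class weights/means for every split after bin k
  w0 <- cumsum(counts)[-n_bins] / total
  m <- cumsum(counts * mids)
  mu_total <- m[n_bins] / total
  mu0 <- m[-n_bins] / cumsum(counts)[-n_bins]
  w1 <- 1 - w0
  mu1 <- (m[n_bins] - m[-n_bins]) / (total - cumsum(counts)[-n_bins])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv) # first (lowest) maximizer
  threshold <- breaks[k + 1L]
  mask <- matrix(as.integer(image > threshold), nrow = nrow(image))
  list(threshold = threshold, mask = mask)
}

# Keep only the largest 4-connected foreground component.
largest_component <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  nextlab <- 0L
  sizes <- integer(0)
  fg <- which(mask > 0)
  for (start in fg) {
    if (lab[start] > 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    count <- 0L
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      count <- count + 1L
      i <- (p - 1L) %% n + 1L
      j <- (p - 1L) %/% n + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < n) p + 1L,
                  if (j > 1L) p - n, if (j < m) p + n)) {
        if (mask[q] > 0 && lab[q] == 0L) {
          lab[q] <- nextlab
          queue <- c(queue, q)
        }
      }
    }
    sizes[nextlab] <- count
  }
  if (nextlab <= 1L) return(mask)
  keep <- which.max(sizes)
  matrix(as.integer(lab == keep), n, m)
}

# Nearest-neighbour resample of a binary mask onto a square out_res grid,
# padding to a square field first so aspect is preserved. Returns the mask
# plus the output pixel-center affine (origin + spacing per in-plane axis).
resample_mask <- function(mask, origin, spacing, out_res) {
  n <- nrow(mask); m <- ncol(mask)
  # pad to square (zeros), extending symmetrically
  side <- max(n, m)
  if (n != side || m != side) {
    padded <- matrix(0L, side, side)
    off_i <- (side - n) %/% 2
    off_j <- (side - m) %/% 2
    padded[off_i + seq_len(n), off_j + seq_len(m)] <- mask
    origin <- origin - c(off_i, off_j) * spacing
    mask <- padded
  }
  extent <- side * spacing
  spacing_out <- extent / out_res
  # pixel-center positions of the output grid, in cm
  u <- origin[1] - spacing[1] / 2 + (seq_len(out_res) - 0.5) * spacing_out[1]
  v <- origin[2] - spacing[2] / 2 + (seq_len(out_res) - 0.5) * spacing_out[2]
  src_i <- pmin(pmax(round((u - origin[1]) / spacing[1]) + 1L, 1L), side)
  src_j <- pmin(pmax(round((v - origin[2]) / spacing[2]) + 1L, 1L), side)
  list(
    mask = mask[src_i, src_j, drop = FALSE],
    origin = c(u[1], v[1]),
    spacing = c(spacing_out[1], spacing_out[2])
  )
}

#' Build the three binary MIP masks a placement model consumes
#'
#' For each scout orientation: maximum intensity projection, Otsu
#' binarization, then nearest-neighbour resampling onto a common square
#' resolution (aspect preserved by zero padding). The pixel-center affine of
#' every mask is retained so pixels map back to patient centimetres.
#'
#' @param scout a `scout_series` containing all three orientations.
#' @param out_resolution output mask side in pixels.
#' @param keep_largest_component drop all but the largest foreground
#'   component after binarization (off by default).
#' @return An object of class `mask_triplet`: per-orientation `mask` (0/1
#'   matrix), `origin`/`spacing` (cm, pixel centers), `axes` (the two
#'   in-plane patient axes), plus the shared `resolution`.
#' @export
make_masks <- function(scout, out_resolution = 224L, keep_largest_component = FALSE) {
  if (!inherits(scout, "scout_series")) {
    stop("scout must be a scout_series", call. = FALSE)
  }
  missing <- setdiff(c("axial", "sagittal", "coronal"), names(scout))
  empty <- vapply(
    c("axial", "sagittal", "coronal"),
    function(o) is.null(scout[[o]]) || length(scout[[o]]$img) == 0, TRUE
  )
  if (length(missing) || any(empty)) {
    stop(sprintf(
      "incomplete scout: missing orientation(s) %s",
      paste(unique(c(missing, names(which(empty)))), collapse = ", ")
    ), call. = FALSE)
  }
  out_resolution <- as.integer(out_resolution)
  planes <- lapply(c(axial = "axial", sagittal = "sagittal", coronal = "coronal"),
                   function(o) {
    stk <- scout[[o]]
    proj <- mip(stk)
    bin <- otsu_binarize(proj)$mask
    if (keep_largest_component) bin <- largest_component(bin)
    rs <- resample_mask(bin, stk$origin, stk$spacing, out_resolution)
    list(mask = rs$mask, origin = rs$origin, spacing = rs$spacing,
         axes = stk$axes, threshold_plane = o)
  })
  structure(c(planes, list(resolution = out_resolution)), class = "mask_triplet")
}

#' Stack a mask triplet into the network input array
#' @param masks a [make_masks()] result.
#' @return numeric array `[res, res, 3]`, channels ordered axial, sagittal,
#'   coronal.
#' @export
mask_array <- function(masks) {
  stopifnot(inherits(masks, "mask_triplet"))
  res <- masks$resolution
  arr <- array(0, dim = c(res, res, 3L))
  arr[, , 1] <- masks$axial$mask
  arr[, , 2] <- masks$sagittal$mask
  arr[, , 3] <- masks$coronal$mask
  arr
}

#' Map mask pixel indices to patient-frame cm (and back)
#'
#' @param plane one plane of a `mask_triplet` (e.g. `masks$axial`).
#' @param ij 2-column matrix (or length-2 vector) of pixel indices.
#' @return `pixel_to_cm`: matrix of in-plane cm coordinates;
#'   `cm_to_pixel`: matrix of (possibly fractional) pixel indices.
#' @export
pixel_to_cm <- function(plane, ij) {
  ij <- matrix(as.numeric(ij), ncol = 2L)
  cbind(plane$origin[1] + (ij[, 1] - 1) * plane$spacing[1],
        plane$origin[2] + (ij[, 2] - 1) * plane$spacing[2])
}

#' @rdname pixel_to_cm
#' @param uv 2-column matrix (or length-2 vector) of in-plane cm coordinates.
#' @export
cm_to_pixel <- function(plane, uv) {
  uv <- matrix(as.numeric(uv), ncol = 2L)
  cbind((uv[, 1] - plane$origin[1]) / plane$spacing[1] + 1,
        (uv[, 2] - plane$origin[2]) / plane$spacing[2] + 1)
}
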