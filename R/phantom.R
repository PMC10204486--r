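#' Specification of a synthetic prone bilateral-breast scout phantom
#'
#' The phantom emulates the anatomy visible on a 3-plane breast MRI scout in
#' prone positioning: two pendant breasts (ellipsoids) anterior to the chest
#' wall, a thorax block containing lung and heart surrogates, optional arm
#' blocks, and air background. Intensities are piecewise-constant tissue
#' values with additive Gaussian noise; no MR physics is simulated, since the
#' downstream masks only require plausible geometry.
#'
#' Patient frame: LR = +x (patient left positive), AP = +y (posterior
#' positive), SI = +z (superior positive), centimetres.
#'
#' With `arms = "overhead"` the breast ellipsoids are stretched in SI and
#' shrunk axially (LR/AP), reproducing the elongated pendant shape seen when
#' patients are positioned with raised arms — a known hard case for
#' placement.
#'
#' @param breast_semiaxes 2x3 matrix (rows `left`, `right`; columns
#'   `lr, ap, si`) of ellipsoid semi-axes in cm, all positive.
#' @param breast_centers 2x3 matrix of ellipsoid centers in cm; the left
#'   breast must have positive LR, the right negative, and both must lie
#'   anterior to the chest wall.
#' @param chest_wall_ap AP position (cm) of the chest-wall plane; tissue at
#'   larger AP belongs to the thorax.
#' @param noise Gaussian noise standard deviation as a fraction of the
#'   breast-tissue intensity.
#' @param arms `"down"` or `"overhead"`.
#' @param fov in-plane field of view of each scout slice, cm.
#' @param grid_n in-plane pixels per slice (square).
#' @param n_slices named integer vector: slices per orientation.
#' @param seed integer seed controlling the noise realization.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(breast_semiaxes,
                         breast_centers,
                         chest_wall_ap = 0,
                         noise = 0.05,
                         arms = c("down", "overhead"),
                         fov = 45,
                         grid_n = 96L,
                         n_slices = c(axial = 12L, sagittal = 12L, coronal = 9L),
                         seed = 1L) {
  arms <- match.arg(arms)
  breast_semiaxes <- matrix(as.numeric(breast_semiaxes), nrow = 2L,
                            dimnames = list(c("left", "right"), c("lr", "ap", "si")))
  breast_centers <- matrix(as.numeric(breast_centers), nrow = 2L,
                           dimnames = list(c("left", "right"), c("lr", "ap", "si")))
  if (arms == "overhead") {
    # raised arms stretch the pendant breast in SI and narrow it axially
    breast_semiaxes[, c("lr", "ap")] <- breast_semiaxes[, c("lr", "ap")] * 0.8
    breast_semiaxes[, "si"] <- breast_semiaxes[, "si"] * 1.35
  }
  if (any(breast_semiaxes <= 0)) {
    stop("breast semi-axes must be strictly positive", call. = FALSE)
  }
  if (!(breast_centers["left", "lr"] > 0 && breast_centers["right", "lr"] < 0)) {
    stop("left/right breast centers must lie on opposite sides of the midline",
         call. = FALSE)
  }
  if (any(breast_centers[, "ap"] >= chest_wall_ap)) {
    stop("breast centers must lie anterior to the chest wall", call. = FALSE)
  }
  if (!is.finite(noise) || noise < 0) stop("noise must be >= 0", call. = FALSE)
  stopifnot(all(c("axial", "sagittal", "coronal") %in% names(n_slices)))
  structure(list(
    breast_semiaxes = breast_semiaxes,
    breast_centers = breast_centers,
    chest_wall_ap = chest_wall_ap,
    noise = noise,
    arms = arms,
    fov = fov,
    grid_n = as.integer(grid_n),
    n_slices = vapply(n_slices[c("axial", "sagittal", "coronal")], as.integer, 1L),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Draw a randomized phantom specification
#'
#' Anatomy ranges are chosen so that the resulting ground-truth volumes
#' bracket typical clinical sizes (scan roughly 22-32 cm axial FOV with
#' 15-20 cm SI coverage; pre-scan roughly 11-15 x 9-13 x 13-18 cm). Left and
#' right breasts differ by a small asymmetry, and both breasts lie fully off
#' the midline, as in prone positioning with medial separation.
#'
#' @param seed integer seed.
#' @param noise noise fraction passed to [phantom_spec()].
#' @param arms arm position passed to [phantom_spec()].
#' @param grid_n,n_slices raster options passed to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
random_phantom_spec <- function(seed,
                                noise = 0.05,
                                arms = "down",
                                grid_n = 96L,
                                n_slices = c(axial = 12L, sagittal = 12L, coronal = 9L)) {
  with_seed(seed, {
    base <- c(
      lr = stats::runif(1, 4.5, 6.5),
      ap = stats::runif(1, 3.5, 5.5),
      si = stats::runif(1, 5.5, 8.0)
    )
    asym <- stats::runif(3, -0.075, 0.075)
    semi <- rbind(left = base + asym, right = base - asym)

    # medial gap keeps each expanded box off the midline
    gap_lr <- stats::runif(2, 0.1, 1.0)
    c_lr <- semi[, "lr"] + 1 + gap_lr
    gap_ap <- stats::runif(2, 0.5, 1.5)
    c_ap <- -(semi[, "ap"] + gap_ap)
    c_si <- stats::runif(1, -2, 2) + stats::runif(2, -0.3, 0.3)
    centers <- cbind(lr = c(c_lr[1], -c_lr[2]), ap = c_ap, si = c_si)
    rownames(centers) <- c("left", "right")

    phantom_spec(
      breast_semiaxes = semi, breast_centers = centers,
      noise = noise, arms = arms, grid_n = grid_n, n_slices = n_slices,
      seed = derive_seed(seed, 1L)
    )
  })
}

# Tissue intensity model (arbitrary units; breast tissue = 1, air = 0).
# Structures are painted in a fixed order so overlaps resolve
# deterministically; breasts are painted last.
phantom_intensity <- function(spec, x, y, z) {
  cw <- spec$chest_wall_ap
  val <- numeric(length(x))
  inb <- function(v, lo, hi) v >= lo & v <= hi
  # thorax block (mediastinum / liver surrogate)
  val[inb(x, -16, 16) & inb(y, cw, cw + 12) & inb(z, -14, 14)] <- 0.5
  # lungs (dark)
  lung <- (inb(x, 3, 13) | inb(x, -13, -3)) & inb(y, cw + 1.5, cw + 10.5) & inb(z, -9, 9)
  val[lung] <- 0.12
  # heart (bright, patient left of center)
  val[inb(x, -2, 6) & inb(y, cw + 1, cw + 7.5) & inb(z, -5, 3)] <- 0.8
  # chest wall slab
  val[inb(x, -16, 16) & inb(y, cw - 1, cw) & inb(z, -14, 14)] <- 0.9
  # arms by the sides
  if (spec$arms == "down") {
    val[(inb(x, 16.5, 20.5) | inb(x, -20.5, -16.5)) &
          inb(y, cw - 2, cw + 8) & inb(z, -12, 12)] <- 0.7
  }
  # breasts
  for (side in c("left", "right")) {
    ctr <- spec$breast_centers[side, ]
    ax <- spec$breast_semiaxes[side, ]
    r2 <- ((x - ctr[1]) / ax[1])^2 + ((y - ctr[2]) / ax[2])^2 + ((z - ctr[3]) / ax[3])^2
    val[r2 <= 1] <- 1.0
  }
  val
}

# In-plane pixel-center coordinates for a slice grid.
grid_coords <- function(fov, n) {
  spacing <- fov / n
  list(coords = -fov / 2 + (seq_len(n) - 0.5) * spacing, spacing = spacing,
       origin = -fov / 2 + 0.5 * spacing)
}

# Sample one oriented slice stack. `axes` are the two in-plane patient axes;
# `ortho` the projected axis; slice_pos its sampled positions.
sample_stack <- function(spec, axes, ortho, slice_pos) {
  g <- grid_coords(spec$fov, spec$grid_n)
  n <- spec$grid_n
  u <- rep(g$coords, times = n)        # dim 1 (rows)
  v <- rep(g$coords, each = n)         # dim 2 (cols)
  img <- array(0, dim = c(n, n, length(slice_pos)))
  for (s in seq_along(slice_pos)) {
    xyz <- list(lr = NULL, ap = NULL, si = NULL)
    xyz[[axes[1]]] <- u
    xyz[[axes[2]]] <- v
    xyz[[ortho]] <- rep(slice_pos[s], length(u))
    img[, , s] <- phantom_intensity(spec, xyz$lr, xyz$ap, xyz$si)
  }
  if (spec$noise > 0) {
    img <- pmax(img + stats::rnorm(length(img), sd = spec$noise), 0)
  }
  structure(list(
    img = img, axes = axes, orientation = NULL,
    origin = c(g$origin, g$origin), spacing = c(g$spacing, g$spacing),
    slice_pos = slice_pos
  ), class = "scout_stack")
}

#' Generate a synthetic 3-plane scout with guideline-derived ground truth
#'
#' Produces the scout series and the deterministic ground-truth volumes. The
#' bilateral pre-scan boxes are each breast ellipsoid's axis-aligned bounding
#' box expanded by exactly 1 cm per face, clipped at the patient midline so
#' the two volumes never overlap, then assigned the element-wise maximum of
#' the two sizes (the shared-size constraint) with centers pushed back off
#' the midline if the larger size would cross it. The scan volume is the
#' smallest square-axial box covering both expanded breast boxes plus a 2 cm
#' axillary margin superiorly.
#'
#' Output is bit-identical for a fixed spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_case`: list with `scout`
#'   (`scout_series`), `scan_truth` ([scan_params()]), `prescan_truth`
#'   ([prescan_params()]), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  scout <- with_seed(spec$seed, {
    axial <- sample_stack(spec, c("lr", "ap"), "si",
                          seq(-16, 16, length.out = spec$n_slices[["axial"]]))
    sagittal <- sample_stack(spec, c("ap", "si"), "lr",
                             seq(-18, 18, length.out = spec$n_slices[["sagittal"]]))
    coronal <- sample_stack(spec, c("lr", "si"), "ap",
                            seq(-13.5, 11, length.out = spec$n_slices[["coronal"]]))
    axial$orientation <- "axial"
    sagittal$orientation <- "sagittal"
    coronal$orientation <- "coronal"
    structure(list(axial = axial, sagittal = sagittal, coronal = coronal),
              class = "scout_series")
  })
  truth <- phantom_ground_truth(spec)
  structure(list(
    scout = scout,
    scan_truth = truth$scan,
    prescan_truth = truth$prescan,
    spec = spec
  ), class = "phantom_case")
}

# Deterministic ground-truth construction from the spec geometry.
phantom_ground_truth <- function(spec, margin = 1, axillary_margin = 2) {
  lo <- spec$breast_centers - spec$breast_semiaxes - margin
  hi <- spec$breast_centers + spec$breast_semiaxes + margin

  # midline clip: left box floor at x = 0, right box ceiling at x = 0
  lo_clip <- lo
  hi_clip <- hi
  lo_clip["left", "lr"] <- max(lo["left", "lr"], 0)
  hi_clip["right", "lr"] <- min(hi["right", "lr"], 0)

  size <- hi_clip - lo_clip
  ctr <- (hi_clip + lo_clip) / 2
  shared <- pmax(size["left", ], size["right", ])
  # re-clip centers so the shared size still respects the midline
  ctr["left", "lr"] <- max(ctr["left", "lr"], shared["lr"] / 2)
  ctr["right", "lr"] <- min(ctr["right", "lr"], -shared["lr"] / 2)
  prescan <- prescan_params(ctr["left", ], ctr["right", ], shared)

  # scan: cover both expanded (pre-clip) breast boxes, square axial footprint,
  # extra superior coverage toward the axilla
  lo_u <- pmin(lo["left", ], lo["right", ])
  hi_u <- pmax(hi["left", ], hi["right", ])
  hi_u["si"] <- hi_u["si"] + axillary_margin
  extent <- hi_u - lo_u
  fov <- max(extent[c("lr", "ap")])
  center <- (hi_u + lo_u) / 2
  scan <- scan_params(center[["lr"]], center[["ap"]], center[["si"]],
                      fov, extent[["si"]])
  list(scan = scan, prescan = prescan)
}

#' Voxel masks of the phantom tissue classes
#'
#' Rasterizes the breast ellipsoids and the thorax block on a regular voxel
#' grid, returning the coordinates of tissue voxels. Used by
#' [check_guidelines()].
#'
#' @param spec a [phantom_spec()].
#' @param spacing voxel edge in cm.
#' @return An object of class `phantom_masks`: voxel-center coordinate
#'   matrices (`n x 3`, columns lr/ap/si) for `left`, `right` and `thorax`,
#'   plus the `spacing` and frame tag.
#' @export
phantom_masks <- function(spec, spacing = 0.2) {
  stopifnot(inherits(spec, "phantom_spec"))
  lo <- apply(spec$breast_centers - spec$breast_semiaxes, 2, min)
  hi <- apply(spec$breast_centers + spec$breast_semiaxes, 2, max)
  cw <- spec$chest_wall_ap
  gx <- seq(min(lo["lr"], -16), max(hi["lr"], 16), by = spacing)
  gy <- seq(min(lo["ap"], cw), max(hi["ap"], cw + 12), by = spacing)
  gz <- seq(min(lo["si"], -14), max(hi["si"], 14), by = spacing)

  breast_coords <- function(side) {
    ctr <- spec$breast_centers[side, ]
    ax <- spec$breast_semiaxes[side, ]
    # evaluate only inside the ellipsoid bounding box
    sx <- gx[gx >= ctr[1] - ax[1] & gx <= ctr[1] + ax[1]]
    sy <- gy[gy >= ctr[2] - ax[2] & gy <= ctr[2] + ax[2]]
    sz <- gz[gz >= ctr[3] - ax[3] & gz <= ctr[3] + ax[3]]
    pts <- expand.grid(lr = sx, ap = sy, si = sz, KEEP.OUT.ATTRS = FALSE)
    r2 <- ((pts$lr - ctr[1]) / ax[1])^2 + ((pts$ap - ctr[2]) / ax[2])^2 +
      ((pts$si - ctr[3]) / ax[3])^2
    as.matrix(pts[r2 <= 1, , drop = FALSE])
  }
  tx <- gx[abs(gx) <= 16]
  ty <- gy[gy >= cw & gy <= cw + 12]
  tz <- gz[abs(gz) <= 14]
  thorax <- as.matrix(expand.grid(lr = tx, ap = ty, si = tz, KEEP.OUT.ATTRS = FALSE))

  structure(list(
    left = breast_coords("left"), right = breast_coords("right"),
    thorax = thorax, spacing = spacing, frame = "patient-cm"
  ), class = "phantom_masks")
}

coords_in_box <- function(coords, box) {
  lo <- box_lo(box); hi <- box_hi(box)
  coords[, 1] >= lo[1] & coords[, 1] <= hi[1] &
    coords[, 2] >= lo[2] & coords[, 2] <= hi[2] &
    coords[, 3] >= lo[3] & coords[, 3] <= hi[3]
}

#' Check a bilateral pre-scan placement against the placement guidelines
#'
#' Evaluates the four placement goals for a pair of pre-scan boxes: (1) each
#' breast is fully inside its box, (2) every box face lies within
#' `margin_tol` cm of the corresponding breast extremum, (3) at most
#' `thorax_frac_max` of each box volume intersects the thorax block, and
#' (4) the two boxes do not overlap.
#'
#' @param boxes list with [box3d()] elements `left` and `right` (as returned
#'   by [prescan_params_to_boxes()]).
#' @param masks a [phantom_masks()] object in the same (patient-cm) frame.
#' @param margin_tol largest allowed face margin, cm.
#' @param thorax_frac_max largest allowed thorax fraction of the box volume.
#' @return A list with logical `goal1`..`goal4`, `all_pass`, and a numeric
#'   `detail` list (worst margins, thorax fractions, pair intersection
#'   volume).
#' @export
check_guidelines <- function(boxes, masks, margin_tol = 1.5, thorax_frac_max = 0.2) {
  if (!inherits(masks, "phantom_masks") || !identical(masks$frame, "patient-cm")) {
    stop("masks must be phantom_masks in the patient-cm frame", call. = FALSE)
  }
  stopifnot(inherits(boxes$left, "box3d"), inherits(boxes$right, "box3d"))

  side_stats <- lapply(c("left", "right"), function(side) {
    bx <- boxes[[side]]
    coords <- masks[[side]]
    inside <- coords_in_box(coords, bx)
    ext_lo <- apply(coords, 2, min)
    ext_hi <- apply(coords, 2, max)
    margins <- c(ext_lo - box_lo(bx), box_hi(bx) - ext_hi)
    thorax_frac <- sum(coords_in_box(masks$thorax, bx)) * masks$spacing^3 / volume(bx)
    list(contained = all(inside), max_margin = max(margins), thorax_frac = thorax_frac)
  })
  names(side_stats) <- c("left", "right")

  ov <- axis_overlap(box_lo(boxes$left), box_hi(boxes$left),
                     box_lo(boxes$right), box_hi(boxes$right))
  pair_intersection <- prod(ov)

  res <- list(
    goal1 = side_stats$left$contained && side_stats$right$contained,
    goal2 = max(side_stats$left$max_margin, side_stats$right$max_margin) <= margin_tol,
    goal3 = max(side_stats$left$thorax_frac, side_stats$right$thorax_frac) <= thorax_frac_max,
    goal4 = pair_intersection == 0,
    detail = list(
      max_margin = c(left = side_stats$left$max_margin,
                     right = side_stats$right$max_margin),
      thorax_frac = c(left = side_stats$left$thorax_frac,
                      right = side_stats$right$thorax_frac),
      pair_intersection = pair_intersection
    )
  )
  res$all_pass <- res$goal1 && res$goal2 && res$goal3 && res$goal4
  res
}
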