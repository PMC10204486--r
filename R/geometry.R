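#' Axis-aligned 3D box in the patient frame
#'
#' Boxes are the geometric currency of the package: every prescribed volume
#' (scan or pre-scan) is an axis-aligned cuboid in continuous patient
#' coordinates. The frame convention used throughout is LR = +x (patient left
#' positive), AP = +y (posterior positive), SI = +z (superior positive), all
#' in centimetres.
#'
#' @param center numeric length-3, box center `(lr, ap, si)` in cm.
#' @param size numeric length-3, edge lengths `(lr, ap, si)` in cm; must be
#'   strictly positive.
#' @return An object of class `box3d` with fields `center` and `size`.
#' @examples
#' b <- box3d(c(0, 0, 0), c(10, 10, 10))
#' volume(b)
#' @export
box3d <- function(center, size) {
  center <- as.numeric(center)
  size <- as.numeric(size)
  if (length(center) != 3L || length(size) != 3L) {
    stop("`center` and `size` must each have length 3", call. = FALSE)
  }
  if (any(!is.finite(center)) || any(!is.finite(size))) {
    stop("box coordinates must be finite", call. = FALSE)
  }
  if (any(size <= 0)) {
    stop("box sizes must be strictly positive", call. = FALSE)
  }
  names(center) <- names(size) <- c("lr", "ap", "si")
  structure(list(center = center, size = size), class = "box3d")
}

#' @export
print.box3d <- function(x, ...) {
  cat(sprintf(
    "<box3d> center (%.2f, %.2f, %.2f) cm, size %.2f x %.2f x %.2f cm\n",
    x$center[1], x$center[2], x$center[3], x$size[1], x$size[2], x$size[3]
  ))
  invisible(x)
}

#' Box volume in cubic centimetres
#' @param box a [box3d()]
#' @return numeric scalar, cm^3.
#' @export
volume <- function(box) {
  stopifnot(inherits(box, "box3d"))
  prod(box$size)
}

box_lo <- function(box) box$center - box$size / 2
box_hi <- function(box) box$center + box$size / 2

assert_box <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "box3d")) {
    stop(sprintf("`%s` must be a box3d object", arg), call. = FALSE)
  }
  invisible(x)
}

# Smallest permitted edge when sanitising degenerate predicted sizes (cm).
# Evaluation of a badly trained model must be total, so metric code clamps
# rather than erroring.
MIN_BOX_EDGE <- 0.1

#' Clamp non-positive box sizes to a small positive edge
#'
#' Predicted sizes from an untrained regressor can be non-positive; metrics
#' must still be computable. Sizes below `min_edge` are clamped with a
#' warning.
#'
#' @param center,size numeric length-3 vectors in cm.
#' @param min_edge smallest permitted edge length in cm.
#' @return a valid [box3d()].
#' @export
clamp_box <- function(center, size, min_edge = MIN_BOX_EDGE) {
  size <- as.numeric(size)
  if (any(size < min_edge)) {
    warning(sprintf(
      "degenerate box size(s) clamped to %.2f cm: [%s]",
      min_edge, paste(sprintf("%.3f", size), collapse = ", ")
    ), call. = FALSE)
    size <- pmax(size, min_edge)
  }
  box3d(center, size)
}

#' Five-parameter scan volume
#'
#' The diagnostic scan volume is square in the axial plane: its LR and AP
#' sizes both equal the axial field of view, with a separate SI coverage.
#'
#' @param pos_lr,pos_ap,pos_si volume center in cm (patient frame).
#' @param fov_axial axial field of view in cm (> 0); the LR and AP edge.
#' @param si_coverage SI extent in cm (> 0).
#' @return An object of class `scan_params` (numeric length 5 in the
#'   canonical order `pos_lr, pos_ap, pos_si, fov_axial, si_coverage`).
#' @export
scan_params <- function(pos_lr, pos_ap, pos_si, fov_axial, si_coverage) {
  p <- c(
    pos_lr = as.numeric(pos_lr), pos_ap = as.numeric(pos_ap),
    pos_si = as.numeric(pos_si), fov_axial = as.numeric(fov_axial),
    si_coverage = as.numeric(si_coverage)
  )
  if (any(!is.finite(p))) stop("scan parameters must be finite", call. = FALSE)
  if (p[["fov_axial"]] <= 0 || p[["si_coverage"]] <= 0) {
    stop("fov_axial and si_coverage must be strictly positive", call. = FALSE)
  }
  structure(p, class = "scan_params")
}

#' Nine-parameter bilateral pre-scan volume pair
#'
#' The two local-calibration (pre-scan) volumes are positioned independently,
#' one over each breast, but share a common size, giving nine free values.
#'
#' @param left_center,right_center numeric length-3 centers `(lr, ap, si)` cm.
#' @param size numeric length-3 shared size `(lr, ap, si)` cm, all > 0.
#' @return An object of class `prescan_params` (numeric length 9 in the
#'   canonical order `left lr/ap/si, right lr/ap/si, size lr/ap/si`).
#' @export
prescan_params <- function(left_center, right_center, size) {
  left_center <- as.numeric(left_center)
  right_center <- as.numeric(right_center)
  size <- as.numeric(size)
  stopifnot(length(left_center) == 3L, length(right_center) == 3L, length(size) == 3L)
  p <- c(left_center, right_center, size)
  if (any(!is.finite(p))) stop("pre-scan parameters must be finite", call. = FALSE)
  if (any(size <= 0)) {
    stop("shared pre-scan size must be strictly positive", call. = FALSE)
  }
  names(p) <- c(
    "left_lr", "left_ap", "left_si",
    "right_lr", "right_ap", "right_si",
    "size_lr", "size_ap", "size_si"
  )
  structure(p, class = "prescan_params")
}

#' Convert scan parameters to a box
#' @param p a [scan_params()] object or numeric length-5 vector in canonical
#'   order.
#' @return a [box3d()] with sizes `(fov_axial, fov_axial, si_coverage)`.
#' @export
scan_params_to_box <- function(p) {
  p <- as.numeric(unclass(p))
  if (length(p) != 5L) stop("scan parameter vector must have length 5", call. = FALSE)
  if (p[4] <= 0 || p[5] <= 0) {
    stop("fov_axial and si_coverage must be strictly positive", call. = FALSE)
  }
  box3d(center = p[1:3], size = c(p[4], p[4], p[5]))
}

#' Convert pre-scan parameters to the two bilateral boxes
#' @param p a [prescan_params()] object or numeric length-9 vector in
#'   canonical order.
#' @return a list with elements `left` and `right`, two [box3d()] of
#'   identical size.
#' @export
prescan_params_to_boxes <- function(p) {
  p <- as.numeric(unclass(p))
  if (length(p) != 9L) stop("pre-scan parameter vector must have length 9", call. = FALSE)
  if (any(p[7:9] <= 0)) {
    stop("shared pre-scan size must be strictly positive", call. = FALSE)
  }
  list(
    left = box3d(center = p[1:3], size = p[7:9]),
    right = box3d(center = p[4:6], size = p[7:9])
  )
}

# Per-axis overlap length of two intervals given (lo, hi) pairs; >= 0.
axis_overlap <- function(lo_a, hi_a, lo_b, hi_b) {
  pmax(0, pmin(hi_a, hi_b) - pmax(lo_a, lo_b))
}

#' 3D intersection over union of two boxes
#'
#' Intersection volume divided by union volume; 0 for disjoint boxes, 1 iff
#' the boxes coincide. Symmetric.
#'
#' @param a,b [box3d()] objects.
#' @return numeric in `[0, 1]`.
#' @export
iou3d <- function(a, b) {
  assert_box(a); assert_box(b)
  inter <- prod(axis_overlap(box_lo(a), box_hi(a), box_lo(b), box_hi(b)))
  union <- volume(a) + volume(b) - inter
  inter / union
}

#' 3D generalized intersection over union
#'
#' `IoU(a, b) - (|C| - |a U b|) / |C|` where `C` is the smallest axis-aligned
#' box enclosing both. Equals the IoU when the enclosing box carries no empty
#' space beyond the union, and tends to -1 as two disjoint boxes separate
#' infinitely; usable as a training signal even with zero overlap.
#'
#' @param a,b [box3d()] objects.
#' @return numeric in `(-1, 1]`.
#' @export
giou3d <- function(a, b) {
  assert_box(a); assert_box(b)
  inter <- prod(axis_overlap(box_lo(a), box_hi(a), box_lo(b), box_hi(b)))
  union <- volume(a) + volume(b) - inter
  enclosing <- prod(pmax(box_hi(a), box_hi(b)) - pmin(box_lo(a), box_lo(b)))
  inter / union - (enclosing - union) / enclosing
}

# plane -> indices of the two in-plane axes (the third is projected away)
PLANE_AXES <- list(
  axial = c(1L, 2L),    # LR, AP (SI projected)
  sagittal = c(2L, 3L), # AP, SI (LR projected)
  coronal = c(1L, 3L)   # LR, SI (AP projected)
)

#' 2D IoU of box projections onto an anatomical plane
#'
#' Projects both cuboids onto the axial (LR-AP), sagittal (AP-SI) or coronal
#' (LR-SI) plane and returns the rectangle IoU.
#'
#' @param a,b [box3d()] objects.
#' @param plane one of `"axial"`, `"sagittal"`, `"coronal"`.
#' @return numeric in `[0, 1]`.
#' @export
projected_iou <- function(a, b, plane = c("axial", "sagittal", "coronal")) {
  assert_box(a); assert_box(b)
  plane <- match.arg(plane)
  ax <- PLANE_AXES[[plane]]
  ov <- axis_overlap(box_lo(a)[ax], box_hi(a)[ax], box_lo(b)[ax], box_hi(b)[ax])
  inter <- prod(ov)
  union <- prod(a$size[ax]) + prod(b$size[ax]) - inter
  inter / union
}

#' Euclidean distance between box centers (cm)
#' @param a,b [box3d()] objects.
#' @return numeric >= 0.
#' @export
center_distance <- function(a, b) {
  assert_box(a); assert_box(b)
  sqrt(sum((a$center - b$center)^2))
}

#' Signed percent volume error of a prediction against a reference
#'
#' `100 * (vol(pred) - vol(ref)) / vol(ref)`. Positive when the prediction is
#' too large. Asymmetric by construction.
#'
#' @param pred,ref [box3d()] objects.
#' @return numeric percent (signed).
#' @export
volume_error <- function(pred, ref) {
  assert_box(pred); assert_box(ref)
  100 * (volume(pred) - volume(ref)) / volume(ref)
}

#' Percent of the reference volume covered by the prediction
#'
#' `100 * vol(ref intersect pred) / vol(ref)` — the fraction of the
#' human-placed volume that the predicted volume captures. Asymmetric: the
#' reference is always the denominator.
#'
#' @param ref,pred [box3d()] objects.
#' @return numeric in `[0, 100]`.
#' @export
overlap_fraction <- function(ref, pred) {
  assert_box(ref); assert_box(pred)
  inter <- prod(axis_overlap(box_lo(ref), box_hi(ref), box_lo(pred), box_hi(pred)))
  100 * inter / volume(ref)
}

#' Root-mean-squared error between two placement parameter vectors (cm)
#' @param pred,truth equal-length numeric vectors (5 scan or 9 pre-scan
#'   parameters, all in cm).
#' @return numeric >= 0.
#' @export
param_rmse <- function(pred, truth) {
  pred <- as.numeric(unclass(pred))
  truth <- as.numeric(unclass(truth))
  if (length(pred) != length(truth)) {
    stop("parameter vectors must have equal length", call. = FALSE)
  }
  sqrt(mean((pred - truth)^2))
}

#' Combined IoU of a full exam placement
#'
#' The sum of the scan-volume and both pre-scan-volume 3D IoU scores; ranges
#' from 0 (no agreement anywhere) to 3 (all three volumes exact).
#'
#' @param scan_iou,left_iou,right_iou numerics in `[0, 1]`.
#' @return numeric in `[0, 3]`.
#' @export
combined_iou <- function(scan_iou, left_iou, right_iou) {
  vals <- c(scan_iou, left_iou, right_iou)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("all IoU inputs must lie in [0, 1]", call. = FALSE)
  }
  scan_iou + left_iou + right_iou
}
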