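# Training losses. Both losses operate on placement parameter vectors; the
# GIoU loss converts parameters to boxes in centimetres first. Gradients are
# analytic and verified against finite differences in the test suite.

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
softplus_inv <- function(y) y + log(-expm1(-y))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Root-mean-squared-error loss over a parameter batch
#'
#' @param pred,truth numeric matrices (`head_size x N`) or equal-length
#'   vectors of placement parameters.
#' @param gradient also return the gradient with respect to `pred`?
#' @return the scalar loss, or (with `gradient = TRUE`) a list with `value`
#'   and `grad`.
#' @export
loss_rmse <- function(pred, truth, gradient = FALSE) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth))) {
    stop("pred and truth must have identical shapes", call. = FALSE)
  }
  diff <- pred - truth
  value <- sqrt(mean(diff^2))
  if (!gradient) return(value)
  grad <- if (value > 0) diff / (length(diff) * value) else diff * 0
  list(value = value, grad = grad)
}

# GIoU and its gradient w.r.t. the predicted box, one box pair, all in cm.
# Subgradients are taken at the (measure-zero) kinks of min/max.
giou_box_grad <- function(cp, sp, ct, st) {
  lo_p <- cp - sp / 2; hi_p <- cp + sp / 2
  lo_t <- ct - st / 2; hi_t <- ct + st / 2
  I <- pmax(0, pmin(hi_p, hi_t) - pmax(lo_p, lo_t))
  E <- pmax(hi_p, hi_t) - pmin(lo_p, lo_t)
  VI <- prod(I)
  Vp <- prod(sp)
  Vt <- prod(st)
  U <- Vp + Vt - VI
  C <- prod(E)
  G <- VI / U - (C - U) / C

  gVI <- (U + VI) / U^2 - 1 / C
  gVp <- -VI / U^2 + 1 / C
  gC <- -U / C^2

  oth <- function(v) vapply(1:3, function(d) prod(v[-d]), 0)
  VI_oth <- oth(I)
  C_oth <- oth(E)

  active <- I > 0
  dI_dlo <- -as.numeric(lo_p > lo_t & active)
  dI_dhi <- as.numeric(hi_p < hi_t & active)
  dE_dlo <- -as.numeric(lo_p < lo_t)
  dE_dhi <- as.numeric(hi_p > hi_t)

  dG_dlo <- gVI * VI_oth * dI_dlo + gC * C_oth * dE_dlo
  dG_dhi <- gVI * VI_oth * dI_dhi + gC * C_oth * dE_dhi
  dG_dc <- dG_dlo + dG_dhi
  dG_ds <- (-dG_dlo + dG_dhi) / 2 + gVp * oth(sp)
  list(giou = G, dcenter = dG_dc, dsize = dG_ds)
}

# Split a cm-scale parameter vector into predicted boxes. Predicted sizes go
# through a softplus so raw regression outputs always yield valid boxes;
# truth sizes are used as given.
giou_loss_single <- function(pred, truth, head_size) {
  if (head_size == 5L) {
    sp_raw <- pred[4:5]
    sp <- softplus(sp_raw)
    g <- giou_box_grad(pred[1:3], c(sp[1], sp[1], sp[2]),
                       truth[1:3], c(truth[4], truth[4], truth[5]))
    grad <- numeric(5)
    grad[1:3] <- -g$dcenter
    grad[4] <- -(g$dsize[1] + g$dsize[2]) * sigmoid(sp_raw[1])
    grad[5] <- -g$dsize[3] * sigmoid(sp_raw[2])
    list(value = 1 - g$giou, grad = grad)
  } else {
    s_raw <- pred[7:9]
    sp <- softplus(s_raw)
    st <- truth[7:9]
    gl <- giou_box_grad(pred[1:3], sp, truth[1:3], st)
    gr <- giou_box_grad(pred[4:6], sp, truth[4:6], st)
    grad <- numeric(9)
    grad[1:3] <- -gl$dcenter / 2
    grad[4:6] <- -gr$dcenter / 2
    grad[7:9] <- -(gl$dsize + gr$dsize) / 2 * sigmoid(s_raw)
    list(value = 1 - (gl$giou + gr$giou) / 2, grad = grad)
  }
}

#' 3D GIoU loss over a parameter batch
#'
#' Converts each predicted/true parameter vector to its box(es) in cm and
#' returns the mean of `1 - GIoU3D` over boxes and batch items (for the
#' 9-parameter head the two bilateral boxes are averaged). Predicted size
#' parameters pass through a softplus transform so that raw regression
#' outputs always produce valid boxes; the loss is 0 iff all boxes coincide
#' and stays below 2 even for arbitrarily separated boxes.
#'
#' @param pred,truth numeric matrices (`head_size x N`) or vectors of
#'   placement parameters in cm (canonical [scan_params()] /
#'   [prescan_params()] order).
#' @param head_size 5 or 9.
#' @param gradient also return the gradient with respect to `pred`?
#' @return the scalar loss, or (with `gradient = TRUE`) a list with `value`
#'   and `grad`.
#' @export
loss_giou <- function(pred, truth, head_size = nrow(as.matrix(pred)),
                      gradient = FALSE) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth))) {
    stop("pred and truth must have identical shapes", call. = FALSE)
  }
  head_size <- as.integer(head_size)
  if (!head_size %in% c(5L, 9L) || nrow(pred) != head_size) {
    stop("head_size must be 5 or 9 and match the parameter rows", call. = FALSE)
  }
  n <- ncol(pred)
  value <- 0
  grad <- matrix(0, head_size, n)
  for (i in seq_len(n)) {
    res <- giou_loss_single(pred[, i], truth[, i], head_size)
    value <- value + res$value / n
    grad[, i] <- res$grad / n
  }
  if (!gradient) return(value)
  list(value = value, grad = grad)
}
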