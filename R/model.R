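#' Configuration for the placement regressor
#'
#' The regressor is an AlexNet-style network: five convolutional layers
#' (kernels 11/5/3/3/3, strides 4/1/1/1/1, max-pooling after layers 1, 2 and
#' 5) followed by three fully connected layers, with dropout between the
#' fully connected layers only. Channel and hidden widths are the AlexNet
#' widths scaled by `width_multiplier` so that CPU training stays practical.
#' The head emits 5 (scan volume) or 9 (bilateral pre-scan) normalized
#' placement parameters.
#'
#' Outputs are normalized by `ref_length` (cm): the network regresses
#' `parameter / ref_length`, and all metrics are computed after conversion
#' back to centimetres. The default of 45 cm matches the upper range of
#' clinical scout fields of view.
#'
#' @param head_size 5 for the scan-volume model, 9 for the pre-scan model.
#' @param dropout_rate dropout probability between FC layers, in `[0, 1)`.
#' @param input_resolution square input mask resolution in pixels.
#' @param width_multiplier scale on AlexNet channel/hidden widths.
#' @param ref_length normalization length in cm.
#' @param seed integer seed for weight initialization.
#' @return An object of class `placement_model_config`.
#' @export
placement_model_config <- function(head_size = 5L,
                                   dropout_rate = 0.5,
                                   input_resolution = 224L,
                                   width_multiplier = 0.25,
                                   ref_length = 45,
                                   seed = 1L) {
  head_size <- as.integer(head_size)
  if (!head_size %in% c(5L, 9L)) {
    stop("head_size must be 5 (scan) or 9 (pre-scan)", call. = FALSE)
  }
  if (!is.finite(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  if (input_resolution < 16L) {
    stop("input_resolution must be at least 16 pixels", call. = FALSE)
  }
  structure(list(
    head_size = head_size,
    dropout_rate = dropout_rate,
    input_resolution = as.integer(input_resolution),
    width_multiplier = width_multiplier,
    ref_length = ref_length,
    seed = as.integer(seed)
  ), class = "placement_model_config")
}

# AlexNet base widths scaled by the multiplier.
model_widths <- function(cfg) {
  conv <- pmax(4L, as.integer(round(c(96, 256, 384, 384, 256) * cfg$width_multiplier)))
  fc <- pmax(8L, as.integer(round(c(4096, 4096) * cfg$width_multiplier)))
  list(conv = conv, fc = fc)
}

# Per-layer spatial dimension table shared with the C++ kernels.
# Columns: k, stride, pad, H_in, W_in, oH, oW, pool, pH, pW.
conv_arch <- function(cfg) {
  k <- c(11L, 5L, 3L, 3L, 3L)
  stride <- c(4L, 1L, 1L, 1L, 1L)
  pad <- c(2L, 2L, 1L, 1L, 1L)
  pool_after <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  H <- cfg$input_resolution
  arch <- matrix(0L, nrow = 5L, ncol = 10L)
  for (l in 1:5) {
    oH <- (H + 2L * pad[l] - k[l]) %/% stride[l] + 1L
    if (oH < 1L) stop("input resolution too small for the conv stack", call. = FALSE)
    # pool only when the map is large enough for a 3x3 window
    pool <- pool_after[l] && oH >= 3L
    pH <- if (pool) (oH - 3L) %/% 2L + 1L else oH
    arch[l, ] <- c(k[l], stride[l], pad[l], H, H, oH, oH, as.integer(pool), pH, pH)
    H <- pH
  }
  arch
}

#' Build a placement model with seeded initialization
#'
#' Weights use He initialization for conv/ReLU layers and Glorot-style
#' scaling for the linear head; biases start at zero. Two builds with the
#' same config and seed are identical.
#'
#' @param cfg a [placement_model_config()].
#' @return An object of class `placement_model`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "placement_model_config"))
  widths <- model_widths(cfg)
  arch <- conv_arch(cfg)
  flat_dim <- widths$conv[5] * arch[5, 9] * arch[5, 10]
  fc_dims <- c(flat_dim, widths$fc, cfg$head_size)

  model <- with_seed(cfg$seed, {
    in_ch <- c(3L, widths$conv[-5])
    conv <- vector("list", 5L)
    for (l in 1:5) {
      fan_in <- in_ch[l] * arch[l, 1]^2
      conv[[l]] <- list(
        W = matrix(stats::rnorm(widths$conv[l] * fan_in, sd = sqrt(2 / fan_in)),
                   nrow = widths$conv[l]),
        b = numeric(widths$conv[l])
      )
    }
    fc <- vector("list", 3L)
    for (l in 1:3) {
      sd_l <- if (l < 3L) sqrt(2 / fc_dims[l]) else sqrt(1 / fc_dims[l])
      fc[[l]] <- list(
        W = matrix(stats::rnorm(fc_dims[l + 1] * fc_dims[l], sd = sd_l),
                   nrow = fc_dims[l + 1]),
        b = numeric(fc_dims[l + 1])
      )
    }
    list(conv = conv, fc = fc)
  })
  structure(list(
    cfg = cfg, conv = model$conv, fc = model$fc,
    arch = arch, flat_dim = flat_dim
  ), class = "placement_model")
}

#' @export
print.placement_model <- function(x, ...) {
  widths <- model_widths(x$cfg)
  cat(sprintf(
    paste0("<placement_model> head %d, input %dx%dx3, conv channels [%s], ",
           "fc [%s], dropout %.2f\n"),
    x$cfg$head_size, x$cfg$input_resolution, x$cfg$input_resolution,
    paste(widths$conv, collapse = ", "), paste(widths$fc, collapse = ", "),
    x$cfg$dropout_rate
  ))
  invisible(x)
}

# Coerce input masks to the (C, H*W, N) cube layout the C++ kernels expect.
# Accepts a mask_triplet, an [res, res, 3] array, or an [res, res, 3, N]
# batch.
input_cube <- function(model, x) {
  res <- model$cfg$input_resolution
  if (inherits(x, "mask_triplet")) x <- mask_array(x)
  d <- dim(x)
  if (is.null(d) || !length(d) %in% c(3L, 4L)) {
    stop("input must be an [res, res, 3] array or [res, res, 3, N] batch", call. = FALSE)
  }
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  d <- dim(x)
  if (d[1] != res || d[2] != res || d[3] != 3L) {
    stop(sprintf(
      "input resolution mismatch: model expects %dx%dx3, got %dx%dx%d",
      res, res, d[1], d[2], d[3]
    ), call. = FALSE)
  }
  x <- aperm(x, c(3L, 1L, 2L, 4L))
  dim(x) <- c(3L, res * res, d[4])
  x
}

# Inverted-dropout mask: scaled at train time so inference needs no scaling.
dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nrow = nr)
}

# Full forward pass; keep_cache retains intermediates for backprop.
# Dropout masks are drawn from the R RNG, so callers control reproducibility
# through set.seed()/with_seed().
forward_pass <- function(model, x, dropout_active = FALSE, keep_cache = FALSE) {
  xc <- input_cube(model, x)
  Ws <- lapply(model$conv, `[[`, "W")
  bs <- lapply(model$conv, `[[`, "b")
  cv <- conv_stack_forward(xc, Ws, bs, model$arch)
  feat <- cv$feat
  n <- ncol(feat)
  rate <- if (dropout_active) model$cfg$dropout_rate else 0

  z1 <- model$fc[[1]]$W %*% feat + model$fc[[1]]$b
  a1 <- pmax(z1, 0)
  m1 <- dropout_mask(nrow(a1), n, rate)
  d1 <- if (is.null(m1)) a1 else a1 * m1

  z2 <- model$fc[[2]]$W %*% d1 + model$fc[[2]]$b
  a2 <- pmax(z2, 0)
  m2 <- dropout_mask(nrow(a2), n, rate)
  d2 <- if (is.null(m2)) a2 else a2 * m2

  out <- model$fc[[3]]$W %*% d2 + model$fc[[3]]$b
  if (!keep_cache) return(out)
  list(out = out, cache = list(
    xc = xc, conv = cv, feat = feat,
    a1 = a1, m1 = m1, d1 = d1, a2 = a2, m2 = m2, d2 = d2
  ))
}

#' Forward pass of the placement model
#'
#' Maps three binary scout masks (stacked as channels) to the normalized
#' placement parameter vector. With `dropout_active = FALSE` the pass is
#' deterministic; with dropout active, repeated passes sample the
#' Monte-Carlo-dropout predictive distribution.
#'
#' @param model a [build_model()] result.
#' @param masks a [make_masks()] triplet, an `[res, res, 3]` array, or an
#'   `[res, res, 3, N]` batch.
#' @param dropout_active keep dropout sampling on (Monte Carlo mode)?
#' @return A numeric matrix `head_size x N` of normalized parameters (divide
#'   by nothing — multiply by `cfg$ref_length` for cm, see
#'   [denormalize_params()]).
#' @export
model_forward <- function(model, masks, dropout_active = FALSE) {
  stopifnot(inherits(model, "placement_model"))
  forward_pass(model, masks, dropout_active = dropout_active)
}

# Gradient of the network for a given upstream gradient on the outputs.
# Returns grads in the same nested structure as the parameters.
backward_pass <- function(model, cache, dout) {
  dW3 <- tcrossprod(dout, cache$d2)
  db3 <- rowSums(dout)
  dd2 <- crossprod(model$fc[[3]]$W, dout)
  da2 <- if (is.null(cache$m2)) dd2 else dd2 * cache$m2
  dz2 <- da2 * (cache$a2 > 0)

  dW2 <- tcrossprod(dz2, cache$d1)
  db2 <- rowSums(dz2)
  dd1 <- crossprod(model$fc[[2]]$W, dz2)
  da1 <- if (is.null(cache$m1)) dd1 else dd1 * cache$m1
  dz1 <- da1 * (cache$a1 > 0)

  dW1 <- tcrossprod(dz1, cache$feat)
  db1 <- rowSums(dz1)
  dfeat <- crossprod(model$fc[[1]]$W, dz1)

  Ws <- lapply(model$conv, `[[`, "W")
  dconv <- conv_stack_backward(
    dfeat, cache$xc, cache$conv$acts, cache$conv$pooled,
    cache$conv$poolidx, Ws, model$arch
  )
  list(
    conv = lapply(1:5, function(l) list(W = dconv$dWs[[l]], b = as.numeric(dconv$dbs[[l]]))),
    fc = list(
      list(W = dW1, b = db1),
      list(W = dW2, b = db2),
      list(W = dW3, b = db3)
    )
  )
}

#' Convert normalized network outputs to centimetres
#'
#' @param v numeric vector or matrix of normalized parameters.
#' @param cfg the model's [placement_model_config()] (uses `ref_length`).
#' @return same shape as `v`, in cm.
#' @export
denormalize_params <- function(v, cfg) {
  v * cfg$ref_length
}

#' Convert centimetre parameters to the normalized scale
#' @inheritParams denormalize_params
#' @return same shape as `v`, normalized.
#' @export
normalize_params <- function(v, cfg) {
  v / cfg$ref_length
}

#' Save / load a placement model
#'
#' Checkpoints embed the full configuration, so a loaded model is usable
#' without external context.
#'
#' @param model a `placement_model`.
#' @param path file path (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "placement_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "placement_model")) {
    stop("file does not contain a placement_model", call. = FALSE)
  }
  model
}
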