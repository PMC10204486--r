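#' Training configuration
#'
#' Defaults follow the training regimen used for the placement models:
#' RMSprop, batch size 32, five-fold cross-validation and five-times shift
#' augmentation. The loss defaults differ by head because they perform
#' differently: RMSE for the 5-parameter scan head and GIoU for the
#' 9-parameter pre-scan head (see [default_loss_for_head()]).
#'
#' @param loss `"rmse"` or `"giou"`.
#' @param batch_size minibatch size (>= 1).
#' @param learning_rate RMSprop learning rate; `NULL` picks a per-loss
#'   default (1e-4 for RMSE, 1e-3 for GIoU — the GIoU loss needs larger
#'   steps to escape its near-flat regime when predicted boxes are small and
#'   disjoint from the target).
#' @param rho RMSprop decay of the squared-gradient average.
#' @param epochs training epochs per fold.
#' @param folds cross-validation folds (>= 2).
#' @param augment shifted copies per source case (>= 1).
#' @param max_shift largest augmentation shift per axis, cm.
#' @param seed integer seed controlling splits, shifts, initialization,
#'   shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(loss = c("rmse", "giou"),
                         batch_size = 32L,
                         learning_rate = NULL,
                         rho = 0.9,
                         epochs = 30L,
                         folds = 5L,
                         augment = 5L,
                         max_shift = 3,
                         seed = 1L) {
  loss <- match.arg(loss)
  learning_rate <- learning_rate %||% if (loss == "rmse") 1e-4 else 1e-3
  folds <- as.integer(folds)
  augment <- as.integer(augment)
  batch_size <- as.integer(batch_size)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (augment < 1L) stop("augment must be >= 1", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(
    loss = loss, batch_size = batch_size, learning_rate = learning_rate,
    rho = rho, epochs = as.integer(epochs), folds = folds, augment = augment,
    max_shift = max_shift, seed = as.integer(seed)
  ), class = "train_config")
}

#' Default loss for a head size
#'
#' RMSE for the scan model and GIoU for the pre-scan model, the combination
#' found to maximize held-out 3D IoU for each head.
#'
#' @param head_size 5 or 9.
#' @return `"rmse"` or `"giou"`.
#' @export
default_loss_for_head <- function(head_size) {
  if (as.integer(head_size) == 5L) "rmse" else "giou"
}

#' Shift-augment a mask triplet and its placement targets
#'
#' Translates the anatomy by `shift` (cm, patient frame). Each mask moves by
#' the shift's two in-plane components (axial: LR/AP, sagittal: AP/SI,
#' coronal: LR/SI); position targets move by the same shift and size targets
#' are unchanged. The shift must be a whole number of pixels under every
#' mask's affine, and must not push foreground outside the frame.
#'
#' @param masks a [make_masks()] triplet.
#' @param targets a [scan_params()] or [prescan_params()] object (cm).
#' @param shift numeric length-3 `(lr, ap, si)` shift in cm.
#' @return list with shifted `masks` and `targets`.
#' @export
augment_shift <- function(masks, targets, shift) {
  stopifnot(inherits(masks, "mask_triplet"))
  shift <- as.numeric(shift)
  stopifnot(length(shift) == 3L)
  names(shift) <- c("lr", "ap", "si")

  shifted <- masks
  for (o in c("axial", "sagittal", "coronal")) {
    plane <- masks[[o]]
    inplane <- shift[plane$axes]
    px <- inplane / plane$spacing
    if (any(abs(px - round(px)) > 1e-6)) {
      stop(sprintf(
        "shift (%s) cm is not a whole number of pixels for the %s mask",
        paste(sprintf("%.3f", shift), collapse = ", "), o
      ), call. = FALSE)
    }
    px <- as.integer(round(px))
    m <- plane$mask
    n <- nrow(m)
    out <- matrix(0L, n, n)
    src_i <- seq_len(n) - px[1]
    src_j <- seq_len(n) - px[2]
    ok_i <- src_i >= 1L & src_i <= n
    ok_j <- src_j >= 1L & src_j <= n
    out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
    if (sum(out) != sum(m)) {
      stop("shift pushes mask foreground outside the frame", call. = FALSE)
    }
    shifted[[o]]$mask <- out
  }

  if (inherits(targets, "scan_params")) {
    p <- unclass(targets)
    p[1:3] <- p[1:3] + shift
    targets <- scan_params(p[1], p[2], p[3], p[4], p[5])
  } else if (inherits(targets, "prescan_params")) {
    p <- unclass(targets)
    p[1:6] <- p[1:6] + rep(shift, 2)
    targets <- prescan_params(p[1:3], p[4:6], p[7:9])
  } else {
    stop("targets must be scan_params or prescan_params", call. = FALSE)
  }
  list(masks = shifted, targets = targets)
}

#' Deterministic k-fold partition
#'
#' Partitions case indices into `folds` disjoint, exhaustive groups whose
#' sizes differ by at most one; the assignment is a seeded random
#' permutation. Augmented copies of a case must always inherit the source
#' case's fold, which [train_model()] enforces.
#'
#' @param n_cases number of source cases.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold labels (1..folds), one per case.
#' @export
kfold_split <- function(n_cases, folds, seed) {
  n_cases <- as.integer(n_cases)
  folds <- as.integer(folds)
  if (n_cases < folds) stop("n_cases must be >= folds", call. = FALSE)
  with_seed(seed, {
    perm <- sample.int(n_cases)
    fold <- integer(n_cases)
    fold[perm] <- rep_len(seq_len(folds), n_cases)
    fold
  })
}

#' Assemble a training case from a phantom
#'
#' Preprocesses the scout into masks at the model resolution and attaches
#' the ground-truth parameters for the requested head.
#'
#' @param phantom a [generate_phantom()] result.
#' @param head_size 5 (scan) or 9 (pre-scan).
#' @param resolution mask resolution in pixels.
#' @param id case identifier.
#' @return list with `id`, `masks` (mask_triplet) and `target` (cm
#'   parameters).
#' @export
build_case <- function(phantom, head_size, resolution, id = NULL) {
  stopifnot(inherits(phantom, "phantom_case"))
  masks <- make_masks(phantom$scout, out_resolution = resolution)
  target <- if (as.integer(head_size) == 5L) phantom$scan_truth else phantom$prescan_truth
  list(id = id %||% "case", masks = masks, target = target)
}

# Draw a whole-pixel augmentation shift within +/- max_shift cm. Retries if
# the shift would clip foreground; falls back to the zero shift.
draw_shift_case <- function(case, max_shift) {
  spacing <- case$masks$axial$spacing[1]
  max_px <- floor(max_shift / spacing)
  for (try in 1:20) {
    px <- sample(seq(-max_px, max_px), 3L, replace = TRUE)
    shift <- px * spacing
    out <- tryCatch(augment_shift(case$masks, case$target, shift),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  list(masks = case$masks, targets = case$target)
}

# Flatten parameter objects to the canonical numeric vector.
param_vector <- function(p) as.numeric(unclass(p))

# RMSprop update over the nested parameter list (fused C++ step).
rmsprop_update <- function(model, grads, cache, lr, rho, eps = 1e-8) {
  upd <- function(p, g, c) rmsprop_step(p, g, c, lr, rho, eps)
  for (l in seq_along(model$conv)) {
    u <- upd(model$conv[[l]]$W, grads$conv[[l]]$W, cache$conv[[l]]$W)
    model$conv[[l]]$W <- u$p; cache$conv[[l]]$W <- u$c
    u <- upd(model$conv[[l]]$b, grads$conv[[l]]$b, cache$conv[[l]]$b)
    model$conv[[l]]$b <- u$p; cache$conv[[l]]$b <- u$c
  }
  for (l in seq_along(model$fc)) {
    u <- upd(model$fc[[l]]$W, grads$fc[[l]]$W, cache$fc[[l]]$W)
    model$fc[[l]]$W <- u$p; cache$fc[[l]]$W <- u$c
    u <- upd(model$fc[[l]]$b, grads$fc[[l]]$b, cache$fc[[l]]$b)
    model$fc[[l]]$b <- u$p; cache$fc[[l]]$b <- u$c
  }
  list(model = model, cache = cache)
}

zero_like_params <- function(model) {
  list(
    conv = lapply(model$conv, function(p) list(W = p$W * 0, b = p$b * 0)),
    fc = lapply(model$fc, function(p) list(W = p$W * 0, b = p$b * 0))
  )
}

# Batch loss + gradient on normalized network outputs.
batch_loss <- function(out, truth_norm, loss, head_size, ref_length, gradient = TRUE) {
  if (loss == "rmse") {
    r <- loss_rmse(out, truth_norm, gradient = gradient)
  } else {
    r <- loss_giou(out * ref_length, truth_norm * ref_length,
                   head_size = head_size, gradient = gradient)
    if (gradient) r$grad <- r$grad * ref_length
  }
  r
}

#' Train placement models with k-fold cross-validation
#'
#' Augments every case with `cfg$augment` shifted copies (replacing the
#' original; one copy may carry the zero shift), partitions the source cases
#' into folds — augmented copies always share their source's fold — and
#' trains one model per fold on the out-of-fold data with RMSprop. All
#' randomness (splits, shifts, initialization, shuffling, dropout) derives
#' from `cfg$seed`, so identical configurations reproduce identical models.
#'
#' @param cases list of [build_case()] results (all with the same head and
#'   resolution).
#' @param model_cfg a [placement_model_config()].
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses?
#' @return An object of class `train_result`: per-fold `models`,
#'   `fold_assignment` (per source case), a per-epoch `log` data frame, and
#'   the configurations.
#' @export
train_model <- function(cases, model_cfg, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model_cfg, "placement_model_config"), inherits(cfg, "train_config"))
  n <- length(cases)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  if (n < cfg$folds) stop("fewer cases than folds", call. = FALSE)
  head_size <- model_cfg$head_size
  res <- model_cfg$input_resolution
  L <- model_cfg$ref_length

  fold_assignment <- kfold_split(n, cfg$folds, derive_seed(cfg$seed, 1L))

  # Build the augmented design: each case contributes `augment` shifted
  # copies tagged with the source index (and hence the source's fold).
  m <- n * cfg$augment
  X <- array(0, dim = c(res, res, 3L, m))
  Y <- matrix(0, head_size, m)
  src <- integer(m)
  with_seed(derive_seed(cfg$seed, 2L), {
    j <- 0L
    for (i in seq_len(n)) {
      tv <- param_vector(cases[[i]]$target)
      if (length(tv) != head_size) {
        stop("case target length does not match the model head", call. = FALSE)
      }
      for (a in seq_len(cfg$augment)) {
        j <- j + 1L
        aug <- draw_shift_case(cases[[i]], cfg$max_shift)
        X[, , , j] <- mask_array(aug$masks)
        Y[, j] <- param_vector(aug$targets) / L
        src[j] <- i
      }
    }
  })

  models <- vector("list", cfg$folds)
  log_rows <- list()
  for (f in seq_len(cfg$folds)) {
    train_idx <- which(fold_assignment[src] != f)
    val_idx <- which(fold_assignment[src] == f)
    # leakage guard: no source case on both sides of the split
    if (length(intersect(src[train_idx], src[val_idx])) > 0L) {
      stop("internal error: fold leakage detected", call. = FALSE)
    }
    fold_cfg <- model_cfg
    fold_cfg$seed <- derive_seed(cfg$seed, 100L + f)
    model <- build_model(fold_cfg)
    cache <- zero_like_params(model)

    with_seed(derive_seed(cfg$seed, 200L + f), {
      for (epoch in seq_len(cfg$epochs)) {
        ord <- sample(train_idx)
        nb <- ceiling(length(ord) / cfg$batch_size)
        epoch_loss <- 0
        for (b in seq_len(nb)) {
          idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, length(ord))]
          fw <- forward_pass(model, X[, , , idx, drop = FALSE],
                             dropout_active = TRUE, keep_cache = TRUE)
          lg <- batch_loss(fw$out, Y[, idx, drop = FALSE], cfg$loss,
                           head_size, L, gradient = TRUE)
          grads <- backward_pass(model, fw$cache, lg$grad)
          u <- rmsprop_update(model, grads, cache, cfg$learning_rate, cfg$rho)
          model <- u$model; cache <- u$cache
          epoch_loss <- epoch_loss + lg$value * length(idx)
        }
        train_loss <- epoch_loss / length(train_idx)
        val_out <- forward_pass(model, X[, , , val_idx, drop = FALSE],
                                dropout_active = FALSE)
        val_loss <- batch_loss(val_out, Y[, val_idx, drop = FALSE], cfg$loss,
                               head_size, L, gradient = FALSE)
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          fold = f, epoch = epoch, train_loss = train_loss, val_loss = val_loss
        )
        if (verbose) {
          message(sprintf("fold %d epoch %3d  train %.5f  val %.5f",
                          f, epoch, train_loss, val_loss))
        }
      }
    })
    models[[f]] <- model
  }

  structure(list(
    models = models,
    fold_assignment = fold_assignment,
    log = do.call(rbind, log_rows),
    model_cfg = model_cfg,
    train_cfg = cfg
  ), class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  last <- x$log[x$log$epoch == max(x$log$epoch), ]
  cat(sprintf(
    "<train_result> %d folds, %d epochs, loss %s; final val loss %.4f (mean)\n",
    x$train_cfg$folds, x$train_cfg$epochs, x$train_cfg$loss, mean(last$val_loss)
  ))
  invisible(x)
}
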