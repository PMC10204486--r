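#' Monte-Carlo-dropout prediction with per-parameter uncertainty
#'
#' Runs `T` stochastic forward passes with dropout kept active, then reports
#' the element-wise mean as the placement prediction and the sample standard
#' deviation as its uncertainty, both in centimetres. With `T = 1` the mean
#' equals the single pass and the standard deviation is reported as 0 with
#' `sd_defined = FALSE`; with a dropout rate of 0 all passes coincide and
#' the uncertainty is exactly 0.
#'
#' @param model a trained [build_model()] / [train_model()] model.
#' @param masks a [make_masks()] triplet or input array at the model
#'   resolution.
#' @param T number of Monte Carlo passes (>= 1); 100 by default.
#' @param seed optional integer seed for the dropout sampling.
#' @param keep_samples retain the `head_size x T` matrix of raw samples?
#' @return An object of class `placement_prediction`: `mean` and `sd`
#'   (cm, canonical parameter order), `T`, `head_size`, `sd_defined`, and
#'   optionally `samples`.
#' @export
mc_dropout_predict <- function(model, masks, T = 100L, seed = NULL,
                               keep_samples = FALSE) {
  stopifnot(inherits(model, "placement_model"))
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1", call. = FALSE)
  x <- if (inherits(masks, "mask_triplet")) mask_array(masks) else masks
  d <- dim(x)
  if (length(d) != 3L) stop("masks must describe a single case", call. = FALSE)
  samples <- if (model$cfg$dropout_rate == 0) {
    # point-mass predictive distribution: one deterministic pass suffices
    # (and guarantees exactly zero spread)
    out <- forward_pass(model, x, dropout_active = TRUE)
    matrix(out, nrow(out), T)
  } else {
    batch <- array(x, dim = c(d, T)) # same input replicated; dropout varies
    with_seed(seed, forward_pass(model, batch, dropout_active = TRUE))
  }
  samples_cm <- denormalize_params(samples, model$cfg)

  mean_cm <- rowMeans(samples_cm)
  sd_defined <- T > 1L
  sd_cm <- if (sd_defined) apply(samples_cm, 1, stats::sd) else rep(0, nrow(samples_cm))
  # identical passes (e.g. dropout rate 0) must report exactly zero spread,
  # not the rounding residue of mean subtraction
  degenerate <- apply(samples_cm, 1, function(r) all(r == r[1]))
  sd_cm[degenerate] <- 0
  param_names <- if (model$cfg$head_size == 5L) {
    c("pos_lr", "pos_ap", "pos_si", "fov_axial", "si_coverage")
  } else {
    c("left_lr", "left_ap", "left_si", "right_lr", "right_ap", "right_si",
      "size_lr", "size_ap", "size_si")
  }
  names(mean_cm) <- names(sd_cm) <- param_names
  structure(list(
    mean = mean_cm, sd = sd_cm, T = T,
    head_size = model$cfg$head_size, sd_defined = sd_defined,
    samples = if (keep_samples) samples_cm else NULL
  ), class = "placement_prediction")
}

#' @export
print.placement_prediction <- function(x, ...) {
  cat(sprintf("<placement_prediction> head %d, T = %d passes\n", x$head_size, x$T))
  print(round(rbind(mean_cm = x$mean, sd_cm = x$sd), 2))
  invisible(x)
}

#' Convert a prediction to its volume box(es)
#'
#' Maps the Monte-Carlo mean parameters to one scan box (head 5) or the two
#' bilateral pre-scan boxes (head 9). Non-positive predicted sizes are
#' clamped to a small positive edge with a warning rather than erroring, so
#' evaluation of a badly trained model never crashes.
#'
#' @param pred a [mc_dropout_predict()] result.
#' @return a [box3d()] for head 5, or a list `left`/`right` for head 9.
#' @export
prediction_to_volumes <- function(pred) {
  stopifnot(inherits(pred, "placement_prediction"))
  p <- as.numeric(pred$mean)
  if (pred$head_size == 5L) {
    clamp_box(p[1:3], c(p[4], p[4], p[5]))
  } else {
    size <- pmax(p[7:9], 0)
    left <- clamp_box(p[1:3], size)
    # reuse the clamped size so the shared-size constraint survives clamping
    right <- box3d(p[4:6], left$size)
    list(left = left, right = right)
  }
}

#' Held-out Monte Carlo predictions for every case of a cross-validated run
#'
#' Each case is predicted by the model of the fold in which it was held out,
#' so no prediction ever comes from a model that saw the case in training.
#'
#' @param result a [train_model()] result.
#' @param cases the same case list the result was trained on.
#' @param T Monte Carlo passes per case.
#' @param seed integer seed; per-case seeds are derived from it.
#' @return list of [mc_dropout_predict()] objects, one per case.
#' @export
heldout_predictions <- function(result, cases, T = 100L, seed = 1L) {
  stopifnot(inherits(result, "train_result"))
  if (length(cases) != length(result$fold_assignment)) {
    stop("cases do not match the training run", call. = FALSE)
  }
  lapply(seq_along(cases), function(i) {
    f <- result$fold_assignment[i]
    mc_dropout_predict(result$models[[f]], cases[[i]]$masks, T = T,
                       seed = derive_seed(seed, i))
  })
}
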