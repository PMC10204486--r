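sp_inv <- scoutbox:::softplus_inv

test_that("RMSE loss matches its closed form and rejects shape mismatches", {
  expect_equal(loss_rmse(matrix(1:10, 5), matrix(1:10, 5)), 0)
  expect_equal(loss_rmse(matrix(2, 5, 3), matrix(1, 5, 3)), 1)
  expect_equal(loss_rmse(c(3, 4, 0, 0, 0), rep(0, 5)), sqrt(5))
  expect_error(loss_rmse(matrix(0, 5, 2), matrix(0, 5, 3)), "identical shapes")

  g <- loss_rmse(c(1, 1, 0, 0, 0), rep(0, 5), gradient = TRUE)
  num <- sapply(1:5, function(i) {
    e <- rep(0, 5); e[i] <- 1e-6
    (loss_rmse(c(1, 1, 0, 0, 0) + e, rep(0, 5)) -
       loss_rmse(c(1, 1, 0, 0, 0) - e, rep(0, 5))) / 2e-6
  })
  expect_equal(as.numeric(g$grad), num, tolerance = 1e-6)
})

test_that("GIoU loss reproduces closed-form box cases for both heads", {
  # identical boxes: zero loss (sizes inverted through the softplus)
  p <- c(1, 2, 3, sp_inv(10), sp_inv(8))
  expect_equal(loss_giou(p, c(1, 2, 3, 10, 8), 5), 0, tolerance = 1e-12)

  # unit cubes at separation 3: 1 - (-0.5) = 1.5
  expect_equal(loss_giou(c(3, 0, 0, sp_inv(1), sp_inv(1)), c(0, 0, 0, 1, 1), 5), 1.5)

  # bilateral: one perfect box and one offset box average their losses
  truth9 <- c(7, 0, 0, -7, 0, 0, 4, 4, 4)
  pred9 <- c(7, 0, 0, -7 + 2, 0, 0, sp_inv(4), sp_inv(4), sp_inv(4))
  right_only <- 1 - giou3d(box3d(c(-5, 0, 0), c(4, 4, 4)),
                           box3d(c(-7, 0, 0), c(4, 4, 4)))
  expect_equal(loss_giou(pred9, truth9, 9), (0 + right_only) / 2, tolerance = 1e-12)

  expect_error(loss_giou(matrix(0, 5, 2), matrix(0, 5, 3), 5), "identical shapes")
  expect_error(loss_giou(matrix(0, 4, 2), matrix(0, 4, 2), 4), "head_size")

  # loss stays in [0, 2) even for far-separated boxes
  far <- loss_giou(c(500, 0, 0, sp_inv(1), sp_inv(1)), c(0, 0, 0, 1, 1), 5)
  expect_gt(far, 1); expect_lt(far, 2)
})

test_that("GIoU loss gradients match finite differences for both heads", {
  set.seed(31)
  num_grad <- function(p, t, h) {
    sapply(seq_along(p), function(i) {
      e <- numeric(length(p)); e[i] <- 1e-6
      (loss_giou(p + e, t, h) - loss_giou(p - e, t, h)) / 2e-6
    })
  }
  for (r in 1:5) {
    p <- c(stats::runif(3, -3, 3), stats::runif(2, 2, 12))
    t <- c(stats::runif(3, -3, 3), stats::runif(2, 3, 12))
    g <- loss_giou(p, t, 5, gradient = TRUE)$grad
    expect_equal(as.numeric(g), num_grad(p, t, 5), tolerance = 1e-5)
  }
  for (r in 1:5) {
    p <- c(stats::runif(6, -8, 8), stats::runif(3, 2, 10))
    t <- c(stats::runif(3, 2, 8), stats::runif(3, -8, -2), stats::runif(3, 3, 10))
    g <- loss_giou(p, t, 9, gradient = TRUE)$grad
    expect_equal(as.numeric(g), num_grad(p, t, 9), tolerance = 1e-5)
  }
})

test_that("shift augmentation moves masks and position targets coherently", {
  case <- tiny_cases(1, 5L, resolution = 32L)[[1]]
  spacing <- case$masks$axial$spacing[1]

  # zero shift is the identity
  z <- augment_shift(case$masks, case$target, c(0, 0, 0))
  expect_identical(z$masks, case$masks)
  expect_identical(z$targets, case$target)

  # one-pixel LR shift moves axial and coronal masks, leaves sagittal alone
  s <- c(spacing, 0, 0)
  a <- augment_shift(case$masks, case$target, s)
  expect_identical(a$masks$sagittal$mask, case$masks$sagittal$mask)
  expect_false(identical(a$masks$axial$mask, case$masks$axial$mask))
  expect_equal(sum(a$masks$axial$mask), sum(case$masks$axial$mask))
  expect_equal(unclass(a$targets)[["pos_lr"]],
               unclass(case$target)[["pos_lr"]] + spacing)
  expect_equal(unclass(a$targets)[["fov_axial"]], unclass(case$target)[["fov_axial"]])

  # content moved toward +LR by one pixel
  expect_equal(a$masks$axial$mask[2:32, ], case$masks$axial$mask[1:31, ])

  # non-integer pixel shifts and foreground-clipping shifts are rejected
  expect_error(augment_shift(case$masks, case$target, c(spacing / 3, 0, 0)),
               "whole number of pixels")
  expect_error(augment_shift(case$masks, case$target, c(spacing * 20, 0, 0)),
               "foreground")
})

test_that("shifting input and target together leaves both losses invariant", {
  case <- tiny_cases(1, 9L, resolution = 32L)[[1]]
  spacing <- case$masks$axial$spacing[1]
  truth <- as.numeric(unclass(case$target))
  pred <- truth + c(rep(0.8, 6), rep(0, 3))
  pred[7:9] <- sp_inv(truth[7:9] * 1.1)

  for (px in list(c(1, 0, 0), c(0, -2, 1), c(1, 2, -2))) {
    s <- px * spacing
    shifted <- augment_shift(case$masks, case$target, s)
    truth_s <- as.numeric(unclass(shifted$targets))
    pred_s <- pred; pred_s[1:6] <- pred[1:6] + rep(s, 2)
    expect_equal(loss_giou(pred_s, truth_s, 9), loss_giou(pred, truth, 9),
                 tolerance = 1e-10)
    expect_equal(loss_rmse(pred_s, truth_s), loss_rmse(pred, truth),
                 tolerance = 1e-10)
  }
})

test_that("k-fold splits partition cases evenly and deterministically", {
  f <- kfold_split(10, 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))
  expect_identical(f, kfold_split(10, 5, seed = 3))
  expect_false(identical(f, kfold_split(10, 5, seed = 4)))

  f2 <- kfold_split(13, 5, seed = 1)
  expect_lte(diff(range(table(f2))), 1)
  expect_equal(length(f2), 13L)
  expect_error(kfold_split(3, 5, seed = 1), ">= folds")
})

test_that("a short seeded training run learns and reproduces exactly", {
  cases <- tiny_cases(20, 5L, resolution = 32L)
  mcfg <- placement_model_config(5L, input_resolution = 32L, seed = 2L)
  tcfg <- train_config(loss = "rmse", epochs = 3L, folds = 2L, batch_size = 16L,
                       seed = 17L)
  r1 <- train_model(cases, mcfg, tcfg)

  # augmentation bookkeeping: 5 shifted copies per source case
  expect_equal(nrow(r1$log), 3L * 2L)
  first <- r1$log$train_loss[r1$log$epoch == 1]
  last <- r1$log$train_loss[r1$log$epoch == 3]
  expect_true(all(last < first))

  # exact reproducibility of the whole pipeline under one seed
  r2 <- train_model(cases, mcfg, tcfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$models[[1]]$fc, r2$models[[1]]$fc)

  # both losses run to completion on the same data
  r3 <- train_model(cases, mcfg,
                    train_config(loss = "giou", epochs = 1L, folds = 2L, seed = 17L))
  expect_s3_class(r3, "train_result")

  expect_error(train_model(list(), mcfg, tcfg), "empty")
  expect_error(train_model(cases[1], mcfg, tcfg), "fewer cases than folds")
})
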