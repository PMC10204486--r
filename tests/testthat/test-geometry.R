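test_that("box construction validates sizes and parameter conversions map fields", {
  b <- box3d(c(1, 2, 3), c(10, 10, 10))
  expect_equal(unname(b$center), c(1, 2, 3))
  expect_equal(volume(b), 1000)
  expect_error(box3d(c(0, 0, 0), c(0, 1, 1)), "positive")
  expect_error(box3d(c(0, 0), c(1, 1, 1)), "length 3")

  # square axial footprint from the 5-parameter scan description
  sb <- scan_params_to_box(scan_params(0, 0, 0, 33, 19))
  expect_equal(unname(sb$size), c(33, 33, 19))
  sb2 <- scan_params_to_box(c(1, 2, 3, 10, 10))
  expect_equal(unname(sb2$center), c(1, 2, 3))
  expect_equal(unname(sb2$size), c(10, 10, 10))
  expect_error(scan_params(0, 0, 0, 0, 10), "positive")
  expect_error(scan_params_to_box(c(0, 0, 0, 0, 10)), "positive")

  # bilateral pair shares one size
  pp <- prescan_params_to_boxes(prescan_params(c(7, 0, 0), c(-7, 0, 0),
                                               c(13, 11, 16)))
  expect_equal(pp$left$size, pp$right$size)
  expect_equal(unname(pp$left$size), c(13, 11, 16))
  expect_error(prescan_params(c(7, 0, 0), c(-7, 0, 0), c(0, 1, 1)), "positive")
  # coincident centers are geometrically legal
  same <- prescan_params_to_boxes(prescan_params(c(0, 0, 0), c(0, 0, 0), c(5, 5, 5)))
  expect_equal(same$left$center, same$right$center)
})

test_that("IoU, distance, volume error and overlap reproduce the worked cube cases", {
  cube10 <- box3d(c(0, 0, 0), c(10, 10, 10))
  cube11 <- box3d(c(0, 0, 0), c(11, 11, 11))
  shifted <- box3d(c(1, 1, 1), c(10, 10, 10))

  expect_equal(iou3d(cube10, cube11), 1000 / 1331)
  expect_equal(iou3d(cube10, shifted), 729 / 1271)
  expect_equal(iou3d(cube10, cube10), 1)
  expect_equal(center_distance(cube10, shifted), sqrt(3))
  expect_equal(center_distance(cube10, cube10), 0)
  expect_equal(center_distance(cube10, box3d(c(3, 4, 0), c(1, 1, 1))), 5)
  expect_equal(volume_error(cube11, cube10), 33.1)
  expect_equal(volume_error(cube10, cube10), 0)
  expect_equal(volume_error(box3d(c(0, 0, 0), c(5, 5, 5)), cube10), -87.5)
  expect_equal(overlap_fraction(cube10, shifted), 72.9)
  expect_equal(overlap_fraction(cube10, cube11), 100)
  expect_equal(overlap_fraction(cube10, box3d(c(50, 0, 0), c(1, 1, 1))), 0)

  expect_equal(projected_iou(cube10, shifted, "axial"), 81 / 119)
  expect_equal(projected_iou(cube10, cube10, "sagittal"), 1)
  expect_equal(projected_iou(cube10, box3d(c(30, 30, 0), c(2, 2, 2)), "axial"), 0)
  expect_error(projected_iou(cube10, cube10, "oblique"))
})

test_that("GIoU equals IoU under a tight enclosure and penalizes separation", {
  cube10 <- box3d(c(0, 0, 0), c(10, 10, 10))
  cube11 <- box3d(c(0, 0, 0), c(11, 11, 11))
  expect_equal(giou3d(cube10, cube11), iou3d(cube10, cube11))
  expect_equal(giou3d(cube10, cube10), 1)
  u1 <- box3d(c(0, 0, 0), c(1, 1, 1))
  u2 <- box3d(c(3, 0, 0), c(1, 1, 1))
  expect_equal(giou3d(u1, u2), -0.5)
})

test_that("parameter RMSE follows the quadratic mean of element errors", {
  expect_equal(param_rmse(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 0)
  expect_equal(param_rmse(rep(1, 9), rep(0, 9)), 1)
  expect_equal(param_rmse(c(3, 4, 0, 0, 0), rep(0, 5)), sqrt(5))
  expect_error(param_rmse(1:5, 1:9), "equal length")
})

test_that("combined IoU sums the three volume scores and validates its domain", {
  expect_equal(combined_iou(1, 1, 1), 3)
  expect_equal(combined_iou(0, 0, 0), 0)
  expect_equal(combined_iou(0.69, 0.68, 0.65), 2.02)
  expect_error(combined_iou(1.2, 0, 0), "\\[0, 1\\]")
  expect_error(combined_iou(-0.1, 0, 0), "\\[0, 1\\]")
})

test_that("metric symmetries, translation invariance and identity hold on random pairs", {
  set.seed(71)
  for (i in 1:50) {
    a <- random_box(); b <- random_box()
    expect_equal(iou3d(a, b), iou3d(b, a))
    expect_equal(giou3d(a, b), giou3d(b, a))
    expect_equal(center_distance(a, b), center_distance(b, a))
    expect_lte(giou3d(a, b), iou3d(a, b) + 1e-12)

    # the same rigid translation applied to both boxes changes nothing
    t <- stats::runif(3, -20, 20)
    at <- box3d(a$center + t, a$size)
    bt <- box3d(b$center + t, b$size)
    expect_equal(iou3d(at, bt), iou3d(a, b), tolerance = 1e-10)
    expect_equal(giou3d(at, bt), giou3d(a, b), tolerance = 1e-10)
    expect_equal(volume_error(at, bt), volume_error(a, b), tolerance = 1e-10)
    expect_equal(overlap_fraction(at, bt), overlap_fraction(a, b), tolerance = 1e-10)
  }
  # iou3d(a, b) = 1 iff the boxes coincide
  a <- random_box()
  expect_equal(iou3d(a, box3d(a$center, a$size)), 1)
  expect_lt(iou3d(a, box3d(a$center + 0.01, a$size)), 1)

  # overlap_fraction and volume_error are asymmetric by construction
  big <- box3d(c(0, 0, 0), c(10, 10, 10))
  small <- box3d(c(0, 0, 0), c(5, 5, 5))
  expect_false(isTRUE(all.equal(overlap_fraction(big, small),
                                overlap_fraction(small, big))))
  expect_false(isTRUE(all.equal(volume_error(big, small),
                                volume_error(small, big))))
})

test_that("degenerate predicted sizes are clamped with a warning", {
  expect_warning(b <- clamp_box(c(0, 0, 0), c(-1, 0.01, 5)), "clamped")
  expect_true(all(b$size >= 0.1))
  expect_equal(unname(b$size[3]), 5)
})
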