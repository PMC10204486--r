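test_that("phantom generation is bit-identical for a fixed spec", {
  a <- tiny_phantom(3)
  b <- tiny_phantom(3)
  expect_identical(a, b)
  c <- tiny_phantom(4)
  expect_false(identical(a$scout$axial$img, c$scout$axial$img))
})

test_that("a mirror-symmetric spec yields mirror-symmetric ground truth", {
  semi <- rbind(left = c(5.5, 4.5, 7), right = c(5.5, 4.5, 7))
  ctr <- rbind(left = c(7, -5.5, 0), right = c(-7, -5.5, 0))
  spec <- phantom_spec(semi, ctr, noise = 0, grid_n = 64L, seed = 9L)
  ph <- generate_phantom(spec)
  p <- unclass(ph$prescan_truth)
  expect_equal(p[["left_lr"]], -p[["right_lr"]])
  expect_equal(p[["left_ap"]], p[["right_ap"]])
  expect_equal(p[["left_si"]], p[["right_si"]])
  boxes <- prescan_params_to_boxes(ph$prescan_truth)
  expect_identical(boxes$left$size, boxes$right$size)
  # scan volume centered on the midline for symmetric anatomy
  expect_equal(unclass(ph$scan_truth)[["pos_lr"]], 0)
})

test_that("ground truth encodes the placement goals: margin, midline, axilla", {
  semi <- rbind(left = c(5, 4, 7), right = c(5, 4, 7))
  ctr <- rbind(left = c(7, -5, 1), right = c(-7, -5, 1))
  spec <- phantom_spec(semi, ctr, noise = 0, grid_n = 64L, seed = 2L)
  ph <- generate_phantom(spec)
  boxes <- prescan_params_to_boxes(ph$prescan_truth)
  # 1 cm margin on unclipped faces of the breast bounding box
  expect_equal(unname(boxes$left$center - boxes$left$size / 2),
               c(7 - 5 - 1, -5 - 4 - 1, 1 - 7 - 1))
  # scan: covers expanded boxes, square axial, 2 cm extra superiorly
  sp <- unclass(ph$scan_truth)
  expect_equal(sp[["fov_axial"]], (7 + 5 + 1) * 2)
  expect_equal(sp[["si_coverage"]], (7 + 1) * 2 + 2)
  expect_equal(sp[["pos_si"]], 1 + 1)

  # breasts close to the midline: expanded boxes are clipped, never overlap
  ctr2 <- rbind(left = c(5.3, -5, 0), right = c(-5.3, -5, 0))
  ph2 <- generate_phantom(phantom_spec(semi, ctr2, noise = 0, grid_n = 64L))
  b2 <- prescan_params_to_boxes(ph2$prescan_truth)
  expect_gte(b2$left$center[["lr"]] - b2$left$size[["lr"]] / 2, 0)
  expect_lte(b2$right$center[["lr"]] + b2$right$size[["lr"]] / 2, 0)
  expect_equal(iou3d(b2$left, b2$right), 0)
})

test_that("generated ground truth passes the guideline checker across random specs", {
  n_pass <- 0L
  for (i in 1:100) {
    spec <- random_phantom_spec(i + 1000L)
    gt <- scoutbox:::phantom_ground_truth(spec)
    ck <- check_guidelines(prescan_params_to_boxes(gt$prescan),
                           phantom_masks(spec, spacing = 0.25))
    n_pass <- n_pass + ck$all_pass
  }
  expect_equal(n_pass, 100L)
})

test_that("the guideline checker flags shrunken and midline-translated boxes", {
  spec <- tiny_spec(5)
  gt <- scoutbox:::phantom_ground_truth(spec)
  boxes <- prescan_params_to_boxes(gt$prescan)
  masks <- phantom_masks(spec, spacing = 0.25)
  expect_true(check_guidelines(boxes, masks)$all_pass)

  shrunk <- list(left = box3d(boxes$left$center, boxes$left$size - 3),
                 right = box3d(boxes$right$center, boxes$right$size - 3))
  expect_false(check_guidelines(shrunk, masks)$goal1)

  onmid <- list(left = box3d(c(0, boxes$left$center[2:3]), boxes$left$size),
                right = box3d(c(0, boxes$right$center[2:3]), boxes$right$size))
  expect_false(check_guidelines(onmid, masks)$goal4)

  expect_error(check_guidelines(boxes, list(left = 1)), "phantom_masks")
})

test_that("breast tissue is strictly brighter than air in noiseless mode", {
  ph <- generate_phantom(tiny_spec(7, noise = 0))
  for (o in c("axial", "sagittal", "coronal")) {
    img <- ph$scout[[o]]$img
    expect_true(all(img >= 0))
    expect_gt(max(img), 0.99) # breast voxels present at intensity 1
  }
  # Otsu separation is guaranteed: foreground strictly above background
  m <- mip(ph$scout$axial)
  ob <- otsu_binarize(m)
  expect_gt(min(m[ob$mask == 1]), max(m[ob$mask == 0]))
})

test_that("ground-truth sizes bracket realistic clinical volume sizes", {
  sizes <- t(vapply(1:25, function(i) {
    gt <- scoutbox:::phantom_ground_truth(random_phantom_spec(i + 500L))
    c(unclass(gt$scan)[4:5], unclass(gt$prescan)[7:9])
  }, numeric(5)))
  # scan axial FOV in the 20-35 cm range, SI coverage near 15-21 cm
  expect_true(all(sizes[, 1] > 20 & sizes[, 1] < 35))
  expect_true(all(sizes[, 2] > 14 & sizes[, 2] < 22))
  # pre-scan shared size near 13 x 11 x 16 cm
  expect_true(all(abs(sizes[, 3] - 13) < 3))
  expect_true(all(abs(sizes[, 4] - 11) < 3))
  expect_true(all(abs(sizes[, 5] - 16) < 3.5))
})

test_that("overhead arms stretch the breasts in SI and narrow them axially", {
  down <- tiny_spec(11, arms = "down")
  up <- tiny_spec(11, arms = "overhead")
  expect_gt(up$breast_semiaxes["left", "si"], down$breast_semiaxes["left", "si"])
  expect_lt(up$breast_semiaxes["left", "lr"], down$breast_semiaxes["left", "lr"])
  expect_lt(up$breast_semiaxes["left", "ap"], down$breast_semiaxes["left", "ap"])
})

test_that("invalid anatomy is rejected", {
  semi <- rbind(left = c(5, 4, 7), right = c(5, 4, 7))
  expect_error(phantom_spec(semi, rbind(left = c(7, -5, 0), right = c(7, -5, 0))),
               "midline")
  expect_error(phantom_spec(semi, rbind(left = c(7, 2, 0), right = c(-7, -5, 0))),
               "anterior")
  expect_error(phantom_spec(semi * -1, rbind(left = c(7, -5, 0), right = c(-7, -5, 0))),
               "positive")
})
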