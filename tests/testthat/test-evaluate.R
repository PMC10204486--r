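test_that("case evaluation fills every metric and honors the cube worked cases", {
  cube10 <- box3d(c(0, 0, 0), c(10, 10, 10))

  perfect <- evaluate_case(cube10, cube10, pred_params = c(0, 0, 0, 10, 10),
                           truth_params = c(0, 0, 0, 10, 10), case_id = "p")
  expect_equal(perfect$iou3d, 1)
  expect_equal(perfect$center_distance, 0)
  expect_equal(perfect$volume_error, 0)
  expect_equal(perfect$overlap_pct, 100)
  expect_equal(perfect$param_rmse, 0)
  expect_true(all(c("iou_axial", "iou_sagittal", "iou_coronal") %in% names(perfect)))

  # concentric 11 cm cube: IoU 0.75, volume error +33%
  over <- evaluate_case(box3d(c(0, 0, 0), c(11, 11, 11)), cube10, case_id = "o")
  expect_equal(round(over$iou3d, 2), 0.75)
  expect_equal(round(over$volume_error), 33)

  # (1,1,1) offset cube: distance 1.7 cm, IoU 0.57
  off <- evaluate_case(box3d(c(1, 1, 1), c(10, 10, 10)), cube10, case_id = "s")
  expect_equal(round(off$center_distance, 1), 1.7)
  expect_equal(round(off$iou3d, 2), 0.57)
})

test_that("bilateral scoring matches sides by LR sign with nearest-center tie-break", {
  truth <- list(left = box3d(c(7, 0, 0), c(10, 8, 12)),
                right = box3d(c(-7, 0, 0), c(10, 8, 12)))

  # swapped prediction order must still score left against left
  pred <- list(left = box3d(c(-6.5, 0, 0), c(10, 8, 12)),
               right = box3d(c(6.5, 0, 0), c(10, 8, 12)))
  rec <- evaluate_case(pred, truth, case_id = "swap")
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$side, c("L", "R"))
  expect_gt(rec$iou3d[rec$side == "L"], 0.5)

  # same-sign centers: nearest truth center decides
  amb <- list(left = box3d(c(6, 0, 0), c(10, 8, 12)),
              right = box3d(c(1, 0, 0), c(10, 8, 12)))
  rec2 <- evaluate_case(amb, truth, case_id = "amb")
  expect_gt(rec2$iou3d[rec2$side == "L"], rec2$iou3d[rec2$side == "R"])

  expect_error(evaluate_case(box3d(c(0, 0, 0), c(1, 1, 1)), truth), "role mismatch")
})

test_that("summaries use linear-interpolation percentiles", {
  recs <- do.call(rbind, lapply(1:100, function(i) {
    evaluate_case(box3d(c(0, 0, i), c(10, 10, 10)),
                  box3d(c(0, 0, i), c(10, 10, 10)), case_id = as.character(i))
  }))
  recs$center_distance <- 1:100
  rep <- summarize_metrics(recs)
  dist_row <- rep$summary[rep$summary$metric == "center_distance", ]
  expect_equal(dist_row$p5, 5.95)     # 1 + 0.05 * 99
  expect_equal(dist_row$median, 50.5)
  expect_equal(dist_row$p95, 95.05)

  one <- summarize_metrics(recs[1, ])
  expect_true(all(one$summary$p5 == one$summary$median &
                    one$summary$median == one$summary$p95, na.rm = TRUE))

  m <- summarize_metrics(recs)
  expect_true(all(m$summary$p5 <= m$summary$median & m$summary$median <= m$summary$p95,
                  na.rm = TRUE))
  expect_error(summarize_metrics(recs[0, ]), "no records")
  expect_error(summarize_metrics(recs, group_key = "scanner"), "not found")

  recs$grp <- rep(c("a", "b"), 50)
  gr <- summarize_metrics(recs, group_key = "grp")
  expect_length(gr$groups, 2L)
  expect_equal(gr$groups$a$n, 50L)
  expect_length(gr$groups$a$iou3d_stats, 5L) # box-plot five-number summary
})

test_that("the combined-IoU report sums three volumes and excludes partial exams", {
  scan <- data.frame(case_id = c("a", "b", "c"), role = "scan",
                     iou3d = c(0.69, 1, 0.5))
  pre <- rbind(
    data.frame(case_id = c("a", "b"), role = "prescan", side = "L",
               iou3d = c(0.68, 1)),
    data.frame(case_id = c("a", "b"), role = "prescan", side = "R",
               iou3d = c(0.65, 1))
  )
  rep <- combined_report(scan, pre)
  expect_equal(rep$n, 2L)
  expect_equal(rep$n_excluded, 1L)
  a <- rep$per_case[rep$per_case$case_id == "a", ]
  expect_equal(a$ciou, 2.02)
  b <- rep$per_case[rep$per_case$case_id == "b", ]
  expect_equal(b$ciou, 3)
  expect_equal(b$iou_sd, 0)
  expect_true(all(rep$per_case$ciou >= 0 & rep$per_case$ciou <= 3))

  expect_error(combined_report(scan[0, ], pre), "no cases")
})

test_that("evaluating truth against itself over a cohort degenerates to perfection", {
  cases <- tiny_cases(4, 5L, resolution = 32L)
  recs <- do.call(rbind, lapply(cases, function(cs) {
    b <- scan_params_to_box(cs$target)
    evaluate_case(b, b, pred_params = unclass(cs$target),
                  truth_params = unclass(cs$target), case_id = cs$id)
  }))
  rep <- summarize_metrics(recs)
  expect_equal(rep$summary$median[rep$summary$metric == "iou3d"], 1)
  expect_equal(rep$summary$median[rep$summary$metric == "center_distance"], 0)
})
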