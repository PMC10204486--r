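# Cohort evaluation: per-case metric records, percentile summaries and the
# combined-IoU report.

metric_record <- function(case_id, role, side, pred_box, truth_box,
                          pred_params = NULL, truth_params = NULL) {
  data.frame(
    case_id = case_id, role = role, side = side,
    iou3d = iou3d(pred_box, truth_box),
    iou_axial = projected_iou(pred_box, truth_box, "axial"),
    iou_sagittal = projected_iou(pred_box, truth_box, "sagittal"),
    iou_coronal = projected_iou(pred_box, truth_box, "coronal"),
    center_distance = center_distance(pred_box, truth_box),
    volume_error = volume_error(pred_box, truth_box),
    overlap_pct = overlap_fraction(truth_box, pred_box),
    param_rmse = if (is.null(pred_params)) NA_real_ else
      param_rmse(pred_params, truth_params),
    stringsAsFactors = FALSE
  )
}

METRIC_COLS <- c("iou3d", "iou_axial", "iou_sagittal", "iou_coronal",
                 "center_distance", "volume_error", "overlap_pct", "param_rmse")

#' Score one case: predicted against true volumes
#'
#' Computes the full metric record (3D IoU, the three projected 2D IoUs,
#' center distance, signed percent volume error, percent overlap of the
#' reference volume, and parameter RMSE) for a scan volume or a bilateral
#' pre-scan pair. Pre-scan volumes are scored per side: the predicted box
#' whose center has positive LR is matched to the left truth box (ties
#' resolved by nearest truth center).
#'
#' @param pred a [box3d()] (scan) or list `left`/`right` of boxes
#'   (pre-scan), e.g. from [prediction_to_volumes()].
#' @param truth same structure as `pred`, the reference volumes.
#' @param pred_params,truth_params optional cm parameter vectors for the
#'   RMSE column.
#' @param case_id identifier copied into the record.
#' @return data frame with one row (scan) or two rows (pre-scan L/R).
#' @export
evaluate_case <- function(pred, truth, pred_params = NULL, truth_params = NULL,
                          case_id = "case") {
  pred_is_pair <- is.list(pred) && !inherits(pred, "box3d")
  truth_is_pair <- is.list(truth) && !inherits(truth, "box3d")
  if (pred_is_pair != truth_is_pair) {
    stop("role mismatch: prediction and truth must both be a scan box or both a pre-scan pair",
         call. = FALSE)
  }
  if (!pred_is_pair) {
    return(metric_record(case_id, "scan", NA_character_, pred, truth,
                         pred_params, truth_params))
  }

  # side assignment by sign of predicted center LR (left = +LR patient frame);
  # tie broken by nearest truth center
  boxes <- list(pred$left, pred$right)
  lr <- vapply(boxes, function(b) b$center[["lr"]], 0)
  if (sign(lr[1]) != sign(lr[2]) && all(sign(lr) != 0)) {
    pred_left <- boxes[[which(lr > 0)]]
    pred_right <- boxes[[which(lr < 0)]]
  } else {
    d_ll <- center_distance(boxes[[1]], truth$left)
    d_rl <- center_distance(boxes[[2]], truth$left)
    pred_left <- if (d_ll <= d_rl) boxes[[1]] else boxes[[2]]
    pred_right <- if (d_ll <= d_rl) boxes[[2]] else boxes[[1]]
  }
  rbind(
    metric_record(case_id, "prescan", "L", pred_left, truth$left,
                  pred_params, truth_params),
    metric_record(case_id, "prescan", "R", pred_right, truth$right,
                  pred_params, truth_params)
  )
}

# Linear-interpolation percentile (the classic order-statistic rule,
# stats::quantile type 7): the p-th percentile of n sorted values x_(1..n)
# is x_(k) interpolated at position 1 + p*(n-1)/100.
pctl <- function(x, p) unname(stats::quantile(x, p / 100, type = 7, na.rm = TRUE))

#' Summarize metric records into 5th / median / 95th percentile rows
#'
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). With a `group_key`, per-group box-plot-ready
#' summaries (median, quartiles, whiskers, outliers beyond 1.5 IQR) are
#' attached.
#'
#' @param records data frame of [evaluate_case()] rows.
#' @param group_key optional name of a grouping column in `records`.
#' @return An object of class `cohort_report`: `summary` data frame (one row
#'   per metric, columns `p5`, `median`, `p95`), the raw `records`, `n`, and
#'   optionally `groups`.
#' @export
summarize_metrics <- function(records, group_key = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no records to summarize", call. = FALSE)
  }
  cols <- intersect(METRIC_COLS, names(records))
  summary <- do.call(rbind, lapply(cols, function(cn) {
    x <- records[[cn]]
    data.frame(metric = cn, p5 = pctl(x, 5), median = pctl(x, 50),
               p95 = pctl(x, 95), stringsAsFactors = FALSE)
  }))
  groups <- NULL
  if (!is.null(group_key)) {
    if (!group_key %in% names(records)) {
      stop(sprintf("group key '%s' not found in records", group_key), call. = FALSE)
    }
    groups <- lapply(split(records, records[[group_key]]), function(g) {
      bs <- grDevices::boxplot.stats(g$iou3d)
      list(n = nrow(g), iou3d_stats = bs$stats, iou3d_outliers = bs$out,
           median_iou3d = stats::median(g$iou3d))
    })
  }
  structure(list(summary = summary, records = records, n = nrow(records),
                 groups = groups), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d records\n", x$n))
  print(transform(x$summary, p5 = round(p5, 3), median = round(median, 3),
                  p95 = round(p95, 3)), row.names = FALSE)
  invisible(x)
}

#' Combined-IoU report across exams with both volume types
#'
#' For every case present in both record sets, sums the scan, left pre-scan
#' and right pre-scan 3D IoU into the combined IoU (cIoU, range 0-3) and
#' also reports the standard deviation of the three IoUs per case. Cases
#' missing either volume type are excluded and counted.
#'
#' @param scan_records [evaluate_case()] rows with role `"scan"`.
#' @param prescan_records rows with role `"prescan"` (sides L and R).
#' @return list with `per_case` (case_id, ciou, iou_sd), `summary` (mean,
#'   median, p5, p95 of cIoU), `n`, and `n_excluded`.
#' @export
combined_report <- function(scan_records, prescan_records) {
  scan_records <- scan_records[scan_records$role == "scan", ]
  left <- prescan_records[prescan_records$role == "prescan" &
                            prescan_records$side == "L", ]
  right <- prescan_records[prescan_records$role == "prescan" &
                             prescan_records$side == "R", ]
  ids <- Reduce(intersect, list(scan_records$case_id, left$case_id, right$case_id))
  all_ids <- unique(c(scan_records$case_id, left$case_id, right$case_id))
  if (length(ids) == 0L) stop("no cases with both scan and pre-scan volumes", call. = FALSE)

  per_case <- do.call(rbind, lapply(ids, function(id) {
    ious <- c(
      scan_records$iou3d[match(id, scan_records$case_id)],
      left$iou3d[match(id, left$case_id)],
      right$iou3d[match(id, right$case_id)]
    )
    data.frame(case_id = id, ciou = combined_iou(ious[1], ious[2], ious[3]),
               iou_sd = stats::sd(ious), stringsAsFactors = FALSE)
  }))
  list(
    per_case = per_case,
    summary = c(
      mean = mean(per_case$ciou), median = pctl(per_case$ciou, 50),
      p5 = pctl(per_case$ciou, 5), p95 = pctl(per_case$ciou, 95)
    ),
    n = length(ids),
    n_excluded = length(all_ids) - length(ids)
  )
}

#' Evaluate a cross-validated training run on its own cohort
#'
#' Convenience wrapper: held-out Monte Carlo predictions for every case,
#' converted to volumes and scored against the ground truth.
#'
#' @param result a [train_model()] result.
#' @param cases the case list the result was trained on.
#' @param T Monte Carlo passes.
#' @param seed integer seed for the dropout sampling.
#' @return data frame of metric records (one row per scan case, two per
#'   pre-scan case).
#' @export
evaluate_run <- function(result, cases, T = 100L, seed = 1L) {
  preds <- heldout_predictions(result, cases, T = T, seed = seed)
  head_size <- result$model_cfg$head_size
  recs <- lapply(seq_along(cases), function(i) {
    vol <- suppressWarnings(prediction_to_volumes(preds[[i]]))
    truth <- cases[[i]]$target
    if (head_size == 5L) {
      evaluate_case(vol, scan_params_to_box(truth),
                    pred_params = preds[[i]]$mean, truth_params = truth,
                    case_id = cases[[i]]$id)
    } else {
      evaluate_case(vol, prescan_params_to_boxes(truth),
                    pred_params = preds[[i]]$mean, truth_params = truth,
                    case_id = cases[[i]]$id)
    }
  })
  do.call(rbind, recs)
}
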