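# End-to-end pipeline stages. Each run_* function is a thin, scriptable
# wrapper over the package API: it derives a stage seed from the global
# seed, does its work, and writes a resolved-config snapshot next to its
# outputs. The CLI in inst/cli/scoutbox.R dispatches to these.

STAGE_INDEX <- c(simulate = 1L, preprocess = 2L, train = 3L,
                 predict = 4L, evaluate = 5L)

write_stage_config <- function(outdir, stage, config) {
  config$stage <- stage
  config$stage_seed <- derive_seed(config$seed %||% 0L, STAGE_INDEX[[stage]])
  yaml::write_yaml(config, file.path(outdir, paste0(stage, "_config.yaml")))
}

#' Simulate a phantom dataset on disk
#'
#' Writes `n` case directories (`case_001`, ...) each holding the scout
#' NIfTI series, the ground-truth volume records (JSON) and the phantom
#' config (YAML), plus a manifest CSV with per-case truth-file checksums.
#'
#' @param n number of cases (>= 1).
#' @param outdir output directory.
#' @param seed global seed; per-case seeds are derived from it.
#' @param noise,arms,grid_n,n_slices forwarded to [random_phantom_spec()].
#' @return the manifest data frame, invisibly.
#' @export
run_simulate <- function(n, outdir, seed = 1L, noise = 0.05, arms = "down",
                         grid_n = 96L,
                         n_slices = c(axial = 12L, sagittal = 12L, coronal = 9L)) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage_seed <- derive_seed(seed, STAGE_INDEX[["simulate"]])
  rows <- lapply(seq_len(n), function(i) {
    id <- sprintf("case_%03d", i)
    case_dir <- file.path(outdir, id)
    spec <- random_phantom_spec(derive_seed(stage_seed, i), noise = noise,
                                arms = arms, grid_n = grid_n, n_slices = n_slices)
    ph <- generate_phantom(spec)
    write_scout_series(ph$scout, case_dir)
    truth_path <- file.path(case_dir, "truth.json")
    write_volume_records(truth_records(ph), truth_path)
    write_phantom_config(spec, file.path(case_dir, "phantom.yaml"))
    data.frame(id = id, dir = id, truth_md5 = unname(tools::md5sum(truth_path)),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  write_stage_config(outdir, "simulate", list(
    n = n, seed = seed, noise = noise, arms = arms, grid_n = grid_n,
    n_slices = as.list(n_slices)
  ))
  invisible(manifest)
}

read_manifest <- function(indir) {
  path <- file.path(indir, "manifest.csv")
  if (!file.exists(path)) stop("manifest.csv not found", call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Preprocess a simulated dataset into mask triplets
#'
#' Reads each case's scout series, builds the binary MIP mask triplet and
#' writes it next to the case. Cases with incomplete scouts are skipped and
#' logged rather than aborting the run.
#'
#' @param indir dataset directory from [run_simulate()].
#' @param outdir output directory (defaults to `indir`).
#' @param resolution mask resolution in pixels.
#' @return data frame listing processed and skipped cases, invisibly.
#' @export
run_preprocess <- function(indir, outdir = indir, resolution = 224L) {
  manifest <- read_manifest(indir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  status <- lapply(manifest$id, function(id) {
    out <- tryCatch({
      scout <- read_scout_series(file.path(indir, id))
      masks <- make_masks(scout, out_resolution = resolution)
      write_mask_triplet(masks, file.path(outdir, id))
      "ok"
    }, error = function(e) {
      message(sprintf("skipping %s: %s", id, conditionMessage(e)))
      conditionMessage(e)
    })
    data.frame(id = id, status = out, stringsAsFactors = FALSE)
  })
  status <- do.call(rbind, status)
  write_stage_config(outdir, "preprocess", list(
    indir = indir, resolution = as.integer(resolution), seed = 0L
  ))
  invisible(status)
}

load_cases <- function(indir, head_size, resolution) {
  manifest <- read_manifest(indir)
  lapply(manifest$id, function(id) {
    case_dir <- file.path(indir, id)
    masks_path <- file.path(case_dir, "masks.json")
    masks <- if (file.exists(masks_path)) {
      mt <- read_mask_triplet(case_dir)
      if (mt$resolution != resolution) {
        make_masks(read_scout_series(case_dir), out_resolution = resolution)
      } else mt
    } else {
      make_masks(read_scout_series(case_dir), out_resolution = resolution)
    }
    truth <- read_volume_records(file.path(case_dir, "truth.json"))
    target <- if (as.integer(head_size) == 5L) {
      b <- record_to_box(truth[truth$role == "scan", ])
      scan_params(b$center[1], b$center[2], b$center[3], b$size[1], b$size[3])
    } else {
      l <- record_to_box(truth[truth$role == "prescan_left", ])
      r <- record_to_box(truth[truth$role == "prescan_right", ])
      prescan_params(l$center, r$center, l$size)
    }
    list(id = id, masks = masks, target = target)
  })
}

#' Train placement models on a simulated dataset
#'
#' @param indir dataset directory ([run_simulate()], optionally
#'   [run_preprocess()]ed).
#' @param outdir output directory for checkpoints and logs.
#' @param head `"scan"` or `"prescan"`.
#' @param loss `"rmse"`, `"giou"`, or `NULL` for the head's default.
#' @param resolution input mask resolution.
#' @param width_multiplier,dropout model options, see
#'   [placement_model_config()].
#' @param epochs,folds,batch_size,augment,learning_rate training options,
#'   see [train_config()].
#' @param seed global seed.
#' @param verbose print per-epoch losses?
#' @return the [train_model()] result, invisibly.
#' @export
run_train <- function(indir, outdir, head = c("scan", "prescan"), loss = NULL,
                      resolution = 224L, width_multiplier = 0.25,
                      dropout = 0.5, epochs = 30L, folds = 5L,
                      batch_size = 32L, augment = 5L, learning_rate = NULL,
                      seed = 1L, verbose = FALSE) {
  head <- match.arg(head)
  head_size <- if (head == "scan") 5L else 9L
  loss <- loss %||% default_loss_for_head(head_size)
  if (!loss %in% c("rmse", "giou")) stop("loss must be rmse or giou", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage_seed <- derive_seed(seed, STAGE_INDEX[["train"]])

  cases <- load_cases(indir, head_size, resolution)
  model_cfg <- placement_model_config(
    head_size = head_size, dropout_rate = dropout,
    input_resolution = resolution, width_multiplier = width_multiplier,
    seed = stage_seed
  )
  cfg <- train_config(loss = loss, batch_size = batch_size, epochs = epochs,
                      folds = folds, augment = augment,
                      learning_rate = learning_rate, seed = stage_seed)
  result <- train_model(cases, model_cfg, cfg, verbose = verbose)

  for (f in seq_len(cfg$folds)) {
    save_model(result$models[[f]], file.path(outdir, sprintf("fold_%d.rds", f)))
  }
  utils::write.csv(result$log, file.path(outdir, "training_log.csv"),
                   row.names = FALSE)
  saveRDS(result, file.path(outdir, "train_result.rds"))
  write_stage_config(outdir, "train", list(
    indir = indir, head = head, loss = loss, resolution = as.integer(resolution),
    width_multiplier = width_multiplier, dropout = dropout,
    epochs = as.integer(epochs), folds = as.integer(folds),
    batch_size = as.integer(batch_size), augment = as.integer(augment),
    learning_rate = learning_rate, seed = seed
  ))
  invisible(result)
}

#' Predict placement for one case from a checkpoint
#'
#' @param checkpoint path to a saved fold model (`fold_k.rds`).
#' @param case_dir case directory holding a scout series (and optionally
#'   precomputed masks).
#' @param out output JSON path.
#' @param mc_passes Monte Carlo dropout passes.
#' @param seed integer seed for the dropout sampling.
#' @return the [mc_dropout_predict()] result, invisibly.
#' @export
run_predict <- function(checkpoint, case_dir, out, mc_passes = 100L, seed = 1L) {
  model <- load_model(checkpoint)
  res <- model$cfg$input_resolution
  masks_path <- file.path(case_dir, "masks.json")
  masks <- if (file.exists(masks_path)) {
    mt <- read_mask_triplet(case_dir)
    if (mt$resolution != res) {
      make_masks(read_scout_series(case_dir), out_resolution = res)
    } else mt
  } else {
    make_masks(read_scout_series(case_dir), out_resolution = res)
  }
  t0 <- Sys.time()
  pred <- mc_dropout_predict(model, masks, T = mc_passes,
                             seed = derive_seed(seed, STAGE_INDEX[["predict"]]))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  message(sprintf("prediction took %.2f s (%d passes)", elapsed, mc_passes))
  write_prediction(pred, out)
  invisible(pred)
}

#' Evaluate prediction JSONs against ground truth
#'
#' @param pred_paths named character vector of prediction JSON paths; names
#'   are case ids.
#' @param truth_dir dataset directory holding `case_id/truth.json` files.
#' @param outdir output directory for the per-case CSV and summary JSON.
#' @param group_key optional grouping column (must be present after joining;
#'   typically added by the caller to the records CSV).
#' @return the [summarize_metrics()] report, invisibly.
#' @export
run_evaluate <- function(pred_paths, truth_dir, outdir, group_key = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(pred_paths) %||% basename(dirname(pred_paths))
  recs <- list()
  for (i in seq_along(pred_paths)) {
    id <- ids[i]
    truth_path <- file.path(truth_dir, id, "truth.json")
    if (!file.exists(truth_path)) {
      stop(sprintf("no truth found for case %s", id), call. = FALSE)
    }
    truth <- read_volume_records(truth_path)
    pred <- read_prediction(pred_paths[i])
    vols <- suppressWarnings(prediction_to_volumes(pred))
    rec <- if (pred$head_size == 5L) {
      evaluate_case(vols, record_to_box(truth[truth$role == "scan", ]),
                    case_id = id)
    } else {
      evaluate_case(vols, list(
        left = record_to_box(truth[truth$role == "prescan_left", ]),
        right = record_to_box(truth[truth$role == "prescan_right", ])
      ), case_id = id)
    }
    recs[[length(recs) + 1L]] <- rec
  }
  records <- do.call(rbind, recs)
  report <- summarize_metrics(records, group_key = group_key)
  utils::write.csv(records, file.path(outdir, "per_case_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(outdir, "summary.json"),
                       digits = NA, dataframe = "rows")
  write_stage_config(outdir, "evaluate", list(
    n_predictions = length(pred_paths), truth_dir = truth_dir, seed = 0L
  ))
  invisible(report)
}
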