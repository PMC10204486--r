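# Serialization: volume records (JSON/CSV), scout series and mask triplets
# (NIfTI + JSON sidecar), predictions (JSON) and configs (YAML).

#' Tabulate volumes as flat records
#'
#' The record schema is shared by JSON and CSV output: one row per volume
#' with `role` (`scan`, `prescan_left`, `prescan_right`), center and size in
#' cm, patient frame (LR/AP/SI).
#'
#' @param boxes named list of [box3d()] objects; names are the roles.
#' @return data frame with columns `role`, `center_lr`, `center_ap`,
#'   `center_si`, `size_lr`, `size_ap`, `size_si`.
#' @export
volume_records <- function(boxes) {
  do.call(rbind, lapply(names(boxes), function(role) {
    b <- boxes[[role]]
    stopifnot(inherits(b, "box3d"))
    data.frame(
      role = role,
      center_lr = b$center[["lr"]], center_ap = b$center[["ap"]],
      center_si = b$center[["si"]],
      size_lr = b$size[["lr"]], size_ap = b$size[["ap"]],
      size_si = b$size[["si"]],
      stringsAsFactors = FALSE
    )
  }))
}

#' Ground-truth volume records of a phantom case
#' @param phantom a [generate_phantom()] result.
#' @return data frame in the [volume_records()] schema (scan +
#'   prescan_left + prescan_right).
#' @export
truth_records <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_case"))
  pre <- prescan_params_to_boxes(phantom$prescan_truth)
  volume_records(list(
    scan = scan_params_to_box(phantom$scan_truth),
    prescan_left = pre$left,
    prescan_right = pre$right
  ))
}

#' Write / read volume records
#'
#' @param records a [volume_records()] data frame.
#' @param path output path; format inferred from the `.json` / `.csv`
#'   extension unless given.
#' @param format `"json"` or `"csv"`.
#' @return `write_volume_records` returns `path` invisibly;
#'   `read_volume_records` returns the data frame.
#' @export
write_volume_records <- function(records, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "json") {
    jsonlite::write_json(records, path, digits = NA, auto_unbox = FALSE)
  } else if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else {
    stop("format must be json or csv", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_volume_records
#' @export
read_volume_records <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    stop("format must be json or csv", call. = FALSE)
  }
}

#' Convert one volume record row back to a box
#' @param record one row of a [volume_records()] data frame.
#' @return a [box3d()].
#' @export
record_to_box <- function(record) {
  box3d(
    c(record$center_lr, record$center_ap, record$center_si),
    c(record$size_lr, record$size_ap, record$size_si)
  )
}

#' Write / read a scout series as NIfTI plus a JSON sidecar
#'
#' One NIfTI file per orientation (`axial`, `sagittal`, `coronal`), with the
#' in-plane spacing in the voxel dimensions, plus `scout.json` recording the
#' per-orientation origin, spacing, in-plane axes and slice positions.
#'
#' @param scout a `scout_series`.
#' @param dir output directory (created if needed).
#' @return `write_scout_series` returns `dir` invisibly; `read_scout_series`
#'   returns the `scout_series`.
#' @export
write_scout_series <- function(scout, dir) {
  stopifnot(inherits(scout, "scout_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  for (o in c("axial", "sagittal", "coronal")) {
    stk <- scout[[o]]
    slice_gap <- if (length(stk$slice_pos) > 1) diff(stk$slice_pos[1:2]) else 1
    img <- RNifti::asNifti(stk$img, pixdim = c(stk$spacing, abs(slice_gap)))
    RNifti::writeNifti(img, file.path(dir, paste0(o, ".nii")))
    meta[[o]] <- list(
      axes = stk$axes, origin = stk$origin, spacing = stk$spacing,
      slice_pos = stk$slice_pos, orientation = o
    )
  }
  jsonlite::write_json(meta, file.path(dir, "scout.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_scout_series
#' @export
read_scout_series <- function(dir) {
  sidecar <- file.path(dir, "scout.json")
  if (!file.exists(sidecar)) stop("scout.json sidecar not found", call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  stacks <- lapply(c("axial", "sagittal", "coronal"), function(o) {
    path <- file.path(dir, paste0(o, ".nii"))
    if (!file.exists(path)) stop(sprintf("missing orientation: %s", o), call. = FALSE)
    m <- meta[[o]]
    structure(list(
      img = as.array(RNifti::readNifti(path)),
      axes = m$axes, orientation = o,
      origin = m$origin, spacing = m$spacing, slice_pos = m$slice_pos
    ), class = "scout_stack")
  })
  names(stacks) <- c("axial", "sagittal", "coronal")
  structure(stacks, class = "scout_series")
}

#' Write / read a mask triplet as NIfTI plus a JSON affine sidecar
#'
#' @param masks a [make_masks()] triplet.
#' @param dir output directory.
#' @return `write_mask_triplet` returns `dir` invisibly; `read_mask_triplet`
#'   returns the `mask_triplet`.
#' @export
write_mask_triplet <- function(masks, dir) {
  stopifnot(inherits(masks, "mask_triplet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(resolution = masks$resolution)
  for (o in c("axial", "sagittal", "coronal")) {
    plane <- masks[[o]]
    img <- RNifti::asNifti(plane$mask * 1, pixdim = plane$spacing)
    RNifti::writeNifti(img, file.path(dir, paste0("mask_", o, ".nii")))
    meta[[o]] <- list(axes = plane$axes, origin = plane$origin,
                      spacing = plane$spacing)
  }
  jsonlite::write_json(meta, file.path(dir, "masks.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_mask_triplet
#' @export
read_mask_triplet <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "masks.json"), simplifyVector = TRUE)
  planes <- lapply(c(axial = "axial", sagittal = "sagittal", coronal = "coronal"),
                   function(o) {
    m <- meta[[o]]
    mask <- as.array(RNifti::readNifti(file.path(dir, paste0("mask_", o, ".nii"))))
    list(mask = matrix(as.integer(mask), nrow = nrow(mask)),
         origin = m$origin, spacing = m$spacing, axes = m$axes)
  })
  structure(c(planes, list(resolution = as.integer(meta$resolution))),
            class = "mask_triplet")
}

#' Write a prediction as JSON
#'
#' Serializes the Monte-Carlo mean volume record(s), the per-parameter
#' uncertainty block (cm) and the number of passes.
#'
#' @param pred a [mc_dropout_predict()] result.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(pred, path) {
  stopifnot(inherits(pred, "placement_prediction"))
  vols <- suppressWarnings(prediction_to_volumes(pred))
  recs <- if (pred$head_size == 5L) {
    volume_records(list(scan = vols))
  } else {
    volume_records(list(prescan_left = vols$left, prescan_right = vols$right))
  }
  out <- list(
    head_size = pred$head_size,
    T = pred$T,
    mean_parameters_cm = as.list(pred$mean),
    uncertainty_cm = as.list(pred$sd),
    sd_defined = pred$sd_defined,
    volumes = recs
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_prediction
#' @export
read_prediction <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    mean = unlist(p$mean_parameters_cm), sd = unlist(p$uncertainty_cm),
    T = p$T, head_size = as.integer(p$head_size),
    sd_defined = isTRUE(p$sd_defined), samples = NULL
  ), class = "placement_prediction")
}

#' Write / read a phantom specification as YAML
#' @param spec a [phantom_spec()].
#' @param path `.yaml` path.
#' @return `write_phantom_config` returns `path` invisibly;
#'   `read_phantom_config` the `phantom_spec`.
#' @export
write_phantom_config <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  out <- list(
    breast_semiaxes = lapply(seq_len(2), function(i) unname(spec$breast_semiaxes[i, ])),
    breast_centers = lapply(seq_len(2), function(i) unname(spec$breast_centers[i, ])),
    chest_wall_ap = spec$chest_wall_ap, noise = spec$noise,
    arms = spec$arms, fov = spec$fov, grid_n = spec$grid_n,
    n_slices = as.list(spec$n_slices), seed = spec$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  y <- yaml::read_yaml(path)
  # the stored semi-axes are final: bypass the constructor's arm rescaling
  spec <- phantom_spec(
    breast_semiaxes = rbind(y$breast_semiaxes[[1]], y$breast_semiaxes[[2]]),
    breast_centers = rbind(y$breast_centers[[1]], y$breast_centers[[2]]),
    chest_wall_ap = y$chest_wall_ap, noise = y$noise, arms = "down",
    fov = y$fov, grid_n = y$grid_n,
    n_slices = unlist(y$n_slices), seed = y$seed
  )
  spec$arms <- y$arms
  spec
}
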