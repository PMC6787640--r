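#' Analyse one field of view
#'
#' Runs the per-FOV pipeline: linear percentile contrast enhancement,
#' global Otsu binarization of the green channel, 8-connected object
#' labelling with a pixel noise floor, edge/saturation flagging on the
#' original pixels, feature extraction (calibrated area, RG ratio,
#' edge-focus score) and rule-based classification.
#'
#' @param fov A [fov_image()] (the original, un-enhanced frame).
#' @param config A [calibration_config()].
#' @return Classified object table (one row per retained object) with
#'   attribute `n_subfloor`.
#' @export
analyze_fov <- function(fov, config) {
  stopifnot(inherits(fov, "fov_image"),
            inherits(config, "calibration_config"))
  enhanced <- enhance_contrast(fov)
  mask <- binarize(enhanced)
  objects <- label_objects(mask, config$min_object_px, fov$fov_id)
  objects <- flag_exclusions(objects, fov, config)
  features <- compute_features(objects, fov,
                               pixel_size_um = config$pixel_size_um)
  classified <- classify_objects(features, config)
  attr(classified, "n_subfloor") <- attr(objects, "n_subfloor")
  classified
}

#' Analyse a specimen
#'
#' Processes the low-exposure frames of a specimen (bacteria are
#' resolvable in the contrast-enhanced low-exposure pass, so only that
#' pass is analysed by default; high-exposure frames are accepted only
#' when `include_high_exposure = TRUE`) and aggregates the classified
#' objects into a [specimen_report][enumerate_specimen()].
#'
#' @param fovs Either a list of [fov_image()] objects or a specimen
#'   directory containing `manifest.json` (see [read_manifest()]).
#' @param config A [calibration_config()]; when `fovs` is a directory
#'   and `config` is `NULL`, a default configuration is built from the
#'   manifest's `pixel_size_um`.
#' @param specimen_id Overrides the specimen identifier.
#' @param include_high_exposure Also analyse high-exposure frames
#'   (default `FALSE`).
#' @return A list of class `specimen_analysis` with elements `report`
#'   (the [specimen_report][enumerate_specimen()]) and `objects` (the
#'   combined classified object table).
#' @export
analyze_specimen <- function(fovs, config = NULL, specimen_id = NULL,
                             include_high_exposure = FALSE) {
  if (is.character(fovs) && length(fovs) == 1L) {
    dir <- fovs
    manifest <- read_manifest(dir)
    if (is.null(config)) {
      config <- calibration_config(pixel_size_um = manifest$pixel_size_um)
    }
    if (is.null(specimen_id)) specimen_id <- manifest$specimen_id
    files <- manifest$fovs
    fovs <- lapply(seq_len(nrow(files)), function(i) {
      read_fov(file.path(dir, files$file[i]),
               pixel_size_um = manifest$pixel_size_um,
               exposure_class = files$exposure_class[i],
               fov_id = files$fov_id[i],
               specimen_id = manifest$specimen_id)
    })
  }
  stopifnot(is.list(fovs), all(vapply(fovs, inherits, logical(1), "fov_image")))
  if (is.null(config)) stop("`config` is required when passing fov_image objects")
  if (is.null(specimen_id)) {
    specimen_id <- if (length(fovs)) fovs[[1]]$specimen_id else ""
  }
  keep <- vapply(fovs, function(f) {
    f$exposure_class == "low" || include_high_exposure
  }, logical(1))
  n_skipped <- sum(!keep)
  fovs <- fovs[keep]
  if (length(fovs) == 0L) {
    stop_data("no analysable (low-exposure) fields of view")
  }
  tables <- lapply(fovs, analyze_fov, config = config)
  n_subfloor <- sum(vapply(tables, function(t) {
    as.integer(attr(t, "n_subfloor")) %||% 0L
  }, integer(1)))
  objects <- do.call(rbind, tables)
  report <- enumerate_specimen(objects, specimen_id,
                               n_fovs = length(fovs),
                               n_subfloor = n_subfloor)
  structure(list(report = report, objects = objects,
                 n_fovs_skipped = n_skipped),
            class = "specimen_analysis")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.specimen_analysis <- function(x, ...) {
  print(x$report)
  if (x$n_fovs_skipped > 0) {
    cat(sprintf("  (%d high-exposure frame(s) not analysed)\n",
                x$n_fovs_skipped))
  }
  invisible(x)
}
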