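#' Write the per-object table
#'
#' One row per detected object with its centroid, calibrated features,
#' exclusion reason (if any) and class label. Numeric columns are written
#' with 17 significant digits so that a read-back round-trips every value
#' to full double precision.
#'
#' @param objects A data frame as produced by [analyze_fov()] /
#'   [classify_objects()], with columns `fov_id`, `object_id`,
#'   `centroid_x_px`, `centroid_y_px`, `area_um2`, `rg_ratio`,
#'   `focus_score`, `excluded_reason`, `label`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_object_table <- function(objects, path) {
  cols <- c("fov_id", "object_id", "centroid_x_px", "centroid_y_px",
            "area_um2", "rg_ratio", "focus_score", "excluded_reason",
            "label")
  missing <- setdiff(cols, names(objects))
  if (length(missing)) {
    stop("object table lacks column(s): ", paste(missing, collapse = ", "))
  }
  out <- objects[, cols, drop = FALSE]
  for (nm in cols) {
    if (is.numeric(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- NA
      out[[nm]] <- v
    }
  }
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read back a per-object table written by [write_object_table()]
#' @param path CSV path.
#' @return A data frame with numeric feature columns restored.
#' @export
read_object_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                colClasses = "character", na.strings = character())
  for (nm in c("centroid_x_px", "centroid_y_px", "area_um2",
               "rg_ratio", "focus_score")) {
    x[[nm]][x[[nm]] == ""] <- NA
    x[[nm]] <- as.numeric(x[[nm]])
  }
  x$excluded_reason[x$excluded_reason == ""] <- NA
  x
}

#' Read and validate a multi-rater classification table
#'
#' The table records, for every numbered object shown to the raters, the
#' class each rater assigned: one of `epithelial`, `leukocyte`,
#' `bacteria`, `debris`. Used by [percent_agreement()].
#'
#' @param path CSV path with columns `object_id`, `rater_id`, `label`.
#' @return A validated data frame of class `rating_table`.
#' @export
read_rating_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read rating table: %s", path))
  x <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  rating_table(x)
}

#' Validate a multi-rater classification table
#'
#' @param x Data frame with character columns `object_id`, `rater_id`,
#'   `label`; every `(object_id, rater_id)` pair at most once, at least
#'   two distinct raters, labels restricted to the four sediment classes.
#' @return `x` with class `rating_table` prepended.
#' @export
rating_table <- function(x) {
  need <- c("object_id", "rater_id", "label")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("rating table lacks column(s): ", paste(missing, collapse = ", "))
  }
  x$object_id <- as.character(x$object_id)
  x$rater_id <- as.character(x$rater_id)
  x$label <- as.character(x$label)
  bad <- setdiff(unique(x$label), CELL_CLASSES)
  if (length(bad)) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(CELL_CLASSES, collapse = "/"), ")")
  }
  key <- paste(x$object_id, x$rater_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate rating for object '%s' by rater '%s'",
                 dup$object_id, dup$rater_id))
  }
  if (length(unique(x$rater_id)) < 2L) {
    stop("a rating table needs at least two raters")
  }
  class(x) <- unique(c("rating_table", class(x)))
  x
}

#' Read a specimen manifest
#'
#' A specimen is a directory of field-of-view images plus a
#' `manifest.json` sidecar telling the pipeline which acquisition pass
#' each file belongs to:
#'
#' ```json
#' {
#'   "specimen_id": "S01",
#'   "pixel_size_um": 0.6,
#'   "fovs": [
#'     {"file": "fov01_low.tif",  "fov_id": "fov01", "exposure_class": "low"},
#'     {"file": "fov01_high.tif", "fov_id": "fov01", "exposure_class": "high"}
#'   ]
#' }
#' ```
#'
#' @param dir Specimen directory containing `manifest.json`.
#' @return A list with `specimen_id`, `pixel_size_um` and a data frame
#'   `fovs` (`file`, `fov_id`, `exposure_class`).
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) {
    stop_usage(sprintf("no manifest.json in %s", dir))
  }
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("specimen_id", "pixel_size_um", "fovs")) {
    if (is.null(m[[f]])) stop_usage(sprintf("manifest lacks field '%s'", f))
  }
  fovs <- as.data.frame(m$fovs, stringsAsFactors = FALSE)
  for (f in c("file", "fov_id", "exposure_class")) {
    if (is.null(fovs[[f]])) {
      stop_usage(sprintf("manifest fovs lack field '%s'", f))
    }
  }
  bad <- setdiff(unique(fovs$exposure_class), c("low", "high"))
  if (length(bad)) {
    stop_usage(paste0("invalid exposure_class: ", paste(bad, collapse = ", ")))
  }
  if (!is.numeric(m$pixel_size_um) || m$pixel_size_um <= 0) {
    stop_usage("manifest pixel_size_um must be positive")
  }
  list(specimen_id = as.character(m$specimen_id),
       pixel_size_um = m$pixel_size_um,
       fovs = fovs)
}

#' Write a specimen manifest
#' @param dir Target directory.
#' @param specimen_id Specimen identifier.
#' @param pixel_size_um Calibration, um per pixel.
#' @param fovs Data frame with columns `file`, `fov_id`, `exposure_class`.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, specimen_id, pixel_size_um, fovs) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(specimen_id = specimen_id, pixel_size_um = pixel_size_um,
         fovs = fovs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize a specimen report to JSON
#' @param report A [specimen_report] as returned by [enumerate_specimen()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_specimen_report <- function(report, path) {
  stopifnot(inherits(report, "specimen_report"))
  jsonlite::write_json(unclass(report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
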