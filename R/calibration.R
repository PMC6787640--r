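#' Calibration and classification configuration
#'
#' Bundles the physical calibration and the classification thresholds used
#' throughout the pipeline. The spatial calibration (`pixel_size_um`) must
#' always be supplied by the user: the field of view of a point-of-care
#' system is known in mm^2 but the sensor geometry varies between
#' instruments, so it is never guessed from image dimensions.
#'
#' The area thresholds carry the published defaults for acridine-orange
#' stained urine sediment: epithelial cells are larger than 500 um^2,
#' bacteria smaller than 30 um^2 and leukocytes lie in between (both
#' boundary values belong to the leukocyte interval, which is closed).
#'
#' @param pixel_size_um Edge length of one pixel in micrometres (> 0).
#' @param saturation_level Intensity at or above which a pixel counts as
#'   saturated. `NULL` (default) means the bit-depth ceiling of the image
#'   being analysed (255 for 8-bit, 65535 for 16-bit).
#' @param epithelial_min_area_um2 Objects strictly larger are epithelial
#'   cells. Default 500 um^2.
#' @param bacteria_max_area_um2 Objects strictly smaller are bacteria.
#'   Default 30 um^2.
#' @param debris_focus_threshold Objects in the bacteria/leukocyte area
#'   range whose edge-focus score falls below this cutoff are cellular
#'   debris (out-of-focus edges). Dimensionless; see
#'   [compute_focus_score()] for the score definition and the methods
#'   vignette for the calibration of the default.
#' @param min_object_px Connected components smaller than this pixel count
#'   are treated as noise and dropped (but tallied). Default 4.
#'
#' @return An object of class `calibration_config`.
#' @examples
#' cfg <- calibration_config(pixel_size_um = 0.5)
#' cfg$epithelial_min_area_um2
#' @export
calibration_config <- function(pixel_size_um,
                               saturation_level = NULL,
                               epithelial_min_area_um2 = 500,
                               bacteria_max_area_um2 = 30,
                               debris_focus_threshold = 0.38,
                               min_object_px = 4L) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number")
  }
  if (!is.null(saturation_level) &&
      (!is.numeric(saturation_level) || saturation_level <= 0)) {
    stop("`saturation_level` must be NULL or a positive number")
  }
  if (!(bacteria_max_area_um2 > 0 &&
        bacteria_max_area_um2 < epithelial_min_area_um2)) {
    stop("need 0 < bacteria_max_area_um2 < epithelial_min_area_um2")
  }
  min_object_px <- as.integer(min_object_px)
  if (is.na(min_object_px) || min_object_px < 1L) {
    stop("`min_object_px` must be an integer >= 1")
  }
  if (!is.numeric(debris_focus_threshold) || debris_focus_threshold < 0) {
    stop("`debris_focus_threshold` must be a non-negative number")
  }
  structure(
    list(pixel_size_um = pixel_size_um,
         saturation_level = saturation_level,
         epithelial_min_area_um2 = epithelial_min_area_um2,
         bacteria_max_area_um2 = bacteria_max_area_um2,
         debris_focus_threshold = debris_focus_threshold,
         min_object_px = min_object_px),
    class = "calibration_config")
}

# Saturation ceiling actually used for a given image.
resolve_saturation_level <- function(config, image) {
  if (!is.null(config$saturation_level)) config$saturation_level
  else 2^image$bit_depth - 1
}

#' @export
print.calibration_config <- function(x, ...) {
  cat("Calibration / classification configuration\n")
  cat(sprintf("  pixel size            : %g um/px (%g um^2/px)\n",
              x$pixel_size_um, x$pixel_size_um^2))
  cat(sprintf("  saturation level      : %s\n",
              if (is.null(x$saturation_level)) "bit-depth maximum"
              else format(x$saturation_level)))
  cat(sprintf("  epithelial if area  > %g um^2\n", x$epithelial_min_area_um2))
  cat(sprintf("  bacteria   if area  < %g um^2\n", x$bacteria_max_area_um2))
  cat(sprintf("  debris if focus     < %g (small/medium objects)\n",
              x$debris_focus_threshold))
  cat(sprintf("  minimum object size   : %d px\n", x$min_object_px))
  invisible(x)
}
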