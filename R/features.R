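#' Calibrated object area
#'
#' Converts a pixel count to square micrometres: `area_px *
#' pixel_size_um^2`. Exactly linear in pixel count and quadratic in pixel
#' size.
#'
#' @param object A `detected_object` (or anything with an `area_px`
#'   field).
#' @param pixel_size_um Micrometres per pixel edge (> 0).
#' @return Area in um^2.
#' @export
compute_area <- function(object, pixel_size_um) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number")
  }
  object$area_px * pixel_size_um^2
}

#' Red-to-green fluorescence ratio of an object
#'
#' Mean red intensity over the object's mask divided by mean green
#' intensity over the mask, computed on the original (never the
#' contrast-enhanced) image so that channel proportions are preserved.
#' Acridine orange shifts emission toward red in acidic compartments, so
#' the ratio is reported for every object; it is invariant under a common
#' multiplicative gain on both channels. When the mask has no green
#' signal the ratio is undefined and `NA` is returned; such objects are
#' routed to the debris class downstream.
#'
#' @param object A `detected_object`.
#' @param original The original [fov_image()].
#' @return Dimensionless ratio, or `NA` if mean green is zero.
#' @export
compute_rg_ratio <- function(object, original) {
  stopifnot(inherits(original, "fov_image"))
  if (original$enhanced) {
    stop("RG ratio must be computed on the original image")
  }
  idx <- object$idx
  if (length(idx) < 1L) stop("empty object mask")
  mean_r <- mean(original$pixels[, , 1][idx])
  mean_g <- mean(original$pixels[, , 2][idx])
  if (mean_g == 0) return(NA_real_)
  mean_r / mean_g
}

# Gradient magnitude of the green channel by central differences,
# replicating the border pixels. Computed once per image and reused for
# every object.
green_gradient_mag <- function(image) {
  g <- fov_channel(image, "green")
  nr <- nrow(g); nc <- ncol(g)
  rp <- c(2:nr, nr); rm <- c(1, 1:(nr - 1))
  cp <- c(2:nc, nc); cm <- c(1, 1:(nc - 1))
  gy <- (g[rp, , drop = FALSE] - g[rm, , drop = FALSE]) / 2
  gx <- (g[, cp, drop = FALSE] - g[, cm, drop = FALSE]) / 2
  sqrt(gx^2 + gy^2)
}

#' Edge-focus score of an object
#'
#' Cellular debris sits in the same RG-ratio/area region as bacteria but
#' has out-of-focus edges; this score separates them. It is the mean
#' gradient magnitude (central differences on the green channel) over the
#' object's boundary pixels, normalised by the object's mean green
#' intensity so that it measures edge sharpness rather than brightness.
#' Higher is sharper; the score is strictly non-increasing under Gaussian
#' blur of a fixed object.
#'
#' @param object A `detected_object` (needs `boundary_idx`).
#' @param original The original [fov_image()].
#' @param gradient Optional precomputed gradient-magnitude matrix from
#'   the internal helper (used by [compute_features()] to avoid
#'   recomputation per object).
#' @return Dimensionless score `>= 0`, or `NA` when the object has no
#'   green signal.
#' @export
compute_focus_score <- function(object, original, gradient = NULL) {
  stopifnot(inherits(original, "fov_image"))
  if (original$enhanced) {
    stop("focus score must be computed on the original image")
  }
  if (length(object$boundary_idx) < 1L) stop("object has an empty boundary")
  if (is.null(gradient)) gradient <- green_gradient_mag(original)
  mean_g <- mean(original$pixels[, , 2][object$idx])
  if (mean_g == 0) return(NA_real_)
  mean(gradient[object$boundary_idx]) / mean_g
}

#' Feature table for a set of detected objects
#'
#' Computes the calibrated area, RG ratio and edge-focus score for each
#' object on the original image, together with centroids and exclusion
#' flags, as one data frame ready for [classify_objects()].
#'
#' @param objects A `detected_objects` list (ideally after
#'   [flag_exclusions()]).
#' @param original The original [fov_image()].
#' @param pixel_size_um Micrometres per pixel; defaults to the image
#'   calibration.
#' @return A data frame with one row per object.
#' @export
compute_features <- function(objects, original,
                             pixel_size_um = original$pixel_size_um) {
  stopifnot(inherits(objects, "detected_objects"),
            inherits(original, "fov_image"))
  n <- length(objects)
  grad <- if (n > 0) green_gradient_mag(original) else NULL
  df <- data.frame(
    fov_id = character(n), object_id = character(n),
    centroid_x_px = numeric(n), centroid_y_px = numeric(n),
    area_px = integer(n), area_um2 = numeric(n),
    rg_ratio = numeric(n), focus_score = numeric(n),
    touches_edge = logical(n), has_saturation = logical(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ob <- objects[[i]]
    df$fov_id[i] <- ob$fov_id
    df$object_id[i] <- ob$object_id
    df$centroid_x_px[i] <- ob$centroid_px[["x"]]
    df$centroid_y_px[i] <- ob$centroid_px[["y"]]
    df$area_px[i] <- ob$area_px
    df$area_um2[i] <- compute_area(ob, pixel_size_um)
    df$rg_ratio[i] <- compute_rg_ratio(ob, original)
    df$focus_score[i] <- compute_focus_score(ob, original, gradient = grad)
    df$touches_edge[i] <- ob$touches_edge
    df$has_saturation[i] <- ob$has_saturation
  }
  attr(df, "n_subfloor") <- attr(objects, "n_subfloor")
  df
}
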