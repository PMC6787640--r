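#' Linear percentile contrast stretch
#'
#' Per channel, maps the `lower` percentile to 0 and the `upper`
#' percentile to the bit-depth maximum, clipping outside that range. The
#' input is untouched; the returned copy is flagged `enhanced` so that
#' downstream saturation testing and feature extraction keep using the
#' original pixels. A constant channel is returned unchanged.
#'
#' @param image A [fov_image()].
#' @param lower,upper Percentile anchors as fractions; defaults 0.01 and
#'   0.999.
#' @return A contrast-enhanced copy of `image` with `enhanced = TRUE`.
#' @export
enhance_contrast <- function(image, lower = 0.01, upper = 0.999) {
  stopifnot(inherits(image, "fov_image"))
  maxval <- 2^image$bit_depth - 1
  px <- image$pixels
  out <- px
  for (ch in 1:3) {
    v <- px[, , ch]
    qs <- quantile(v, c(lower, upper), names = FALSE, type = 7)
    if (qs[2] <= qs[1]) next  # constant (or near-degenerate) channel
    s <- (v - qs[1]) / (qs[2] - qs[1])
    out[, , ch] <- as.integer(round(pmin(pmax(s, 0), 1) * maxval))
  }
  res <- image
  res$pixels <- out
  res$enhanced <- TRUE
  res
}

#' Binarize a field of view
#'
#' Thresholds the green channel (acridine-orange emission is
#' green-dominated across epithelial cells, leukocytes and bacteria) with
#' a global Otsu threshold; pixels strictly above threshold are
#' foreground. Normally applied to the contrast-enhanced low-exposure
#' frame. A constant image yields an all-background mask. Bright objects
#' on a dark background are assumed; inverted-contrast input is out of
#' contract.
#'
#' @param image A [fov_image()] (typically the output of
#'   [enhance_contrast()]).
#' @return A logical matrix of the same grid shape (`TRUE` = foreground).
#' @export
binarize <- function(image) {
  stopifnot(inherits(image, "fov_image"))
  g <- fov_channel(image, "green")
  if (max(g) == min(g)) {
    return(matrix(FALSE, nrow(g), ncol(g)))
  }
  maxval <- 2^image$bit_depth - 1
  thr <- EBImage::otsu(EBImage::Image(g / maxval), range = c(0, 1),
                       levels = 2^image$bit_depth)
  g / maxval > thr
}

# Boundary pixels of the foreground: mask pixels with a 4-neighbour that
# is background or outside the grid. Because connected components are
# maximal, a component's boundary pixels are exactly the mask boundary
# pixels it contains.
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- function(dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- mask[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- pad(-1, 0) & pad(1, 0) & pad(0, -1) & pad(0, 1)
  mask & !interior
}

#' Label connected objects in a binary mask
#'
#' Extracts 8-connected components (so bacterial rods linked end-to-end,
#' even diagonally, stay one object), drops components smaller than
#' `min_object_px` (tallying them), and computes per object the pixel
#' set, centroid, boundary pixels and pixel area. Object identifiers are
#' deterministic: components are numbered by the raster (row-major)
#' position of their first pixel.
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @param min_object_px Noise floor in pixels; smaller components are
#'   dropped and counted in the `n_subfloor` attribute.
#' @param fov_id Identifier stamped on every object.
#' @return A list of `detected_object`s (class `detected_objects`), with
#'   attributes `n_subfloor` (dropped component count) and `mask_dim`.
#'   Each `detected_object` has `object_id`, `fov_id`, `idx`
#'   (column-major linear pixel indices), `area_px`, `centroid_px`
#'   (`c(x, y)`, 1-based pixel centres), `boundary_idx`, `dim`, and
#'   exclusion flags `touches_edge` / `has_saturation` (`NA` until
#'   [flag_exclusions()]).
#' @export
label_objects <- function(mask, min_object_px = 4L, fov_id = "fov") {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- cc_label_8(mask)
  n_comp <- max(lab)
  if (n_comp == 0L) {
    return(structure(list(), class = "detected_objects",
                     n_subfloor = 0L, mask_dim = c(nr, nc)))
  }
  fg <- which(lab > 0L)
  pix <- split(fg, lab[fg])                 # names "1".."k", label order
  areas <- lengths(pix)
  keep <- areas >= min_object_px
  n_subfloor <- sum(!keep)
  pix <- pix[keep]
  boundary <- mask_boundary(mask)
  objects <- vector("list", length(pix))
  for (i in seq_along(pix)) {
    idx <- pix[[i]]
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    objects[[i]] <- structure(
      list(object_id = sprintf("%s-obj%04d", fov_id, i),
           fov_id = fov_id,
           idx = idx,
           area_px = length(idx),
           centroid_px = c(x = mean(cols), y = mean(rows)),
           boundary_idx = idx[boundary[idx]],
           dim = c(nr, nc),
           touches_edge = NA,
           has_saturation = NA),
      class = "detected_object")
  }
  structure(objects, class = "detected_objects",
            n_subfloor = n_subfloor, mask_dim = c(nr, nc))
}

#' @export
print.detected_objects <- function(x, ...) {
  cat(sprintf("<detected_objects> %d object(s), %d sub-floor component(s) dropped\n",
              length(x), attr(x, "n_subfloor")))
  invisible(x)
}

# Pixel coordinates (row, col) of an object's mask.
object_mask_coords <- function(object) {
  nr <- object$dim[1]
  cbind(row = ((object$idx - 1L) %% nr) + 1L,
        col = ((object$idx - 1L) %/% nr) + 1L)
}

#' Flag edge-touching and saturated objects
#'
#' Objects touching any image border misrepresent their size; objects
#' containing sensor-saturated pixels misrepresent their fluorescence.
#' Both are flagged here (and excluded at enumeration, preserving the
#' audit trail — no object is removed). Saturation is always tested on
#' the original, un-enhanced pixels: contrast enhancement can fabricate
#' or hide ceiling values.
#'
#' @param objects A `detected_objects` list from [label_objects()].
#' @param original The original (not contrast-enhanced) [fov_image()]
#'   the mask was derived from.
#' @param config A [calibration_config()]; supplies the saturation level
#'   (default: the image's bit-depth maximum).
#' @return `objects` with `touches_edge` and `has_saturation` set.
#' @export
flag_exclusions <- function(objects, original, config) {
  stopifnot(inherits(objects, "detected_objects"),
            inherits(original, "fov_image"),
            inherits(config, "calibration_config"))
  if (original$enhanced) {
    stop("saturation must be evaluated on the original image, not a contrast-enhanced copy")
  }
  d <- dim(original$pixels)[1:2]
  if (!identical(as.integer(attr(objects, "mask_dim")), as.integer(d))) {
    stop("mask grid and image dimensions differ")
  }
  sat <- resolve_saturation_level(config, original)
  chan_max <- pmax(original$pixels[, , 1], original$pixels[, , 2],
                   original$pixels[, , 3])
  nr <- d[1]; nc <- d[2]
  for (i in seq_along(objects)) {
    idx <- objects[[i]]$idx
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    objects[[i]]$touches_edge <-
      any(rows == 1L | rows == nr | cols == 1L | cols == nc)
    objects[[i]]$has_saturation <- any(chan_max[idx] >= sat)
  }
  objects
}
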