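#' Construct a field-of-view image
#'
#' A `fov_image` holds one colour fluorescence micrograph together with its
#' acquisition metadata. Pixel intensities are stored as integers at the
#' native bit depth (never rescaled); channel order is R, G, B.
#'
#' @param pixels Integer array of dimension `c(rows, cols, 3)` with values
#'   in `[0, 2^bit_depth - 1]`.
#' @param bit_depth 8 or 16.
#' @param pixel_size_um Micrometres per pixel edge (> 0).
#' @param exposure_class `"low"` or `"high"`. The analysis pipeline
#'   processes low-exposure frames; high-exposure frames are accepted but
#'   flagged.
#' @param fov_id,specimen_id Identifiers carried into all outputs.
#' @param enhanced Internal flag: `TRUE` for the output of
#'   [enhance_contrast()], so that saturation testing and feature
#'   extraction can insist on original pixels.
#'
#' @return An object of class `fov_image`.
#' @export
fov_image <- function(pixels, bit_depth, pixel_size_um,
                      exposure_class = c("low", "high"),
                      fov_id = "fov", specimen_id = "",
                      enhanced = FALSE) {
  exposure_class <- match.arg(exposure_class)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be a rows x cols x 3 array (RGB)")
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) stop("empty pixel grid")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  maxval <- 2^bit_depth - 1
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > maxval) {
    stop(sprintf("intensities must lie in [0, %d]", maxval))
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be positive")
  }
  structure(
    list(pixels = pixels,
         bit_depth = as.integer(bit_depth),
         pixel_size_um = pixel_size_um,
         exposure_class = exposure_class,
         fov_id = as.character(fov_id),
         specimen_id = as.character(specimen_id),
         enhanced = isTRUE(enhanced)),
    class = "fov_image")
}

#' @export
print.fov_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<fov_image %s> %dx%d px, %d-bit RGB, %g um/px, exposure %s%s\n",
    x$fov_id, d[1], d[2], x$bit_depth, x$pixel_size_um, x$exposure_class,
    if (x$enhanced) " (contrast-enhanced)" else ""))
  invisible(x)
}

# One colour channel as a matrix.
fov_channel <- function(image, channel = c("red", "green", "blue")) {
  channel <- match.arg(channel)
  image$pixels[, , match(channel, c("red", "green", "blue"))]
}

# PNG bit depth from the IHDR header (byte 25 of the file).
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L ||
      !identical(as.integer(hdr[2:4]), utf8ToInt("PNG"))) {
    stop(sprintf("not a PNG file: %s", path))
  }
  as.integer(hdr[25L])
}

#' Read one field-of-view micrograph
#'
#' Reads an RGB TIFF or PNG at 8- or 16-bit depth. Intensities are
#' preserved bit-exactly (the stored values are the native integer sample
#' values); no rescaling or gamma is applied. Grayscale and RGBA images
#' are rejected.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_um Micrometres per pixel edge (required calibration).
#' @param exposure_class `"low"` (default) or `"high"`.
#' @param fov_id Identifier; defaults to the file name without extension.
#' @param specimen_id Specimen identifier (optional).
#'
#' @return A [fov_image()].
#' @export
read_fov <- function(path, pixel_size_um,
                     exposure_class = c("low", "high"),
                     fov_id = NULL, specimen_id = "") {
  exposure_class <- match.arg(exposure_class)
  if (!file.exists(path)) stop(sprintf("cannot read image file: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    info <- tiff::readTIFF(path, payload = FALSE)
    bit_depth <- as.integer(info$bits.per.sample[1])
    raw <- tiff::readTIFF(path)
  } else if (ext == "png") {
    bit_depth <- png_bit_depth(path)
    raw <- png::readPNG(path)
  } else {
    stop(sprintf("unsupported image format '.%s' (TIFF or PNG expected)", ext))
  }
  if (!bit_depth %in% c(8L, 16L)) {
    stop(sprintf("unsupported bit depth %d (8 or 16 expected)", bit_depth))
  }
  nch <- if (length(dim(raw)) == 3L) dim(raw)[3] else 1L
  if (nch != 3L) {
    stop(sprintf("RGB image required, got %d channel%s: %s",
                 nch, if (nch == 1L) "" else "s", path))
  }
  pixels <- array(as.integer(round(raw * (2^bit_depth - 1))), dim = dim(raw))
  if (is.null(fov_id)) fov_id <- tools::file_path_sans_ext(basename(path))
  fov_image(pixels, bit_depth, pixel_size_um, exposure_class,
            fov_id = fov_id, specimen_id = specimen_id)
}

#' Write a field-of-view image to TIFF
#'
#' Inverse of [read_fov()] for TIFF output: sample values are written at
#' the image's native bit depth so a read-back is bit-exact.
#'
#' @param image A [fov_image()].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_fov_tiff <- function(image, path) {
  stopifnot(inherits(image, "fov_image"))
  maxval <- 2^image$bit_depth - 1
  tiff::writeTIFF(image$pixels / maxval, path,
                  bits.per.sample = image$bit_depth)
  invisible(path)
}
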