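#' Specification for a synthetic sediment phantom
#'
#' Describes one simulated acridine-orange field of view with full ground
#' truth: large green-dominant epithelial cells with a bright compact
#' nucleus, medium leukocytes with 2-4 bright nuclear lobes and a
#' red-shifted red channel, small dim rod-shaped bacteria, and
#' out-of-focus debris blobs, on a dark background with additive Gaussian
#' sensor noise. Optional fractions of objects are rendered touching the
#' image border or with intensity-clipped (saturated) cores so the
#' exclusion rules can be exercised against known truth.
#'
#' Per-class areas are drawn from lognormal distributions whose default
#' medians (epithelial 800, leukocyte 90, bacteria 4 um^2) sit inside the
#' published class intervals (>500, 30-500, <30 um^2); draws are clamped
#' away from the class boundaries so a phantom's true class always agrees
#' with its true area. The default image is 640 x 640 px at 0.6 um/px,
#' i.e. a 0.147 mm^2 field of view.
#'
#' @param seed Integer RNG seed; identical specs render byte-identical
#'   phantoms.
#' @param image_shape_px `c(rows, cols)`.
#' @param pixel_size_um Micrometres per pixel edge.
#' @param n_per_class Named integer vector: objects to render per class.
#' @param area_dist Per-class list of `c(median_um2 =, sdlog =)` lognormal
#'   parameters.
#' @param leukocyte_red_shift Multiplicative red gain (> 1) applied to
#'   leukocyte sprites; models the red shift in acidic granules. Cosmetic
#'   only: classification never uses the RG ratio.
#' @param debris_blur_sigma_px Gaussian blur width for debris sprites.
#' @param background_level Background intensity (green channel; red/blue
#'   proportionally dimmer).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param saturation_fraction Fraction of epithelial/leukocyte objects
#'   rendered with cores clipped at the intensity ceiling.
#' @param edge_fraction Fraction of objects (every class) placed touching
#'   the image border.
#' @param high_exposure_gain Intensity gain of the simulated
#'   high-exposure pass relative to the low-exposure pass.
#' @param bit_depth Bit depth of the rendered images (8 or 16).
#' @return A validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         image_shape_px = c(640L, 640L),
                         pixel_size_um = 0.6,
                         n_per_class = c(epithelial = 20L, leukocyte = 50L,
                                         bacteria = 200L, debris = 30L),
                         area_dist = list(
                           epithelial = c(median_um2 = 800, sdlog = 0.20),
                           leukocyte  = c(median_um2 = 90,  sdlog = 0.25),
                           bacteria   = c(median_um2 = 4,   sdlog = 0.30),
                           debris     = c(median_um2 = 12,  sdlog = 0.30)),
                         leukocyte_red_shift = 1.8,
                         debris_blur_sigma_px = 2,
                         background_level = 6,
                         noise_sd = 2,
                         saturation_fraction = 0,
                         edge_fraction = 0,
                         high_exposure_gain = 2.5,
                         bit_depth = 8L) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
      "seed must be a single integer")
  chk(length(image_shape_px) == 2L && all(image_shape_px >= 32),
      "image_shape_px must be two values >= 32")
  chk(is.numeric(pixel_size_um) && pixel_size_um > 0,
      "pixel_size_um must be positive")
  chk(all(CELL_CLASSES %in% names(n_per_class)) &&
        all(n_per_class >= 0),
      "n_per_class needs non-negative counts for all four classes")
  chk(all(CELL_CLASSES %in% names(area_dist)),
      "area_dist needs parameters for all four classes")
  med <- function(cl) unname(area_dist[[cl]]["median_um2"])
  if (all(CELL_CLASSES %in% names(area_dist))) {
    chk(med("epithelial") > 500,
        "epithelial median area must exceed 500 um^2")
    chk(med("bacteria") < 30, "bacteria median area must be below 30 um^2")
    chk(med("leukocyte") >= 30 && med("leukocyte") <= 500,
        "leukocyte median area must lie in [30, 500] um^2")
    chk(all(vapply(area_dist, function(p) p["sdlog"] >= 0, logical(1))),
        "sdlog parameters must be non-negative")
  }
  chk(leukocyte_red_shift > 1, "leukocyte_red_shift must exceed 1")
  chk(debris_blur_sigma_px > 0, "debris_blur_sigma_px must be positive")
  chk(background_level >= 0 && noise_sd >= 0,
      "background_level and noise_sd must be non-negative")
  chk(saturation_fraction >= 0 && saturation_fraction <= 1,
      "saturation_fraction must lie in [0, 1]")
  chk(edge_fraction >= 0 && edge_fraction <= 1,
      "edge_fraction must lie in [0, 1]")
  chk(high_exposure_gain > 1, "high_exposure_gain must exceed 1")
  chk(bit_depth %in% c(8L, 16L), "bit_depth must be 8 or 16")
  if (length(problems)) {
    stop("invalid phantom spec: ", paste(problems, collapse = "; "))
  }
  structure(
    list(seed = as.integer(seed),
         image_shape_px = as.integer(image_shape_px),
         pixel_size_um = pixel_size_um,
         n_per_class = vapply(CELL_CLASSES, function(cl)
           as.integer(n_per_class[[cl]]), integer(1)),
         area_dist = area_dist[CELL_CLASSES],
         leukocyte_red_shift = leukocyte_red_shift,
         debris_blur_sigma_px = debris_blur_sigma_px,
         background_level = background_level,
         noise_sd = noise_sd,
         saturation_fraction = saturation_fraction,
         edge_fraction = edge_fraction,
         high_exposure_gain = high_exposure_gain,
         bit_depth = as.integer(bit_depth)),
    class = "phantom_spec")
}

# --- sprite helpers (small local grids; channels in canonical 8-bit
#     units, rescaled at render time for other bit depths) ---------------

sprite_grid <- function(half) {
  s <- 2L * as.integer(ceiling(half)) + 3L
  ctr <- (s + 1) / 2
  list(size = s, x = matrix(rep(seq_len(s), each = s), s, s) - ctr,
       y = matrix(rep(seq_len(s), times = s), s, s) - ctr)
}

blank_sprite <- function(size) {
  z <- matrix(0, size, size)
  list(mask = matrix(FALSE, size, size), R = z, G = z, B = z,
       core = matrix(FALSE, size, size))
}

sprite_epithelial <- function(area_px) {
  q <- runif(1, 1.2, 2)
  a <- sqrt(area_px * q / pi); b <- a / q
  th <- runif(1, 0, pi)
  g <- sprite_grid(a)
  u <- g$x * cos(th) + g$y * sin(th)
  v <- -g$x * sin(th) + g$y * cos(th)
  sp <- blank_sprite(g$size)
  sp$mask <- (u / a)^2 + (v / b)^2 <= 1
  j <- runif(1, 0.9, 1.1)
  rn <- 0.35 * b
  nucleus <- (g$x - runif(1, -0.2, 0.2) * b)^2 +
    (g$y - runif(1, -0.2, 0.2) * b)^2 <= rn^2
  nucleus <- nucleus & sp$mask
  sp$G[sp$mask] <- 120 * j; sp$G[nucleus] <- 200 * j
  sp$R[sp$mask] <- 40 * j;  sp$R[nucleus] <- 70 * j
  sp$B[sp$mask] <- 15 * j
  sp$core <- nucleus
  sp
}

sprite_leukocyte <- function(area_px, red_shift) {
  r <- sqrt(area_px / pi)
  g <- sprite_grid(r)
  sp <- blank_sprite(g$size)
  sp$mask <- g$x^2 + g$y^2 <= r^2
  j <- runif(1, 0.9, 1.1)
  sp$G[sp$mask] <- 135 * j
  sp$R[sp$mask] <- 55 * j
  sp$B[sp$mask] <- 15 * j
  n_lobes <- sample(2:4, 1)
  ang <- runif(1, 0, 2 * pi) + seq_len(n_lobes) * 2 * pi / n_lobes
  lobes <- matrix(FALSE, g$size, g$size)
  for (k in seq_len(n_lobes)) {
    lobes <- lobes | ((g$x - 0.45 * r * cos(ang[k]))^2 +
                        (g$y - 0.45 * r * sin(ang[k]))^2 <= (0.28 * r)^2)
  }
  lobes <- lobes & sp$mask
  sp$G[lobes] <- 200 * j
  sp$R[lobes] <- 85 * j
  sp$R <- sp$R * red_shift
  sp$core <- lobes
  sp
}

sprite_bacteria <- function(area_px, pixel_size_um) {
  # >= 2 px wide: a 1 px line has zero central-difference gradient, so
  # rods must be sampled above Nyquist for the focus score to see them
  w <- max(2, round(1.2 / pixel_size_um))
  len <- max(2, area_px / w)
  th <- runif(1, 0, pi)
  g <- sprite_grid(len / 2 + 1)
  u <- g$x * cos(th) + g$y * sin(th)
  v <- -g$x * sin(th) + g$y * cos(th)
  sp <- blank_sprite(g$size)
  sp$mask <- abs(u) <= len / 2 & abs(v) <= w / 2
  j <- runif(1, 0.9, 1.1)
  sp$G[sp$mask] <- 100 * j
  sp$R[sp$mask] <- 25 * j
  sp$B[sp$mask] <- 5 * j
  sp
}

sprite_debris <- function(area_px, sigma) {
  r <- sqrt(area_px / pi)
  pad <- ceiling(3 * sigma) + 2
  g <- sprite_grid(r + pad)
  sp <- blank_sprite(g$size)
  sp$mask <- g$x^2 + g$y^2 <= r^2
  j <- runif(1, 0.9, 1.1)
  sp$G[sp$mask] <- 190 * j
  sp$R[sp$mask] <- 48 * j
  sp$B[sp$mask] <- 10 * j
  blur <- function(m) {
    EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
  }
  sp$R <- blur(sp$R); sp$G <- blur(sp$G); sp$B <- blur(sp$B)
  sp
}

# Box dilation by m pixels via shifted running maximum.
dilate_box <- function(mask, m) {
  if (m <= 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2 * m, nc + 2 * m)
  out <- pad
  for (dr in -m:m) for (dc in -m:m) {
    sh <- pad
    sh[m + dr + seq_len(nr), m + dc + seq_len(nc)] <- mask
    out <- out | sh
  }
  out[m + seq_len(nr), m + seq_len(nc)]
}

#' Render a synthetic sediment phantom
#'
#' Produces the low-exposure frame the pipeline analyses, the paired
#' high-exposure frame (same scene scaled by `high_exposure_gain`, with
#' bright cells clipping at the intensity ceiling) and the ground-truth
#' table. Rendering is fully deterministic for a given spec: the same
#' seed yields byte-identical images and truth.
#'
#' @param spec A [phantom_spec()].
#' @param specimen_id,fov_id Identifiers stamped on the rendered frames.
#' @return A list with elements `low` and `high` ([fov_image()]s) and
#'   `truth`, a data frame with one row per rendered object:
#'   `object_id`, `true_class`, `true_area_px`, `true_area_um2`,
#'   `centroid_x_px`, `centroid_y_px`, `touches_edge`, `is_saturated`,
#'   `blur_sigma_px`.
#' @export
render_phantom <- function(spec, specimen_id = "phantom",
                           fov_id = "fov01") {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, render_phantom_impl(spec, specimen_id, fov_id))
}

render_phantom_impl <- function(spec, specimen_id, fov_id) {
  nr <- spec$image_shape_px[1]; nc <- spec$image_shape_px[2]
  maxval <- 2^spec$bit_depth - 1
  scale <- maxval / 255                  # sprites are in 8-bit units
  bg <- spec$background_level
  Rc <- matrix(bg * 0.6, nr, nc)
  Gc <- matrix(bg, nr, nc)
  Bc <- matrix(bg * 0.4, nr, nc)
  occupancy <- matrix(FALSE, nr, nc)

  truth <- list()
  render_order <- c("epithelial", "leukocyte", "debris", "bacteria")
  counter <- 0L
  for (cl in render_order) {
    n <- spec$n_per_class[[cl]]
    if (n == 0L) next
    pars <- spec$area_dist[[cl]]
    areas_um2 <- rlnorm(n, log(pars[["median_um2"]]), pars[["sdlog"]])
    clamp <- switch(cl,
                    epithelial = c(560, Inf),
                    leukocyte = c(40, 440),
                    bacteria = c(1.5, 18),
                    debris = c(8, 60))
    areas_um2 <- pmin(pmax(areas_um2, clamp[1]), clamp[2])
    areas_px <- pmax(1, areas_um2 / spec$pixel_size_um^2)
    n_edge <- round(spec$edge_fraction * n)
    edge_ids <- if (n_edge > 0) sample(n, n_edge) else integer()
    n_sat <- if (cl %in% c("epithelial", "leukocyte")) {
      round(spec$saturation_fraction * n)
    } else 0L
    sat_ids <- if (n_sat > 0) sample(n, n_sat) else integer()
    margin <- if (cl == "debris") {
      3L + as.integer(ceiling(2 * spec$debris_blur_sigma_px))
    } else 3L
    for (i in seq_len(n)) {
      sp <- switch(cl,
                   epithelial = sprite_epithelial(areas_px[i]),
                   leukocyte = sprite_leukocyte(areas_px[i],
                                                spec$leukocyte_red_shift),
                   bacteria = sprite_bacteria(areas_px[i],
                                              spec$pixel_size_um),
                   debris = sprite_debris(areas_px[i],
                                          spec$debris_blur_sigma_px))
      if (i %in% sat_ids && any(sp$core)) {
        # clipped core: past the ceiling before quantisation
        sp$G[sp$core] <- 300
        sp$R[sp$core] <- 300
      }
      support <- if (cl == "debris") sp$G > 2 else sp$mask
      placed <- place_sprite(sp, support, occupancy, nr, nc, margin,
                             edge = i %in% edge_ids)
      if (is.null(placed)) {
        n_placed <- length(truth)
        n_total <- sum(spec$n_per_class)
        stop(structure(
          class = c("aosediment_placement_error", "error", "condition"),
          list(message = sprintf(
            "phantom placement failed: placed %d of %d objects",
            n_placed, n_total), call = NULL)))
      }
      rows <- placed$rows; cols <- placed$cols
      Rc[rows, cols] <- Rc[rows, cols] + sp$R[placed$srows, placed$scols]
      Gc[rows, cols] <- Gc[rows, cols] + sp$G[placed$srows, placed$scols]
      Bc[rows, cols] <- Bc[rows, cols] + sp$B[placed$srows, placed$scols]
      occupancy[rows, cols] <- occupancy[rows, cols] |
        placed$support_clip
      m <- placed$mask_clip
      mr <- row(m)[m] + placed$rows[1] - 1L
      mc <- col(m)[m] + placed$cols[1] - 1L
      counter <- counter + 1L
      truth[[counter]] <- data.frame(
        object_id = sprintf("truth%04d", counter),
        true_class = cl,
        true_area_px = sum(m),
        true_area_um2 = sum(m) * spec$pixel_size_um^2,
        centroid_x_px = mean(mc),
        centroid_y_px = mean(mr),
        touches_edge = any(mr == 1L | mr == nr | mc == 1L | mc == nc),
        sat_core = i %in% sat_ids,
        blur_sigma_px = if (cl == "debris") spec$debris_blur_sigma_px else 0,
        stringsAsFactors = FALSE)
      truth[[counter]]$mask_idx <- I(list((mc - 1L) * nr + mr))
    }
  }
  truth <- if (counter > 0) do.call(rbind, truth) else data.frame(
    object_id = character(), true_class = character(),
    true_area_px = integer(), true_area_um2 = numeric(),
    centroid_x_px = numeric(), centroid_y_px = numeric(),
    touches_edge = logical(), sat_core = logical(),
    blur_sigma_px = numeric(), mask_idx = I(list()),
    stringsAsFactors = FALSE)

  quantise <- function(ch, noise_sd) {
    if (noise_sd > 0) ch <- ch + rnorm(length(ch), 0, noise_sd)
    matrix(as.integer(round(pmin(pmax(ch * scale, 0), maxval))), nr, nc)
  }
  low <- array(0L, c(nr, nc, 3))
  low[, , 1] <- quantise(Rc, spec$noise_sd)
  low[, , 2] <- quantise(Gc, spec$noise_sd)
  low[, , 3] <- quantise(Bc, spec$noise_sd)
  high <- array(0L, c(nr, nc, 3))
  g <- spec$high_exposure_gain
  high[, , 1] <- quantise(Rc * g, spec$noise_sd)
  high[, , 2] <- quantise(Gc * g, spec$noise_sd)
  high[, , 3] <- quantise(Bc * g, spec$noise_sd)

  # ground-truth saturation: does the rendered object actually contain
  # ceiling-valued pixels in the low-exposure frame?
  chan_max <- pmax(low[, , 1], low[, , 2], low[, , 3])
  truth$is_saturated <- vapply(truth$mask_idx, function(ix) {
    any(chan_max[ix] >= maxval)
  }, logical(1))
  truth$mask_idx <- NULL
  truth$sat_core <- NULL

  list(
    low = fov_image(low, spec$bit_depth, spec$pixel_size_um, "low",
                    fov_id = paste0(fov_id, "_low"),
                    specimen_id = specimen_id),
    high = fov_image(high, spec$bit_depth, spec$pixel_size_um, "high",
                     fov_id = paste0(fov_id, "_high"),
                     specimen_id = specimen_id),
    truth = truth)
}

# Find a collision-free placement for a sprite; returns the canvas/sprite
# index windows, or NULL after exhausting the retry budget.
place_sprite <- function(sp, support, occupancy, nr, nc, margin,
                         edge = FALSE, retries = 400L) {
  s <- nrow(sp$mask)
  grown <- dilate_box(support, margin)
  bb <- which(support, arr.ind = TRUE)
  if (nrow(bb) == 0L) return(NULL)
  for (t in seq_len(retries)) {
    if (!edge) {
      if (nr - s - margin - 2L < margin + 2L ||
          nc - s - margin - 2L < margin + 2L) return(NULL)
      r0 <- sample(3:(nr - s - 2L), 1)
      c0 <- sample(3:(nc - s - 2L), 1)
    } else {
      side <- sample(4L, 1)
      mid_r <- round(mean(range(bb[, 1])))
      mid_c <- round(mean(range(bb[, 2])))
      r0 <- sample(3:(nr - s - 2L), 1)
      c0 <- sample(3:(nc - s - 2L), 1)
      if (side == 1L) r0 <- 1L - mid_r + 1L          # top
      if (side == 2L) r0 <- nr - mid_r               # bottom
      if (side == 3L) c0 <- 1L - mid_c + 1L          # left
      if (side == 4L) c0 <- nc - mid_c               # right
    }
    rows <- (r0):(r0 + s - 1L); cols <- (c0):(c0 + s - 1L)
    rkeep <- rows >= 1L & rows <= nr
    ckeep <- cols >= 1L & cols <= nc
    if (!any(rkeep) || !any(ckeep)) next
    rows <- rows[rkeep]; cols <- cols[ckeep]
    srows <- which(rkeep); scols <- which(ckeep)
    support_clip <- support[srows, scols, drop = FALSE]
    mask_clip <- sp$mask[srows, scols, drop = FALSE]
    if (!any(mask_clip)) next
    if (edge) {
      mr <- row(mask_clip)[mask_clip] + rows[1] - 1L
      mc <- col(mask_clip)[mask_clip] + cols[1] - 1L
      if (!any(mr == 1L | mr == nr | mc == 1L | mc == nc)) next
    }
    grown_clip <- grown[srows, scols, drop = FALSE]
    if (any(occupancy[rows, cols] & grown_clip)) next
    return(list(rows = rows, cols = cols, srows = srows, scols = scols,
                support_clip = support_clip, mask_clip = mask_clip))
  }
  NULL
}

#' Match detected objects to phantom ground truth
#'
#' Greedy nearest-centroid matching between a classified object table and
#' a phantom truth table, used to compare measured against true geometry.
#'
#' @param objects Classified object table ([analyze_fov()] output).
#' @param truth Truth table from [render_phantom()].
#' @param max_dist_px Maximum allowed centroid distance for a match.
#' @return `truth` with columns `matched_object_id`, `measured_area_um2`
#'   and `measured_label` appended (`NA` where unmatched).
#' @export
match_objects_to_truth <- function(objects, truth, max_dist_px = 10) {
  truth$matched_object_id <- NA_character_
  truth$measured_area_um2 <- NA_real_
  truth$measured_label <- NA_character_
  if (nrow(objects) == 0L || nrow(truth) == 0L) return(truth)
  taken <- rep(FALSE, nrow(objects))
  for (i in seq_len(nrow(truth))) {
    d2 <- (objects$centroid_x_px - truth$centroid_x_px[i])^2 +
      (objects$centroid_y_px - truth$centroid_y_px[i])^2
    d2[taken] <- Inf
    k <- which.min(d2)
    if (length(k) && d2[k] <= max_dist_px^2) {
      taken[k] <- TRUE
      truth$matched_object_id[i] <- objects$object_id[k]
      truth$measured_area_um2[i] <- objects$area_um2[k]
      truth$measured_label[i] <- objects$label[k]
    }
  }
  truth
}

#' Simulated multi-rater classification table
#'
#' Copies the phantom's true labels to `n_raters` raters, independently
#' flipping each rating to a uniformly chosen different class with
#' probability `disagreement_rate`. Seeded by the spec, so fixtures are
#' reproducible.
#'
#' @param spec A [phantom_spec()] (supplies class sizes and the seed).
#' @param n_raters Number of raters (>= 2).
#' @param disagreement_rate Per-rating flip probability in `[0, 1]`.
#' @return A [rating_table()].
#' @export
render_rating_fixture <- function(spec, n_raters, disagreement_rate) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_raters < 2L) stop("need at least 2 raters")
  if (disagreement_rate < 0 || disagreement_rate > 1) {
    stop("`disagreement_rate` must lie in [0, 1]")
  }
  labels <- rep(CELL_CLASSES, times = spec$n_per_class[CELL_CLASSES])
  n <- length(labels)
  if (n == 0L) stop("spec renders no objects")
  object_id <- sprintf("obj%04d", seq_len(n))
  with_seed(spec$seed, {
    rows <- lapply(seq_len(n_raters), function(r) {
      lab <- labels
      flip <- runif(n) < disagreement_rate
      if (any(flip)) {
        lab[flip] <- vapply(lab[flip], function(cur) {
          sample(setdiff(CELL_CLASSES, cur), 1)
        }, character(1))
      }
      data.frame(object_id = object_id,
                 rater_id = sprintf("rater%02d", r),
                 label = lab, stringsAsFactors = FALSE)
    })
    rating_table(do.call(rbind, rows))
  })
}

#' Write a phantom specimen to disk
#'
#' Renders the phantom and writes an analysable specimen directory:
#' low- and high-exposure TIFFs, `truth.csv`, the spec as
#' `phantom_spec.json` and a `manifest.json` consumable by
#' [analyze_specimen()].
#'
#' @param spec A [phantom_spec()].
#' @param dir Output directory (created if needed).
#' @param specimen_id Specimen identifier.
#' @return The rendered phantom (invisibly).
#' @export
write_phantom_specimen <- function(spec, dir, specimen_id = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- render_phantom(spec, specimen_id = specimen_id)
  write_fov_tiff(ph$low, file.path(dir, "fov01_low.tif"))
  write_fov_tiff(ph$high, file.path(dir, "fov01_high.tif"))
  write.csv(ph$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(spec), file.path(dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(dir, specimen_id, spec$pixel_size_um,
                 data.frame(file = c("fov01_low.tif", "fov01_high.tif"),
                            fov_id = c("fov01", "fov01"),
                            exposure_class = c("low", "high"),
                            stringsAsFactors = FALSE))
  invisible(ph)
}

#' Read a phantom spec from JSON
#' @param path JSON file with the fields of [phantom_spec()].
#' @return A validated [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("cannot read spec: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- x[intersect(names(x), names(formals(phantom_spec)))]
  if (!is.null(args$n_per_class)) args$n_per_class <- unlist(args$n_per_class)
  if (!is.null(args$area_dist)) {
    args$area_dist <- lapply(args$area_dist, unlist)
  }
  do.call(phantom_spec, args)
}
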