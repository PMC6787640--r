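#' Area-threshold classification
#'
#' The published decision rule for acridine-orange stained urine
#' sediment: objects larger than `epithelial_min_area_um2` (default
#' 500 um^2) are epithelial cells, objects smaller than
#' `bacteria_max_area_um2` (default 30 um^2) are bacteria, and everything
#' in between is a leukocyte. Both thresholds are strict, so the
#' leukocyte interval is closed: at the defaults an area of exactly 30 or
#' 500 um^2 is a leukocyte. The rule is a total, deterministic partition
#' of `[0, Inf)`.
#'
#' @param area_um2 Numeric vector of calibrated areas (um^2, `>= 0`).
#' @param config A [calibration_config()].
#' @return Character vector: `"epithelial"`, `"leukocyte"` or
#'   `"bacteria"`.
#' @examples
#' cfg <- calibration_config(pixel_size_um = 0.5)
#' classify_by_area(c(600, 25, 100, 30, 500), cfg)
#' @export
classify_by_area <- function(area_um2, config) {
  stopifnot(inherits(config, "calibration_config"))
  if (any(!is.finite(area_um2)) || any(area_um2 < 0)) {
    stop("`area_um2` must be finite and non-negative")
  }
  ifelse(area_um2 > config$epithelial_min_area_um2, "epithelial",
         ifelse(area_um2 < config$bacteria_max_area_um2, "bacteria",
                "leukocyte"))
}

#' Classify detected objects
#'
#' Applies the full decision rule to a feature table (one row per
#' object), in precedence order:
#'
#' 1. an object touching the image edge or containing saturated pixels is
#'    `excluded` (its size or fluorescence is misrepresented);
#' 2. an object whose RG ratio is undefined (no green signal), or whose
#'    edge-focus score falls below `debris_focus_threshold` while its
#'    area class would be bacteria or leukocyte, is `debris`
#'    (out-of-focus edges); large in-focus epithelial cells are never
#'    debris;
#' 3. otherwise the area rule of [classify_by_area()] decides.
#'
#' The RG ratio is reported in the object table but never used in the
#' class decision: in this assay the area separates the classes while the
#' red shift does not.
#'
#' @param features Data frame from [compute_features()] (needs
#'   `area_um2`, `rg_ratio`, `focus_score`, `touches_edge`,
#'   `has_saturation`).
#' @param config A [calibration_config()].
#' @return `features` with columns `excluded_reason` (`"edge"`,
#'   `"saturation"` or `NA`) and `label` (`"epithelial"`, `"leukocyte"`,
#'   `"bacteria"`, `"debris"`, `"excluded"`) appended.
#' @export
classify_objects <- function(features, config) {
  stopifnot(inherits(config, "calibration_config"))
  need <- c("area_um2", "rg_ratio", "focus_score",
            "touches_edge", "has_saturation")
  missing <- setdiff(need, names(features))
  if (length(missing)) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyNA(features$touches_edge) || anyNA(features$has_saturation)) {
    stop("exclusion flags unset; run flag_exclusions() first")
  }
  n <- nrow(features)
  reason <- rep(NA_character_, n)
  reason[features$has_saturation] <- "saturation"
  reason[features$touches_edge] <- "edge"      # edge takes precedence
  area_class <- classify_by_area(features$area_um2, config)
  blurred <- !is.na(features$focus_score) &
    features$focus_score < config$debris_focus_threshold &
    area_class != "epithelial"
  label <- area_class
  label[blurred | is.na(features$rg_ratio)] <- "debris"
  label[!is.na(reason)] <- "excluded"
  features$excluded_reason <- reason
  features$label <- label
  features
}

#' Single-object classification
#'
#' Convenience wrapper around [classify_objects()] for one object.
#'
#' @param features One-row feature data frame (or a list with the same
#'   fields).
#' @param config A [calibration_config()].
#' @return The class label as a string.
#' @export
classify_object <- function(features, config) {
  df <- as.data.frame(features[c("area_um2", "rg_ratio", "focus_score",
                                 "touches_edge", "has_saturation")],
                      stringsAsFactors = FALSE)
  classify_objects(df, config)$label
}

#' Map a count to its clinical range category
#'
#' Clinical microscopic examinations report sediment counts as range
#' bins. The bins partition the non-negative integers: 0–2 is
#' `"Trace (0–2)"`, 3–10 `"Few (3–10)"`, 11–25 `"Moderate (11–25)"` and
#' above 25 `"Many (>25)"`. A count of exactly 10 is `Few`, so the bins
#' never overlap.
#'
#' @param count Non-negative integer vector.
#' @return Character vector of range labels.
#' @examples
#' to_range_category(c(0, 4, 22, 40))
#' @export
to_range_category <- function(count) {
  if (any(!is.finite(count)) || any(count < 0)) {
    stop("`count` must be non-negative")
  }
  ifelse(count <= 2, RANGE_LABELS[1],
         ifelse(count <= 10, RANGE_LABELS[2],
                ifelse(count <= 25, RANGE_LABELS[3], RANGE_LABELS[4])))
}

#' Pairwise interobserver percent agreement for one class
#'
#' For every pair of raters and every object for which at least one rater
#' of the pair assigned class `cls`, the pair either agrees (both
#' assigned `cls`) or disagrees. The statistic is the percentage of
#' agreeing (pair, object) combinations. Objects missing a rating from
#' either rater of a pair are skipped for that pair.
#'
#' @param ratings A [rating_table()].
#' @param cls One of `"epithelial"`, `"leukocyte"`, `"bacteria"`,
#'   `"debris"`.
#' @return Percentage in `[0, 100]` with attribute `n_pairs` (the number
#'   of scored (pair, object) combinations), or `NA` if no rater ever
#'   assigned `cls`.
#' @export
percent_agreement <- function(ratings, cls) {
  ratings <- rating_table(as.data.frame(ratings, stringsAsFactors = FALSE))
  cls <- match.arg(cls, CELL_CLASSES)
  raters <- sort(unique(ratings$rater_id))
  objects <- sort(unique(ratings$object_id))
  wide <- matrix(NA_character_, length(objects), length(raters),
                 dimnames = list(objects, raters))
  wide[cbind(match(ratings$object_id, objects),
             match(ratings$rater_id, raters))] <- ratings$label
  if (!any(wide == cls, na.rm = TRUE)) {
    return(structure(NA_real_, n_pairs = 0L))
  }
  n_pairs <- 0L
  n_agree <- 0L
  for (i in seq_len(length(raters) - 1L)) {
    for (j in (i + 1L):length(raters)) {
      a <- wide[, i]; b <- wide[, j]
      ok <- !is.na(a) & !is.na(b)
      hit <- ok & (a == cls | b == cls)
      n_pairs <- n_pairs + sum(hit)
      n_agree <- n_agree + sum(hit & a == cls & b == cls)
    }
  }
  if (n_pairs == 0L) return(structure(NA_real_, n_pairs = 0L))
  structure(100 * n_agree / n_pairs, n_pairs = n_pairs)
}

#' Per-class interobserver agreement table
#'
#' @param ratings A [rating_table()].
#' @return Data frame with columns `class`, `percent`, `n_pairs`; classes
#'   never assigned by any rater get `NA` percent.
#' @export
agreement_table <- function(ratings) {
  res <- lapply(CELL_CLASSES, function(cl) {
    p <- percent_agreement(ratings, cl)
    data.frame(class = cl, percent = as.numeric(p),
               n_pairs = attr(p, "n_pairs"), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
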