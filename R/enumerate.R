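#' Enumerate a specimen from classified objects
#'
#' Aggregates per-object classifications over all analysed fields of view
#' into the clinical report: total counts per cell class, per-FOV means,
#' the clinical range category for each class, and the exclusion tally.
#' Debris and excluded objects never enter the cell counts, but every
#' detected object is accounted for: `sum(counts) + sum(excluded)` equals
#' the number of detections (including sub-floor components dropped at
#' labelling).
#'
#' @param objects Data frame of classified objects ([classify_objects()]
#'   output, possibly row-bound over FOVs) with columns `fov_id`,
#'   `label`, `excluded_reason`.
#' @param specimen_id Specimen identifier for the report.
#' @param n_fovs Number of analysed fields of view; defaults to the
#'   number of distinct `fov_id`s in `objects`. Must be >= 1 (supply it
#'   explicitly when some FOVs contain no objects).
#' @param n_subfloor Number of sub-floor components dropped during
#'   labelling (see [label_objects()]); defaults to the `n_subfloor`
#'   attribute of `objects` if present, else 0.
#' @return An object of class `specimen_report`: a list with
#'   `specimen_id`, `n_fovs`, `counts`, `per_fov_mean`, `categories`,
#'   `excluded` and `total_detections`.
#' @export
enumerate_specimen <- function(objects, specimen_id,
                               n_fovs = length(unique(objects$fov_id)),
                               n_subfloor = NULL) {
  if (is.null(n_subfloor)) {
    n_subfloor <- attr(objects, "n_subfloor")
    if (is.null(n_subfloor)) n_subfloor <- 0L
  }
  if (!is.numeric(n_fovs) || n_fovs < 1L) {
    stop("a specimen needs at least one analysed field of view")
  }
  need <- c("fov_id", "label", "excluded_reason")
  missing <- setdiff(need, names(objects))
  if (length(missing)) {
    stop("classified table lacks column(s): ", paste(missing, collapse = ", "))
  }
  cell_classes <- c("epithelial", "leukocyte", "bacteria")
  counts <- vapply(cell_classes,
                   function(cl) sum(objects$label == cl), integer(1))
  excluded <- c(
    edge = sum(objects$label == "excluded" &
                 objects$excluded_reason == "edge", na.rm = TRUE),
    saturation = sum(objects$label == "excluded" &
                       objects$excluded_reason == "saturation", na.rm = TRUE),
    subfloor = as.integer(n_subfloor),
    debris = sum(objects$label == "debris"))
  total <- nrow(objects) + as.integer(n_subfloor)
  stopifnot(sum(counts) + sum(excluded) == total)
  structure(
    list(specimen_id = as.character(specimen_id),
         n_fovs = as.integer(n_fovs),
         counts = as.list(counts),
         per_fov_mean = as.list(counts / n_fovs),
         categories = as.list(stats::setNames(
           to_range_category(counts), names(counts))),
         excluded = as.list(excluded),
         total_detections = total),
    class = "specimen_report")
}

#' @export
print.specimen_report <- function(x, ...) {
  cat(sprintf("Specimen %s - %d field(s) of view, %d detection(s)\n",
              x$specimen_id, x$n_fovs, x$total_detections))
  for (cl in names(x$counts)) {
    cat(sprintf("  %-10s total %4d  per-FOV mean %7.2f  %s\n",
                cl, x$counts[[cl]], x$per_fov_mean[[cl]],
                x$categories[[cl]]))
  }
  ex <- x$excluded
  cat(sprintf("  excluded: edge %d, saturation %d, sub-floor %d, debris %d\n",
              ex$edge, ex$saturation, ex$subfloor, ex$debris))
  invisible(x)
}

#' @export
summary.specimen_report <- function(object, ...) {
  df <- data.frame(
    class = names(object$counts),
    count = unlist(object$counts, use.names = FALSE),
    per_fov_mean = unlist(object$per_fov_mean, use.names = FALSE),
    category = unlist(object$categories, use.names = FALSE),
    stringsAsFactors = FALSE)
  attr(df, "excluded") <- unlist(object$excluded)
  df
}
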