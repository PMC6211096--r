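#' Classify one index-change value into a severity class
#'
#' Compares x against the three thresholds of a [derive_threshold_set()]
#' result. For a decreasing orientation (b < 0; larger defoliation pushes x
#' down, as for dMSI): nil if x > T10, low if T35 < x <= T10, medium if
#' T70 < x <= T35, high if x <= T70. For an increasing orientation the
#' inequalities mirror. A value exactly on a threshold goes to the more
#' severe class (the nil region is strictly beyond T10).
#'
#' Classification uses the unrounded limits; rounding is display-only.
#'
#' @param x finite index-change value(s)
#' @param thresholds a `threshold_set` with the default three boundaries
#' @return factor with levels [SEVERITY_LEVELS] (NA for NA input)
#' @export
classify_value <- function(x, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"),
            length(thresholds$limits_x) == 3L)
  tl <- thresholds$limits_x
  if (thresholds$orientation == "decreasing") {
    cls <- ifelse(x > tl[1], "nil",
           ifelse(x > tl[2], "low",
           ifelse(x > tl[3], "medium", "high")))
  } else {
    cls <- ifelse(x < tl[1], "nil",
           ifelse(x < tl[2], "low",
           ifelse(x < tl[3], "medium", "high")))
  }
  factor(cls, levels = SEVERITY_LEVELS)
}

#' Classify a dVI raster into a severity map
#'
#' Applies [classify_value()] per valid pixel; nodata passes through.
#'
#' @param dvi a [dvi_raster()]
#' @param thresholds a `threshold_set` for the same index
#' @return an object of class `severity_map`: list with `grid` (integer
#'   matrix, 1 = nil ... 4 = high, NA = nodata), `transform`, `index_name`,
#'   `thresholds`, and `class_counts` (named pixel counts per class)
#' @export
classify_dvi <- function(dvi, thresholds) {
  stopifnot(inherits(dvi, "dvi_raster"), inherits(thresholds, "threshold_set"))
  if (nzchar(thresholds$index_name) &&
      thresholds$index_name != dvi$index_name)
    stop(sprintf("threshold set is for %s but raster holds %s",
                 thresholds$index_name, dvi$index_name))
  cls <- classify_value(as.vector(dvi$grid), thresholds)
  grid <- matrix(as.integer(cls), nrow(dvi$grid), ncol(dvi$grid))
  counts <- table(factor(as.character(cls), levels = SEVERITY_LEVELS))
  structure(list(grid = grid, transform = dvi$transform,
                 index_name = dvi$index_name, thresholds = thresholds,
                 class_counts = stats::setNames(as.integer(counts),
                                                SEVERITY_LEVELS)),
            class = "severity_map")
}

#' @export
print.severity_map <- function(x, ...) {
  cat(sprintf("severity_map d%s: %d x %d; counts %s; %d nodata\n",
              x$index_name, nrow(x$grid), ncol(x$grid),
              paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
                    collapse = " "),
              sum(is.na(x$grid))))
  invisible(x)
}

#' Write a severity map as an ASCII grid plus a JSON sidecar
#'
#' The raster uses codes 1 = nil, 2 = low, 3 = medium, 4 = high with
#' sentinel 0 for nodata; the sidecar records the index and the thresholds
#' the map was classified with, so the map is self-documenting.
#'
#' @param map a `severity_map`
#' @param path output `.asc` path; the sidecar is written to `<path>.json`
#' @return `path`, invisibly
#' @export
write_severity_map <- function(map, path) {
  write_ascii_grid(map$grid, path, map$transform, nodata = 0)
  side <- list(index_name = map$index_name,
               codes = list(nodata = 0, nil = 1, low = 2, medium = 3,
                            high = 4),
               boundaries_y = map$thresholds$boundaries_y,
               limits_x = map$thresholds$limits_x,
               orientation = map$thresholds$orientation,
               class_counts = as.list(map$class_counts))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Confusion matrix of observed vs predicted severity classes
#'
#' Rows are the observed class, columns the predicted class, both ordered
#' nil, low, medium, high.
#'
#' @param observed,predicted vectors of class labels (factor or character),
#'   equal length
#' @return 4 x 4 integer matrix of class `confusion_matrix` with dimnames
#'   `observed` x `predicted`
#' @export
confusion_matrix <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length")
  obs <- factor(as.character(observed), levels = SEVERITY_LEVELS)
  prd <- factor(as.character(predicted), levels = SEVERITY_LEVELS)
  if (length(observed) && (anyNA(obs) || anyNA(prd)))
    stop("invalid class labels")
  cm <- table(observed = obs, predicted = prd)
  cm <- matrix(as.integer(cm), 4, 4,
               dimnames = list(observed = SEVERITY_LEVELS,
                               predicted = SEVERITY_LEVELS))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Producer's, user's and overall accuracy from a confusion matrix
#'
#' Producer's accuracy (per observed class i) = counts\[i,i\] / row total,
#' the complement of omission error; user's accuracy (per predicted class j)
#' = counts\[j,j\] / column total, the complement of commission error;
#' overall accuracy = trace / total. A class with an empty marginal has an
#' undefined rate, reported as `NA` and excluded from any summary.
#'
#' @param cm a 4 x 4 `confusion_matrix` (or plain matrix, observed rows x
#'   predicted columns)
#' @return list with `producer` (named per class), `user` (named per
#'   class), `overall`, `total`
#' @export
accuracy_metrics <- function(cm) {
  m <- unclass(cm)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  rt <- rowSums(m); ct <- colSums(m); dg <- diag(m)
  producer <- ifelse(rt > 0, dg / rt, NA_real_)
  user <- ifelse(ct > 0, dg / ct, NA_real_)
  nms <- rownames(m) %||% SEVERITY_LEVELS[seq_len(nrow(m))]
  list(producer = stats::setNames(producer, nms),
       user = stats::setNames(user, nms),
       overall = sum(dg) / total,
       total = total)
}

#' Write an accuracy report mirroring the confusion-matrix table
#'
#' @param cm a `confusion_matrix`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_accuracy_report <- function(cm, path) {
  met <- accuracy_metrics(cm)
  obj <- list(counts = unclass(cm),
              row_totals = rowSums(cm), col_totals = colSums(cm),
              producer = as.list(met$producer), user = as.list(met$user),
              overall = met$overall, total = met$total)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
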