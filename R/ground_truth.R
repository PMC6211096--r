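#' Severity class labels, from least to most severe
#'
#' Four defoliation severity classes defined on the interpreted defoliation
#' percentage: nil (0-5%), low (10-30%), medium (35-65%), high (70-100%).
#' The gaps between bins cannot occur because interpretation is on a 5% grid.
#' @export
SEVERITY_LEVELS <- c("nil", "low", "medium", "high")

#' Defoliated-area fraction of a cell, expressed at 5% intervals
#'
#' Converts a delineated defoliated surface area within a ground-truth cell
#' into a percentage of the cell area, rounded to the nearest multiple of 5
#' (ties away from zero) — the precision at which an interpreter reads
#' defoliation off aerial orthoimagery.
#'
#' @param defoliated_area defoliated surface area within the cell (m^2)
#' @param cell_area total cell area (m^2); default 900 (a 30 m pixel)
#' @return percentage in `{0, 5, ..., 100}`
#' @examples
#' defoliation_percent(450, 900)  # 50
#' @export
defoliation_percent <- function(defoliated_area, cell_area = 900) {
  if (any(cell_area <= 0)) stop("cell_area must be positive")
  if (any(defoliated_area < 0 | defoliated_area > cell_area))
    stop("defoliated_area must lie in [0, cell_area]")
  5 * round_half_away(100 * defoliated_area / cell_area / 5)
}

#' Bin a defoliation percentage into a severity class
#'
#' Bins: 0-5 nil, 10-30 low, 35-65 medium, 70-100 high. Only multiples of 5
#' in \[0, 100\] are accepted: values between bins cannot arise from 5%-grid
#' interpretation, and rejecting them here surfaces upstream mistakes rather
#' than silently rounding.
#'
#' @param defoliation_pct percentage, a multiple of 5 in \[0, 100\]
#' @return factor with levels [SEVERITY_LEVELS]
#' @examples
#' bin_severity(c(0, 30, 50, 70))
#' @export
bin_severity <- function(defoliation_pct) {
  p <- defoliation_pct
  if (any(is.na(p)) || any(p < 0 | p > 100) || any(p %% 5 != 0))
    stop("defoliation_pct must be a multiple of 5 in [0, 100]")
  cls <- ifelse(p <= 5, "nil",
         ifelse(p <= 30, "low",
         ifelse(p <= 65, "medium", "high")))
  factor(cls, levels = SEVERITY_LEVELS)
}

#' Construct a table of ground-truth cells
#'
#' One row per 30 m interpretation cell, addressed by the (row, col) of the
#' raster pixel it coincides with. If `defoliation_pct` is omitted it is
#' derived from the areas via [defoliation_percent()]; severity is always
#' derived via [bin_severity()].
#'
#' @param cell_id unique identifiers
#' @param row,col 1-based pixel indices into the raster grid
#' @param defoliated_area_m2 defoliated area per cell (m^2)
#' @param cell_area_m2 cell area (m^2), default 900
#' @param defoliation_pct optional pre-interpreted percentages (multiples
#'   of 5); must be consistent with the areas to within the 5% rounding
#' @return data.frame of class `ground_truth` with columns cell_id, row,
#'   col, defoliated_area_m2, cell_area_m2, defoliation_pct, severity
#' @export
ground_truth_cells <- function(cell_id, row, col, defoliated_area_m2,
                               cell_area_m2 = 900, defoliation_pct = NULL) {
  n <- length(cell_id)
  stopifnot(length(row) == n, length(col) == n,
            length(defoliated_area_m2) == n)
  if (anyDuplicated(cell_id)) stop("cell_id values must be unique")
  cell_area_m2 <- rep_len(cell_area_m2, n)
  pct <- defoliation_percent(defoliated_area_m2, cell_area_m2)
  if (!is.null(defoliation_pct)) {
    if (any(defoliation_pct %% 5 != 0))
      stop("defoliation_pct must be multiples of 5")
    if (any(abs(defoliation_pct - pct) > 5))
      stop("defoliation_pct inconsistent with defoliated_area_m2")
    pct <- defoliation_pct
  }
  out <- data.frame(cell_id = cell_id, row = as.integer(row),
                    col = as.integer(col),
                    defoliated_area_m2 = defoliated_area_m2,
                    cell_area_m2 = cell_area_m2,
                    defoliation_pct = pct,
                    severity = bin_severity(pct),
                    stringsAsFactors = FALSE)
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Pair ground-truth cells with dVI values into calibration samples
#'
#' Looks up the dVI value at each cell's pixel and pairs it with the
#' observed defoliation fraction, producing the (x, y) samples the logistic
#' calibration is fitted to. Output order follows input order.
#'
#' @param dvi a [dvi_raster()]
#' @param cells a `ground_truth` table ([ground_truth_cells()])
#' @return data.frame of class `calibration_samples` with columns cell_id,
#'   x (dVI), y (defoliation fraction in \[0, 1\]), severity
#' @export
extract_samples <- function(dvi, cells) {
  stopifnot(inherits(dvi, "dvi_raster"), inherits(cells, "data.frame"))
  if (nrow(cells) == 0L) {
    out <- data.frame(cell_id = character(0), x = numeric(0),
                      y = numeric(0),
                      severity = factor(character(0),
                                        levels = SEVERITY_LEVELS))
    class(out) <- c("calibration_samples", "data.frame")
    return(out)
  }
  d <- dim(dvi$grid)
  oob <- cells$row < 1 | cells$row > d[1] | cells$col < 1 | cells$col > d[2]
  if (any(oob))
    stop("cell(s) outside the raster grid: ",
         paste(cells$cell_id[oob], collapse = ", "))
  x <- dvi$grid[cbind(cells$row, cells$col)]
  if (anyNA(x))
    stop("cell(s) fall on nodata pixels: ",
         paste(cells$cell_id[is.na(x)], collapse = ", "))
  out <- data.frame(cell_id = cells$cell_id, x = x,
                    y = cells$defoliation_pct / 100,
                    severity = cells$severity, stringsAsFactors = FALSE)
  class(out) <- c("calibration_samples", "data.frame")
  out
}

#' Read / write ground-truth and sample tables as CSV
#'
#' `read_ground_truth()` expects columns cell_id, row, col,
#' defoliated_area_m2, cell_area_m2 and optionally defoliation_pct;
#' `write_samples()`/`read_samples()` round-trip the calibration-sample
#' table (cell_id, x, y, severity).
#'
#' @param path CSV file path
#' @return `read_ground_truth()`: a `ground_truth` table;
#'   `read_samples()`: a `calibration_samples` table
#' @export
read_ground_truth <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "row", "col", "defoliated_area_m2")
  if (!all(need %in% names(tab)))
    stop("ground-truth CSV must have columns ",
         paste(need, collapse = ", "))
  ground_truth_cells(
    cell_id = tab$cell_id, row = tab$row, col = tab$col,
    defoliated_area_m2 = tab$defoliated_area_m2,
    cell_area_m2 = if ("cell_area_m2" %in% names(tab)) tab$cell_area_m2
                   else 900,
    defoliation_pct = tab$defoliation_pct)
}

#' @rdname read_ground_truth
#' @param cells a `ground_truth` table to write
#' @export
write_ground_truth <- function(cells, path) {
  write.csv(as.data.frame(cells), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_ground_truth
#' @param samples a `calibration_samples` table to write
#' @export
write_samples <- function(samples, path) {
  write.csv(as.data.frame(samples), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_ground_truth
#' @export
read_samples <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y", "severity")
  if (!all(need %in% names(tab)))
    stop("samples CSV must have columns ", paste(need, collapse = ", "))
  tab$severity <- factor(tab$severity, levels = SEVERITY_LEVELS)
  class(tab) <- c("calibration_samples", "data.frame")
  tab
}
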