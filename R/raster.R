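#' @importFrom stats optim plogis qlogis rnorm runif median setNames
#' @importFrom utils read.csv write.csv
NULL

#' Affine georeference for a north-up raster grid
#'
#' Minimal affine transform for axis-aligned, square-pixel grids: the world
#' x-coordinate of the grid's left edge, the y-coordinate of its top edge,
#' and the pixel size in metres. Rows run north to south, columns west to
#' east, pixel-is-area convention (a cell's world coordinate refers to its
#' centre).
#'
#' @param xmin world x of the left edge of column 1 (m)
#' @param ymax world y of the top edge of row 1 (m)
#' @param cellsize pixel edge length in metres (default 30, the Landsat
#'   multispectral pixel)
#' @return an object of class `grid_transform`
#' @export
grid_transform <- function(xmin = 0, ymax = 0, cellsize = 30) {
  stopifnot(is.numeric(cellsize), length(cellsize) == 1L, cellsize > 0)
  structure(list(xmin = xmin, ymax = ymax, cellsize = cellsize),
            class = "grid_transform")
}

#' @export
format.grid_transform <- function(x, ...) {
  sprintf("grid_transform(xmin = %g, ymax = %g, cellsize = %g m)",
          x$xmin, x$ymax, x$cellsize)
}

#' @export
print.grid_transform <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

same_transform <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b)))
}

#' Convert world coordinates to pixel indices
#'
#' Maps a world coordinate to the (row, col) of the pixel whose centre is
#' nearest, under the transform's north-up, pixel-is-area convention.
#'
#' @param transform a [grid_transform()]
#' @param x,y world coordinates (m)
#' @return integer vector `c(row, col)` (1-based)
#' @export
world_to_cell <- function(transform, x, y) {
  col <- floor((x - transform$xmin) / transform$cellsize) + 1L
  row <- floor((transform$ymax - y) / transform$cellsize) + 1L
  c(row = as.integer(row), col = as.integer(col))
}

## Round half away from zero: deterministic and symmetric about 0, unlike
## the IEEE banker's rounding of base round().
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Multi-band reflectance raster for one acquisition date
#'
#' A stack of co-registered single-band grids of integer-scaled surface
#' reflectance (reflectance x 10^4, valid range 0-10000). Bands are named
#' `"B4"` (red), `"B5"` (NIR), `"B6"` (SWIR1), `"B7"` (SWIR2). Missing
#' pixels are `NA`.
#'
#' @param bands named list of numeric matrices, all the same dimension
#' @param transform a [grid_transform()]
#' @param date_tag acquisition label, e.g. `"2015-09"`; used to order
#'   pre/post pairs, so tags must sort chronologically
#' @return an object of class `band_stack`
#' @export
band_stack <- function(bands, transform = grid_transform(), date_tag = "") {
  stopifnot(is.list(bands), length(bands) >= 1L, !is.null(names(bands)))
  dims <- lapply(bands, dim)
  if (length(unique(dims)) != 1L)
    stop("all bands must share the same dimensions")
  for (nm in names(bands)) {
    v <- bands[[nm]][!is.na(bands[[nm]])]
    if (length(v) && (min(v) < 0 || max(v) > 10000))
      stop(sprintf("band %s has reflectance outside [0, 10000]", nm))
  }
  structure(list(bands = bands, transform = transform, date_tag = date_tag),
            class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("band_stack: %d x %d, bands [%s], date '%s'\n",
              d[1], d[2], paste(names(x$bands), collapse = ", "),
              x$date_tag))
  invisible(x)
}

#' @export
dim.band_stack <- function(x) dim(x$bands[[1]])

#' Boolean pixel mask
#'
#' `TRUE` marks a usable pixel. `kind` records what the mask encodes:
#' `"qa_clear"` (clear terrain, i.e. not water/snow/cloud/shadow) or
#' `"forest_pine"` (pine-dominated forest cover).
#'
#' @param grid logical matrix
#' @param kind one of `"qa_clear"`, `"forest_pine"`
#' @return an object of class `pixel_mask`
#' @export
pixel_mask <- function(grid, kind = c("qa_clear", "forest_pine")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(grid), is.logical(grid))
  if (anyNA(grid)) stop("mask grid must not contain NA")
  structure(list(grid = grid, kind = kind), class = "pixel_mask")
}

#' Build a clear-terrain mask from a QA code raster
#'
#' Vendor QA layers assign each pixel an integer code; the analysis only
#' needs to know which codes mean clear terrain. Accepts either a logical
#' matrix (used as-is) or an integer code matrix plus the set of clear
#' codes.
#'
#' @param qa logical or numeric matrix
#' @param clear_codes codes counted as clear terrain (ignored when `qa` is
#'   already logical)
#' @return a `"qa_clear"` [pixel_mask()]
#' @export
qa_mask <- function(qa, clear_codes = NULL) {
  if (is.logical(qa)) return(pixel_mask(qa, "qa_clear"))
  if (is.null(clear_codes))
    stop("clear_codes is required when qa is a code raster")
  pixel_mask(matrix(qa %in% clear_codes, nrow(qa), ncol(qa)), "qa_clear")
}

#' Single-index raster for one date
#'
#' Index values are stored integer-scaled: normalized-difference indices
#' (NDMI, NDVI, NBR) and the ratio index MSI are multiplied by 10^4; MID is
#' a band sum already in scaled-reflectance units. See [compute_vi()].
#'
#' @param index_name one of `"MID"`, `"MSI"`, `"NDMI"`, `"NDVI"`, `"NBR"`
#' @param grid numeric matrix of scaled index values (`NA` = nodata)
#' @param transform a [grid_transform()]
#' @param date_tag acquisition label
#' @return an object of class `vi_raster`
#' @export
vi_raster <- function(index_name, grid, transform = grid_transform(),
                      date_tag = "") {
  index_name <- match.arg(index_name, VI_NAMES)
  stopifnot(is.matrix(grid))
  structure(list(index_name = index_name, grid = grid,
                 transform = transform, date_tag = date_tag),
            class = "vi_raster")
}

#' @export
print.vi_raster <- function(x, ...) {
  cat(sprintf("vi_raster %s: %d x %d, date '%s', %d valid px\n",
              x$index_name, nrow(x$grid), ncol(x$grid), x$date_tag,
              sum(!is.na(x$grid))))
  invisible(x)
}

#' Pre-minus-post index-change raster (dVI)
#'
#' The change-detection predictor X: one index's pre-outbreak value minus
#' its post-outbreak value, per pixel. See [compute_dvi()].
#'
#' @param index_name index the difference was computed from
#' @param grid numeric matrix (`NA` = nodata)
#' @param transform a [grid_transform()]
#' @return an object of class `dvi_raster`
#' @export
dvi_raster <- function(index_name, grid, transform = grid_transform()) {
  index_name <- match.arg(index_name, VI_NAMES)
  stopifnot(is.matrix(grid))
  structure(list(index_name = index_name, grid = grid, transform = transform),
            class = "dvi_raster")
}

#' @export
print.dvi_raster <- function(x, ...) {
  cat(sprintf("dvi_raster d%s: %d x %d, %d valid px\n",
              x$index_name, nrow(x$grid), ncol(x$grid), sum(!is.na(x$grid))))
  invisible(x)
}

# ---- ASCII-grid I/O ---------------------------------------------------------

#' Write a grid to an ESRI ASCII raster file
#'
#' Plain-text single-band raster format readable by every GIS. Nodata (`NA`)
#' pixels are written as the sentinel `nodata`.
#'
#' @param grid numeric matrix (row 1 = northernmost row)
#' @param path output file path
#' @param transform a [grid_transform()]
#' @param nodata sentinel value written for `NA` pixels (default -9999)
#' @return `path`, invisibly
#' @export
write_ascii_grid <- function(grid, path, transform = grid_transform(),
                             nodata = -9999) {
  stopifnot(is.matrix(grid))
  nr <- nrow(grid); nc <- ncol(grid)
  yll <- transform$ymax - nr * transform$cellsize
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", transform$xmin),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", transform$cellsize),
           sprintf("NODATA_value %.10g", nodata))
  g <- grid
  g[is.na(g)] <- nodata
  body <- apply(g, 1L, function(r) paste(format(r, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster file
#'
#' @param path file path
#' @return list with `grid` (numeric matrix, sentinel replaced by `NA`),
#'   `transform` ([grid_transform()]), and `nodata` (the sentinel read)
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("ASCII grid body size does not match header in ", path)
  grid <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  grid[grid == nodata] <- NA_real_
  tr <- grid_transform(xmin = hdr$xllcorner,
                       ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                       cellsize = hdr$cellsize)
  list(grid = grid, transform = tr, nodata = nodata)
}
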