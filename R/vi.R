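#' Vegetation index names
#'
#' The five indices supported by the workflow, all computable from Landsat-8
#' bands 4 (red), 5 (NIR), 6 (SWIR1) and 7 (SWIR2):
#' \describe{
#'   \item{MID}{middle-infrared sum, B6 + B7}
#'   \item{MSI}{moisture stress index, B6 / B5}
#'   \item{NDMI}{normalized difference moisture index, (B5 - B6)/(B5 + B6)}
#'   \item{NDVI}{normalized difference vegetation index, (B5 - B4)/(B5 + B4)}
#'   \item{NBR}{normalized burn ratio, (B5 - B7)/(B5 + B7)}
#' }
#' @export
VI_NAMES <- c("MID", "MSI", "NDMI", "NDVI", "NBR")

VI_BANDS <- list(MID  = c("B6", "B7"),
                 MSI  = c("B5", "B6"),
                 NDMI = c("B5", "B6"),
                 NDVI = c("B4", "B5"),
                 NBR  = c("B5", "B7"))

#' Compute a vegetation index from a band stack
#'
#' Applies the index formula per pixel on the integer-scaled reflectance.
#' Scale handling: the normalized-difference indices (NDMI, NDVI, NBR) and
#' the MSI band ratio are dimensionless, so the x 10^4 reflectance scaling
#' cancels; their values are re-scaled by 10^4 and rounded half-away-from-zero
#' to integers, giving NDMI/NDVI/NBR in [-10000, 10000] and MSI >= 0. MID is
#' the plain band sum B6 + B7, already in scaled-reflectance units (range
#' [0, 20000]). Pixels where a ratio denominator is zero become nodata; their
#' count is recorded in the `n_degenerate` attribute of the result.
#'
#' Nodata (`NA`) in any required band propagates to the index.
#'
#' @param stack a [band_stack()] holding the required bands
#' @param index_name one of [VI_NAMES]
#' @return a [vi_raster()] with attribute `n_degenerate` (count of pixels
#'   lost to zero denominators)
#' @examples
#' b <- matrix(2000, 2, 2)
#' s <- band_stack(list(B5 = b, B6 = matrix(1000, 2, 2)), date_tag = "t0")
#' compute_vi(s, "MSI")$grid[1, 1]  # 0.5 x 10^4 = 5000
#' @export
compute_vi <- function(stack, index_name) {
  index_name <- match.arg(index_name, VI_NAMES)
  stopifnot(inherits(stack, "band_stack"))
  need <- VI_BANDS[[index_name]]
  missing_b <- setdiff(need, names(stack$bands))
  if (length(missing_b))
    stop(sprintf("index %s requires band(s) %s not present in the stack",
                 index_name, paste(missing_b, collapse = ", ")))
  B <- stack$bands
  n_degenerate <- 0L
  grid <- switch(index_name,
    MID = B$B6 + B$B7,
    MSI = {
      den <- B$B5
      bad <- !is.na(den) & den == 0 & !is.na(B$B6)
      n_degenerate <- sum(bad)
      out <- round_half_away(1e4 * B$B6 / den)
      out[bad] <- NA_real_
      out
    },
    {
      pair <- switch(index_name,
                     NDMI = list(B$B5, B$B6),
                     NDVI = list(B$B5, B$B4),
                     NBR  = list(B$B5, B$B7))
      num <- pair[[1]] - pair[[2]]
      den <- pair[[1]] + pair[[2]]
      bad <- !is.na(den) & den == 0 & !is.na(num)
      n_degenerate <- sum(bad)
      out <- round_half_away(1e4 * num / den)
      out[bad] <- NA_real_
      out
    })
  res <- vi_raster(index_name, grid, stack$transform, stack$date_tag)
  attr(res, "n_degenerate") <- n_degenerate
  res
}

#' Apply one or more pixel masks to a raster
#'
#' Pixels that fail any mask (`FALSE`) are set to nodata. Works on a
#' [vi_raster()], [dvi_raster()] or [band_stack()] (every band of a stack is
#' masked identically). Masking is idempotent and never revives nodata.
#'
#' @param raster the raster to mask
#' @param masks a single [pixel_mask()] or a list of them
#' @return the masked raster, with attribute `n_masked` giving the number of
#'   previously-valid pixels set to nodata
#' @export
apply_masks <- function(raster, masks) {
  if (inherits(masks, "pixel_mask")) masks <- list(masks)
  stopifnot(length(masks) >= 1L,
            all(vapply(masks, inherits, logical(1), "pixel_mask")))
  dims <- if (inherits(raster, "band_stack")) dim(raster$bands[[1]])
          else dim(raster$grid)
  keep <- matrix(TRUE, dims[1], dims[2])
  for (m in masks) {
    if (!identical(dim(m$grid), dims))
      stop("mask shape does not match raster shape")
    keep <- keep & m$grid
  }
  if (inherits(raster, "band_stack")) {
    n_masked <- sum(!keep & !is.na(raster$bands[[1]]))
    raster$bands <- lapply(raster$bands, function(g) {
      g[!keep] <- NA_real_
      g
    })
  } else {
    n_masked <- sum(!keep & !is.na(raster$grid))
    raster$grid[!keep] <- NA_real_
  }
  attr(raster, "n_masked") <- n_masked
  raster
}

#' Pre-minus-post index change (dVI)
#'
#' The change-detection predictor: `pre - post`, per pixel, for one index.
#' A defoliation-driven drop in an index that decreases with foliage loss
#' (NDMI, NDVI, NBR) therefore yields positive dVI, while MSI, which rises
#' under moisture stress, yields negative dMSI.
#'
#' @param vi_pre index raster at the pre-outbreak date
#' @param vi_post index raster at the post-outbreak date (same index, grid
#'   and georeference; `date_tag` must sort after `vi_pre`'s)
#' @return a [dvi_raster()]; a pixel is nodata if either input is nodata
#' @export
compute_dvi <- function(vi_pre, vi_post) {
  stopifnot(inherits(vi_pre, "vi_raster"), inherits(vi_post, "vi_raster"))
  if (vi_pre$index_name != vi_post$index_name)
    stop(sprintf("index mismatch: pre is %s, post is %s",
                 vi_pre$index_name, vi_post$index_name))
  if (!identical(dim(vi_pre$grid), dim(vi_post$grid)))
    stop("pre and post grids differ in shape")
  if (!same_transform(vi_pre$transform, vi_post$transform))
    stop("pre and post georeferences differ")
  if (nzchar(vi_pre$date_tag) && nzchar(vi_post$date_tag) &&
      !(vi_pre$date_tag < vi_post$date_tag))
    stop(sprintf("pre date '%s' does not precede post date '%s'",
                 vi_pre$date_tag, vi_post$date_tag))
  dvi_raster(vi_pre$index_name, vi_pre$grid - vi_post$grid, vi_pre$transform)
}

#' Screen a multi-date index series for temporal stability
#'
#' Before attributing an index change to an outbreak, the pre-outbreak years
#' should show no abrupt change. Computes the mean index over valid pixels
#' for each date and the relative change between every pair of dates
#' (|later - earlier| / |earlier|); the series is flagged unstable if any
#' relative change exceeds `rel_tolerance`.
#'
#' @param series list of [vi_raster()]s of the same index, in chronological
#'   order, already masked to the common valid area
#' @param rel_tolerance maximum tolerated relative change in the masked mean
#'   (default 0.10)
#' @return list with `index_name`, `date_tags`, `means` (per-date masked
#'   means), `rel_changes` (data.frame from/to/rel_change), and `stable`
#' @export
temporal_stability_check <- function(series, rel_tolerance = 0.10) {
  stopifnot(is.list(series), length(series) >= 2L,
            all(vapply(series, inherits, logical(1), "vi_raster")))
  idx <- unique(vapply(series, function(v) v$index_name, character(1)))
  if (length(idx) != 1L)
    stop("all rasters in the series must hold the same index")
  means <- vapply(series, function(v) {
    ok <- !is.na(v$grid)
    if (!any(ok)) stop(sprintf("no valid pixels at date '%s'", v$date_tag))
    mean(v$grid[ok])
  }, numeric(1))
  tags <- vapply(series, function(v) v$date_tag, character(1))
  pairs <- utils::combn(length(series), 2L)
  rel <- apply(pairs, 2L, function(p) {
    abs(means[p[2]] - means[p[1]]) / abs(means[p[1]])
  })
  changes <- data.frame(from = tags[pairs[1, ]], to = tags[pairs[2, ]],
                        rel_change = rel, stringsAsFactors = FALSE)
  list(index_name = idx, date_tags = tags, means = means,
       rel_changes = changes, stable = all(rel <= rel_tolerance),
       rel_tolerance = rel_tolerance)
}
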