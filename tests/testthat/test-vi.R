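test_that("index formulas give the expected scaled values", {
  s <- const_stack(list(B4 = 2000, B5 = 2000, B6 = 1500, B7 = 800))
  expect_equal(compute_vi(s, "NDVI")$grid[1, 1], 0)       # B5 = B4
  expect_equal(compute_vi(s, "MID")$grid[1, 1], 2300)     # 1500 + 800
  s2 <- const_stack(list(B5 = 3000, B6 = 1500))
  expect_equal(compute_vi(s2, "MSI")$grid[1, 1], 5000)    # 0.5 x 10^4
  # hand-computed normalized values
  s3 <- const_stack(list(B4 = 500, B5 = 3000, B6 = 1000, B7 = 600))
  expect_equal(compute_vi(s3, "NDMI")$grid[1, 1],
               round(1e4 * (3000 - 1000) / (3000 + 1000)))
  expect_equal(compute_vi(s3, "NBR")$grid[1, 1],
               round(1e4 * (3000 - 600) / (3000 + 600)))
  expect_equal(compute_vi(s3, "NDVI")$grid[1, 1],
               round(1e4 * (3000 - 500) / (3000 + 500)))
})

test_that("scaled index rounding is half-away-from-zero, symmetric in sign", {
  # (B5 - B4)/(B5 + B4) = +/-0.5/10000 -> +/-0.5 scaled: an exact
  # rounding tie (both reflectances are representable binary fractions)
  s_pos <- const_stack(list(B4 = 4999.75, B5 = 5000.25), nr = 1, nc = 1)
  s_neg <- const_stack(list(B4 = 5000.25, B5 = 4999.75), nr = 1, nc = 1)
  expect_equal(compute_vi(s_pos, "NDVI")$grid[1, 1], 1)
  expect_equal(compute_vi(s_neg, "NDVI")$grid[1, 1], -1)
})

test_that("missing bands and zero denominators are handled", {
  s <- const_stack(list(B5 = 2000, B6 = 1000))
  expect_error(compute_vi(s, "NDVI"), "requires band")
  b5 <- matrix(2000, 2, 2); b5[1, 1] <- 0
  s0 <- const_stack(list(B5 = b5, B6 = matrix(1000, 2, 2)))
  v <- compute_vi(s0, "MSI")
  expect_true(is.na(v$grid[1, 1]))
  expect_equal(attr(v, "n_degenerate"), 1L)
  expect_equal(sum(!is.na(v$grid)), 3L)
})

test_that("valid index values respect their theoretical bounds", {
  set.seed(42)
  for (i in 1:20) {
    bands <- lapply(c(B4 = 1, B5 = 1, B6 = 1, B7 = 1), function(.)
      matrix(sample(0:10000, 25, replace = TRUE), 5, 5))
    s <- band_stack(bands, date_tag = "t")
    for (idx in c("NDMI", "NDVI", "NBR")) {
      g <- compute_vi(s, idx)$grid
      expect_true(all(abs(g[!is.na(g)]) <= 1e4))
    }
    mid <- compute_vi(s, "MID")$grid
    expect_true(all(mid[!is.na(mid)] >= 0 & mid[!is.na(mid)] <= 2e4))
    msi <- compute_vi(s, "MSI")$grid
    expect_true(all(msi[!is.na(msi)] >= 0))
  }
})

test_that("masking is correct, idempotent and closed over nodata", {
  s <- const_stack(list(B5 = 2000, B6 = 1000), nr = 6, nc = 6)
  v <- compute_vi(s, "MSI")
  all_true <- pixel_mask(matrix(TRUE, 6, 6), "qa_clear")
  expect_equal(apply_masks(v, all_true)$grid, v$grid)
  all_false <- pixel_mask(matrix(FALSE, 6, 6), "qa_clear")
  expect_true(all(is.na(apply_masks(v, all_false)$grid)))
  # patch mask: masked count equals the patch pixel count
  patch <- matrix(TRUE, 6, 6); patch[1:2, 1:3] <- FALSE
  m <- pixel_mask(patch, "qa_clear")
  masked <- apply_masks(v, m)
  expect_equal(attr(masked, "n_masked"), 6L)
  # idempotence: second application masks nothing new
  twice <- apply_masks(masked, m)
  expect_identical(twice$grid, masked$grid)
  expect_equal(attr(twice, "n_masked"), 0L)
  # nodata closure: NA pixels never come back
  expect_true(all(is.na(apply_masks(masked, all_true)$grid[!patch])))
  expect_error(apply_masks(v, pixel_mask(matrix(TRUE, 2, 2), "qa_clear")),
               "shape")
})

test_that("cloud-patch masking of a synthetic scene counts the patch", {
  sc <- generate_scene(scene_params(shape = c(40L, 40L),
                                    cloud_fraction = 0.10, seed = 9))
  patch_size <- sum(!sc$qa$grid)
  v <- compute_vi(sc$pre, "MSI")
  expect_equal(attr(apply_masks(v, sc$qa), "n_masked"), patch_size)
})

test_that("dVI is pre minus post, antisymmetric, and strict about inputs", {
  set.seed(7)
  g1 <- matrix(sample(-5000:5000, 16), 4, 4)
  g2 <- matrix(sample(-5000:5000, 16), 4, 4)
  g1[2, 2] <- NA
  a <- vi_raster("NDVI", g1, date_tag = "2015-09")
  b <- vi_raster("NDVI", g2, date_tag = "2016-03")
  expect_true(all(compute_dvi(a, vi_raster("NDVI", g1,
                                           date_tag = "2016-03"))$grid == 0,
                  na.rm = TRUE))
  d <- compute_dvi(a, b)
  expect_equal(d$grid[1, 1], g1[1, 1] - g2[1, 1])
  expect_true(is.na(d$grid[2, 2]))
  # antisymmetry (swap date tags so ordering passes both ways)
  a2 <- vi_raster("NDVI", g2, date_tag = "2015-09")
  b2 <- vi_raster("NDVI", g1, date_tag = "2016-03")
  expect_equal(compute_dvi(a2, b2)$grid, -d$grid)
  # a pre/post pair sitting on the published dNDVI nil/low limit
  p1 <- vi_raster("NDVI", matrix(7000, 1, 1), date_tag = "a")
  p2 <- vi_raster("NDVI", matrix(6257, 1, 1), date_tag = "b")
  expect_equal(compute_dvi(p1, p2)$grid[1, 1], 743)
  expect_error(compute_dvi(a, vi_raster("NBR", g2, date_tag = "z")),
               "index mismatch")
  expect_error(compute_dvi(b, a), "precede")
})

test_that("temporal stability screen flags abrupt pre-outbreak change", {
  g <- matrix(5000, 5, 5)
  mk <- function(m, tag) vi_raster("NDMI", m, date_tag = tag)
  same <- list(mk(g, "2013"), mk(g, "2014"), mk(g, "2015"))
  rep1 <- temporal_stability_check(same)
  expect_true(rep1$stable)
  expect_true(all(rep1$rel_changes$rel_change == 0))
  jump <- list(mk(g, "2013"), mk(g * 1.5, "2014"))
  expect_false(temporal_stability_check(jump)$stable)
  expect_error(temporal_stability_check(list(mk(g * NA, "2013"),
                                             mk(g, "2014"))),
               "no valid pixels")
})

test_that("a quiet pre-outbreak series with 1% noise is stable", {
  n_stable <- 0L
  for (s in 1:100) {
    set.seed(s)
    series <- lapply(c("2013", "2014", "2015"), function(tag)
      vi_raster("NDMI", matrix(rnorm(400, 5000, 50), 20, 20),
                date_tag = tag))
    n_stable <- n_stable + temporal_stability_check(series)$stable
  }
  expect_equal(n_stable, 100L)
})
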