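# Published dMSI coefficients used as a convenient, well-characterized
# curve throughout: a = -3.3570352, b = -0.0092755.
ref_a <- -3.3570352
ref_b <- -0.0092755

test_that("logistic forward curve behaves at its landmarks", {
  expect_equal(logistic_forward(2.3, -0.7, -2.3 / -0.7), 0.5)
  expect_equal(logistic_forward(ref_a, ref_b, -ref_a / ref_b), 0.5)
  # flat curve when b = 0
  expect_equal(logistic_forward(1.2, 0, c(-1e3, 0, 1e3)),
               rep(plogis(1.2), 3))
  # value at the published nil/low dMSI limit is the 10% boundary
  expect_equal(logistic_forward(ref_a, ref_b, -125.04), 0.100, tolerance = 1e-4)
  # overflow-safe far in the tails
  expect_equal(logistic_forward(0, 1, 1e6), 1)
  expect_equal(logistic_forward(0, 1, -1e6), 0)
})

test_that("threshold inversion reproduces the published limits", {
  msi <- list(a = ref_a, b = ref_b)
  expect_equal(round(invert_threshold(msi, 0.10)), -125)
  expect_equal(round(invert_threshold(msi, 0.35)), -295)
  expect_equal(round(invert_threshold(msi, 0.70)), -453)
  mid <- list(a = -3.1299111, b = -0.0041928)
  expect_equal(round(invert_threshold(mid, 0.70)), -949)
  expect_equal(invert_threshold(msi, 0.5), -msi$a / msi$b)
  expect_error(invert_threshold(msi, 0), "strictly")
  expect_error(invert_threshold(msi, 1), "strictly")
  expect_error(invert_threshold(list(a = 1, b = 0), 0.5), "b = 0")
})

test_that("forward and inverse are a round trip to 1e-9", {
  fits <- list(list(a = ref_a, b = ref_b),
               list(a = -3.5552389, b = 0.0014107),
               list(a = 2, b = 0.3))
  ys <- seq(0.1, 0.9, by = 0.1)
  for (f in fits) {
    x <- invert_threshold(f, ys)
    expect_equal(logistic_forward(f$a, f$b, x), ys, tolerance = 1e-9)
  }
})

test_that("fitting samples that lie exactly on a curve recovers it", {
  x <- seq(-700, 150, length.out = 20)
  y <- logistic_forward(ref_a, ref_b, x)
  f <- fit_logistic(data.frame(x = x, y = y))
  expect_equal(f$a, ref_a, tolerance = 1e-6)
  expect_equal(f$b, ref_b, tolerance = 1e-6)
  expect_equal(f$r2_mcfadden, mcfadden_r2(f))
  expect_gte(f$loglik_full, f$loglik_null)
})

test_that("degenerate calibration inputs are rejected", {
  x <- 1:10
  expect_error(fit_logistic(data.frame(x = x, y = rep(0.4, 10))),
               "all equal|degenerate")
  expect_error(fit_logistic(data.frame(x = rep(1, 10),
                                       y = seq(0, 1, length.out = 10))),
               "all equal")
  expect_error(fit_logistic(data.frame(x = 1:3, y = c(0, 0.5, 1))),
               "at least 4")
  expect_error(fit_logistic(data.frame(x = c(1, 2, 3, Inf),
                                       y = c(0, 0.3, 0.6, 1))), "finite")
})

test_that("the fitter agrees with the quasi-binomial GLM on real-shaped data", {
  for (s in 1:3) {
    d <- curve_samples(ref_a, ref_b, seed = s)
    f <- fit_logistic(d)
    g <- suppressWarnings(stats::glm(y ~ x, data = d,
                                     family = stats::quasibinomial()))
    expect_equal(f$a, unname(stats::coef(g)[1]), tolerance = 1e-5)
    expect_equal(f$b, unname(stats::coef(g)[2]), tolerance = 1e-5)
  }
})

test_that("the fitted optimum matches a brute-force likelihood grid", {
  for (s in c(11, 22, 33)) {
    d <- curve_samples(ref_a, ref_b, seed = s)
    f <- fit_logistic(d)
    g <- grid_loglik_argmax(d$x, d$y,
                            a_range = ref_a + c(-0.6, 0.6),
                            b_range = ref_b + c(-0.002, 0.002))
    expect_lte(abs(f$a - g$a), g$step_a)
    expect_lte(abs(f$b - g$b), g$step_b)
  }
})

test_that("independent x and y give a near-zero slope and R2", {
  r2 <- numeric(100)
  babs <- numeric(100)
  for (s in 1:100) {
    set.seed(s)
    d <- curve_samples(ref_a, ref_b, seed = s)
    d$x <- sample(d$x)      # break the association
    f <- fit_logistic(d)
    r2[s] <- f$r2_mcfadden
    babs[s] <- abs(f$b)
  }
  expect_lt(median(r2), 0.05)
  expect_lt(median(babs), abs(ref_b) / 5)
})

test_that("McFadden R2 is 1 - ll_full/ll_null, clipped, and guarded", {
  f0 <- list(loglik_full = -30, loglik_null = -30)
  expect_equal(mcfadden_r2(f0), 0)
  expect_equal(mcfadden_r2(list(loglik_full = -1e-9, loglik_null = -30)),
               1, tolerance = 1e-9)
  expect_equal(mcfadden_r2(list(loglik_full = -10, loglik_null = -40)),
               0.75)
  expect_error(mcfadden_r2(list(loglik_full = 0, loglik_null = 0)),
               "undefined")
})

test_that("threshold sets carry orientation and reproduce published rows", {
  msi <- derive_threshold_set(reference_fit("MSI"))
  expect_equal(msi$limits_x_rounded, c(-125, -295, -453))
  expect_equal(msi$orientation, "decreasing")
  expect_true(all(diff(msi$limits_x) < 0))
  ndmi <- derive_threshold_set(reference_fit("NDMI"))
  expect_equal(ndmi$limits_x_rounded, c(963, 2081, 3121))
  expect_equal(ndmi$orientation, "increasing")
  expect_true(all(diff(ndmi$limits_x) > 0))
  # symmetric boundaries around y = 0.5 with a = 0 give symmetric limits
  sym <- derive_threshold_set(
    structure(list(index_name = "NDVI", a = 0, b = 0.002),
              class = "logistic_fit"),
    boundaries_y = c(0.2, 0.5, 0.8))
  expect_equal(sym$limits_x[1], -sym$limits_x[3])
  expect_equal(sym$limits_x[2], 0)
  expect_error(derive_threshold_set(reference_fit("MSI"),
                                    boundaries_y = c(0.5, 0.2)),
               "increasing")
})

test_that("model comparison ranks by R2 with a stated lexicographic tie rule", {
  mk <- function(idx, r2) structure(
    list(index_name = idx, a = -3, b = -0.01, r2_mcfadden = r2, n = 50L),
    class = "logistic_fit")
  fits <- Map(mk, c("MID", "MSI", "NDMI", "NDVI", "NBR"),
              c(0.740, 0.815, 0.749, 0.787, 0.776))
  rk <- compare_models(fits)
  expect_equal(rk$index_name[1], "MSI")
  expect_equal(attr(rk, "best"), "MSI")
  expect_equal(rk$index_name,
               c("MSI", "NDVI", "NBR", "NDMI", "MID"))
  expect_false(any(rk$tied))
  single <- compare_models(fits[2])
  expect_equal(nrow(single), 1L)
  expect_true(single$best)
  tie <- compare_models(list(mk("NDVI", 0.7), mk("MID", 0.7)))
  expect_equal(tie$index_name, c("MID", "NDVI"))   # lexicographic
  expect_true(all(tie$tied))
  expect_error(compare_models(list()), "no fits")
})
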