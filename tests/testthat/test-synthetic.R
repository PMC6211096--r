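test_that("scene generation is deterministic given the seed", {
  p <- scene_params(shape = c(30L, 30L), seed = 42L)
  s1 <- generate_scene(p)
  s2 <- generate_scene(p)
  expect_identical(s1$pre$bands, s2$pre$bands)
  expect_identical(s1$post$bands, s2$post$bands)
  expect_identical(s1$true_f, s2$true_f)
  s3 <- generate_scene(scene_params(shape = c(30L, 30L), seed = 43L))
  expect_false(identical(s1$pre$bands, s3$pre$bands))
})

test_that("no defoliation and no noise leave the scene unchanged", {
  s <- generate_scene(scene_params(shape = c(20L, 20L),
                                   defoliation_field = 0, noise_sd = 0,
                                   cloud_fraction = 0, seed = 1))
  expect_identical(s$pre$bands, s$post$bands)
  for (idx in VI_NAMES) {
    d <- compute_dvi(compute_vi(s$pre, idx), compute_vi(s$post, idx))
    expect_true(all(d$grid == 0))
  }
})

test_that("full defoliation follows the closed-form band response", {
  s <- generate_scene(scene_params(shape = c(10L, 10L),
                                   defoliation_field = 1, noise_sd = 0,
                                   cloud_fraction = 0,
                                   nonforest_fraction = 0, seed = 1))
  # MSI_post / MSI_pre = (1 + 0.30) / (1 - 0.50) = 2.6
  ratio <- (s$post$bands$B6 / s$post$bands$B5) /
           (s$pre$bands$B6 / s$pre$bands$B5)
  expect_equal(max(abs(ratio - 2.6)), 0, tolerance = 1e-3)
  # per-band: post = pre * (1 + coef)
  expect_equal(s$post$bands$B5, round(s$pre$bands$B5 * 0.5),
               tolerance = 1e-12)
})

test_that("scene structure invariants hold", {
  s <- generate_scene(scene_params(shape = c(40L, 40L), seed = 5))
  expect_equal(dim(s$true_f), c(40L, 40L))
  expect_equal(dim(s$qa$grid), c(40L, 40L))
  expect_equal(dim(s$forest$grid), c(40L, 40L))
  expect_true(all(s$true_f >= 0 & s$true_f <= 1))
  expect_true(all(s$true_f[!s$forest$grid] == 0))
  for (b in s$pre$bands) expect_true(all(b >= 0 & b <= 10000))
  for (b in s$post$bands) expect_true(all(b >= 0 & b <= 10000))
  # patch sizes approximate the requested fractions
  expect_equal(sum(!s$qa$grid) / 1600, 0.05, tolerance = 0.05)
  expect_equal(sum(!s$forest$grid) / 1600, 0.15, tolerance = 0.05)
})

test_that("noiseless MSI rises, and dMSI falls, monotonically with defoliation", {
  s <- generate_scene(scene_params(shape = c(20L, 50L), noise_sd = 0,
                                   cloud_fraction = 0,
                                   nonforest_fraction = 0, seed = 2))
  msi_pre <- compute_vi(s$pre, "MSI")
  msi_post <- compute_vi(s$post, "MSI")
  d <- compute_dvi(msi_pre, msi_post)
  # gradient field: f increases with column, constant within a column
  f_by_col <- s$true_f[1, ]
  expect_true(all(diff(f_by_col) > 0))
  expect_true(all(diff(msi_post$grid[1, ]) >= 0))
  expect_true(all(diff(d$grid[1, ]) <= 0))
  expect_lt(d$grid[1, 50], d$grid[1, 1])
  # hence a fitted dMSI slope is negative
  fx <- make_fixture("tiny", seed = 2)
  dvi <- compute_dvi(compute_vi(fx$scene$pre, "MSI"),
                     compute_vi(fx$scene$post, "MSI"))
  f <- fit_logistic(extract_samples(dvi, fx$truth), index_name = "MSI")
  expect_lt(f$b, 0)
})

test_that("ground-truth draws honour quotas, rounding and determinism", {
  s <- generate_scene(scene_params(shape = c(60L, 60L), seed = 7))
  gt <- generate_ground_truth(s, seed = 3)
  expect_equal(nrow(gt), 50L)
  expect_equal(as.integer(table(gt$severity)), c(10L, 23L, 8L, 9L))
  expect_true(all(gt$defoliation_pct %% 5 == 0))
  gt2 <- generate_ground_truth(s, seed = 3)
  expect_identical(gt, gt2)
  # all drawn cells are clear and forested
  eligible <- s$qa$grid & s$forest$grid
  expect_true(all(eligible[cbind(gt$row, gt$col)]))
  # quota 0 everywhere -> empty table
  empty <- generate_ground_truth(s, class_quotas = c(nil = 0, low = 0,
                                                     medium = 0, high = 0))
  expect_equal(nrow(empty), 0L)
  # unsatisfiable quota names the class
  flat <- generate_scene(scene_params(shape = c(20L, 20L),
                                      defoliation_field = 0, seed = 1))
  expect_error(generate_ground_truth(flat,
                                     class_quotas = c(nil = 1, low = 0,
                                                      medium = 0, high = 2)),
               "high")
})

test_that("exact fractions pass through when interpreter rounding is off", {
  s <- generate_scene(scene_params(shape = c(20L, 20L),
                                   defoliation_field = 0.5, noise_sd = 0,
                                   cloud_fraction = 0,
                                   nonforest_fraction = 0, seed = 1))
  gt <- generate_ground_truth(s, class_quotas = c(nil = 0, low = 0,
                                                  medium = 5, high = 0),
                              interpreter_rounding = 0, seed = 1)
  expect_true(all(gt$defoliation_pct == 50))
})

test_that("stress fixtures exercise the documented failure paths", {
  st <- make_fixture("stress", seed = 4)
  expect_error(generate_ground_truth(st$all_cloud), "eligible")
  # zero-variance scene: identical y at every cell kills the fit
  dvi <- compute_dvi(compute_vi(st$zero_variance$pre, "MSI"),
                     compute_vi(st$zero_variance$post, "MSI"))
  cells <- ground_truth_cells(sprintf("z%d", 1:6), row = 1:6, col = 1:6,
                              defoliated_area_m2 = rep(0, 6))
  smp <- extract_samples(dvi, cells)
  expect_error(fit_logistic(smp), "all equal|degenerate")
  # boundary defoliation: f = 1 everywhere still yields valid reflectance
  expect_true(all(st$full_defoliation$post$bands$B5 >= 0))
})

test_that("the tiny fixture runs the whole pipeline end to end", {
  r <- run_synthetic_pipeline("tiny", seed = 1)
  expect_s3_class(r, "pipeline_run")
  expect_length(r$fits, 5L)
  expect_true(r$best_index %in% VI_NAMES)
  expect_equal(sum(r$confusion), 50)
  expect_true(r$accuracy$overall > 0.5)
})
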