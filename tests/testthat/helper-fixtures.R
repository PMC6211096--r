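# Shared fixture builders. Everything is generated in code; no files.

# Small band stack from per-band constants or matrices.
const_stack <- function(vals, nr = 3, nc = 3, date_tag = "t0") {
  bands <- lapply(vals, function(v) {
    if (is.matrix(v)) v else matrix(v, nr, nc)
  })
  band_stack(bands, grid_transform(0, nr * 30, 30), date_tag = date_tag)
}

# Calibration samples drawn from a known logistic curve (decreasing slope),
# with the standard 10/23/8/9 class mix of x locations and the interpreted
# response rounded to the 5% grid. The generating (a, b) are the recovery
# oracle.
curve_samples <- function(a, b, n_scale = 1L, seed = 1L,
                          rounding = 0.05) {
  stopifnot(b < 0)
  set.seed(seed)
  quotas <- c(10L, 23L, 8L, 9L) * n_scale
  bnd <- (qlogis(c(0.10, 0.35, 0.70)) - a) / b
  x <- c(runif(quotas[1], bnd[1], bnd[1] + 250),
         runif(quotas[2], bnd[2], bnd[1]),
         runif(quotas[3], bnd[3], bnd[2]),
         runif(quotas[4], bnd[3] - 350, bnd[3]))
  y <- logistic_forward(a, b, x)
  if (rounding > 0) y <- rounding * round(y / rounding)
  data.frame(x = x, y = y)
}

# Brute-force maximum of the fractional Bernoulli log-likelihood on an
# (a, b) grid: the independent optimizer oracle.
grid_loglik_argmax <- function(x, y, a_range, b_range, n_grid = 400L) {
  a_grid <- seq(a_range[1], a_range[2], length.out = n_grid)
  b_grid <- seq(b_range[1], b_range[2], length.out = n_grid)
  best <- c(ll = -Inf, a = NA_real_, b = NA_real_)
  for (a in a_grid) {
    eta <- a + outer(x, b_grid)           # n x n_grid
    p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    # p is clamped away from 0/1, so the y = 0 and y = 1 terms vanish
    # without special-casing
    ll <- colSums(y * log(p) + (1 - y) * log(1 - p))
    k <- which.max(ll)
    if (ll[k] > best["ll"]) best <- c(ll = ll[k], a = a, b = b_grid[k])
  }
  list(a = unname(best["a"]), b = unname(best["b"]),
       step_a = diff(a_range) / (n_grid - 1),
       step_b = diff(b_range) / (n_grid - 1))
}

# Overall map/truth agreement at the sampled cells for one synthetic run.
end_to_end_accuracy <- function(seed, noise_sd, preset = "tiny") {
  fx <- make_fixture(preset, seed = seed, noise_sd = noise_sd)
  run_pipeline(fx$scene$pre, fx$scene$post, fx$scene$qa, fx$scene$forest,
               fx$truth, indices = "MSI")$accuracy$overall
}
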