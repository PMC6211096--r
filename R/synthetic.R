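#' Parameters for a synthetic paired-date scene
#'
#' Describes a simulated pine-forest landscape observed at a pre-outbreak
#' and a post-outbreak date. Healthy-pine reflectance baselines and the
#' per-band fractional response at full defoliation encode the expected
#' spectral physiology of a moisture-stressed, defoliating canopy: NIR (B5)
#' drops while red (B4) and the SWIR bands (B6, B7) rise as foliage is lost
#' and evapotranspiration falls.
#'
#' @param shape `c(rows, cols)` of the scene (30 m pixels)
#' @param defoliation_field `"gradient"` (fraction rises linearly west to
#'   east from 0 to 1), `"patchy"` (randomly placed smooth circular
#'   outbreak patches), or a single constant fraction in \[0, 1\]
#' @param band_baselines named mean reflectance per band for healthy pine,
#'   on the x 10^4 scale (defaults B4 = 300, B5 = 2800, B6 = 1600,
#'   B7 = 900)
#' @param response_coefs named fractional change per band at full
#'   defoliation (defaults B4 +0.40, B5 -0.50, B6 +0.30, B7 +0.35)
#' @param noise_sd additive white reflectance noise sd, scaled units
#'   (default 50)
#' @param cloud_fraction fraction of the scene covered by a cloud patch
#'   (QA mask false there; default 0.05)
#' @param nonforest_fraction fraction covered by a non-forest patch with
#'   bare-ground reflectance (forest mask false there; default 0.15)
#' @param seed integer seed; every stochastic draw in the scene flows from
#'   it
#' @return list of class `scene_params`
#' @export
scene_params <- function(shape = c(300L, 300L),
                         defoliation_field = "gradient",
                         band_baselines = c(B4 = 300, B5 = 2800,
                                            B6 = 1600, B7 = 900),
                         response_coefs = c(B4 = 0.40, B5 = -0.50,
                                            B6 = 0.30, B7 = 0.35),
                         noise_sd = 50,
                         cloud_fraction = 0.05,
                         nonforest_fraction = 0.15,
                         seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 4L),
            noise_sd >= 0,
            cloud_fraction >= 0, cloud_fraction <= 1,
            nonforest_fraction >= 0, nonforest_fraction <= 1)
  if (is.numeric(defoliation_field)) {
    stopifnot(length(defoliation_field) == 1L,
              defoliation_field >= 0, defoliation_field <= 1)
  } else {
    defoliation_field <- match.arg(defoliation_field,
                                   c("gradient", "patchy"))
  }
  if (!all(c("B4", "B5", "B6", "B7") %in% names(band_baselines)))
    stop("band_baselines must name B4, B5, B6, B7")
  if (!all(c("B4", "B5", "B6", "B7") %in% names(response_coefs)))
    stop("response_coefs must name B4, B5, B6, B7")
  if (any(band_baselines < 0 | band_baselines > 10000))
    stop("band_baselines must lie in [0, 10000]")
  structure(list(shape = as.integer(shape),
                 defoliation_field = defoliation_field,
                 band_baselines = band_baselines,
                 response_coefs = response_coefs,
                 noise_sd = noise_sd,
                 cloud_fraction = cloud_fraction,
                 nonforest_fraction = nonforest_fraction,
                 seed = as.integer(seed)),
            class = "scene_params")
}

## Deterministic rectangular patch of ~`fraction` of the scene area,
## anchored to a corner so its pixel count is exact and testable.
corner_patch <- function(shape, fraction, corner) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (fraction <= 0) return(m)
  n_target <- round(fraction * prod(shape))
  h <- max(1L, min(shape[1], round(sqrt(n_target * shape[1] / shape[2]))))
  w <- max(1L, min(shape[2], round(n_target / h)))
  if (corner == "nw") m[seq_len(h), seq_len(w)] <- TRUE
  else m[shape[1] - seq_len(h) + 1L, shape[2] - seq_len(w) + 1L] <- TRUE
  m
}

make_defoliation_field <- function(params) {
  nr <- params$shape[1]; nc <- params$shape[2]
  f <- params$defoliation_field
  if (is.numeric(f)) return(matrix(f, nr, nc))
  if (f == "gradient") {
    return(matrix(rep((seq_len(nc) - 1) / (nc - 1), each = nr), nr, nc))
  }
  ## patchy: smooth bumps exp(-d^2 / 2 r^2) of random peak severity
  field <- matrix(0, nr, nc)
  n_patch <- max(3L, round(prod(params$shape) / 1500))
  cy <- runif(n_patch, 1, nr)
  cx <- runif(n_patch, 1, nc)
  rad <- runif(n_patch, 0.04, 0.15) * min(nr, nc)
  peak <- runif(n_patch, 0.4, 1)
  rows <- row(field); cols <- col(field)
  for (k in seq_len(n_patch)) {
    d2 <- (rows - cy[k])^2 + (cols - cx[k])^2
    field <- pmax(field, peak[k] * exp(-d2 / (2 * rad[k]^2)))
  }
  pmin(field, 1)
}

## Bare-ground reflectance used inside the non-forest patch: brighter red
## and SWIR, lower NIR contrast than canopy.
NONFOREST_REFLECTANCE <- c(B4 = 1200, B5 = 2200, B6 = 2600, B7 = 2100)

#' Generate a synthetic pre/post scene with known defoliation
#'
#' Builds two co-registered four-band stacks. Pre-date bands are the
#' healthy baseline plus noise; post-date bands are the pre values adjusted
#' by the band's response coefficient times the local defoliation fraction,
#' plus independent noise; all reflectance is clamped to \[0, 10000\]. A
#' deterministic cloud patch (north-west corner) is flagged unusable in the
#' QA mask, and a non-forest patch (south-east corner) gets bare-ground
#' reflectance and a false forest mask. The true defoliation fraction is 0
#' outside forest. Fully deterministic given `params$seed`.
#'
#' @param params a [scene_params()]
#' @return list of class `synthetic_scene`: `pre`, `post` ([band_stack()]s),
#'   `true_f` (matrix of defoliation fractions), `qa`, `forest`
#'   ([pixel_mask()]s), `params`
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  nr <- params$shape[1]; nc <- params$shape[2]
  set.seed(params$seed)

  cloud <- corner_patch(params$shape, params$cloud_fraction, "nw")
  nonforest <- corner_patch(params$shape, params$nonforest_fraction, "se")
  f <- make_defoliation_field(params)
  f[nonforest] <- 0

  clamp <- function(g) pmin(pmax(g, 0), 10000)
  noise <- function() {
    if (params$noise_sd == 0) matrix(0, nr, nc)
    else matrix(rnorm(nr * nc, 0, params$noise_sd), nr, nc)
  }
  pre <- list(); post <- list()
  for (bn in c("B4", "B5", "B6", "B7")) {
    base <- matrix(params$band_baselines[[bn]], nr, nc)
    base[nonforest] <- NONFOREST_REFLECTANCE[[bn]]
    pre_b <- clamp(round_half_away(base + noise()))
    post_b <- clamp(round_half_away(
      pre_b * (1 + params$response_coefs[[bn]] * f) + noise()))
    pre[[bn]] <- pre_b
    post[[bn]] <- post_b
  }
  tr <- grid_transform(xmin = 0, ymax = nr * 30, cellsize = 30)
  structure(list(
    pre = band_stack(pre, tr, date_tag = "pre"),
    post = band_stack(post, tr, date_tag = "pst"),
    true_f = f,
    qa = pixel_mask(!cloud, "qa_clear"),
    forest = pixel_mask(!nonforest, "forest_pine"),
    params = params), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "synthetic_scene %d x %d (seed %d): %d cloud px, %d non-forest px\n",
    x$params$shape[1], x$params$shape[2], x$params$seed,
    sum(!x$qa$grid), sum(!x$forest$grid)))
  invisible(x)
}

#' Draw interpreter-style ground-truth cells from a synthetic scene
#'
#' Emulates an analyst selecting 30 m cells from aerial orthoimagery:
#' samples the true defoliation fraction at clear, forested pixels, rounds
#' it to the 5% interpretation grid, bins severity, and draws cells without
#' replacement to meet a per-class quota. Deterministic given `seed`.
#'
#' @param scene a [generate_scene()] result
#' @param class_quotas named counts per severity class (default
#'   `c(nil = 10, low = 23, medium = 8, high = 9)`)
#' @param interpreter_rounding rounding interval for the interpreted
#'   percentage (default 5; use 0 to keep exact fractions, which then must
#'   land on the 5% grid themselves)
#' @param seed integer seed for the cell draw
#' @return a `ground_truth` table ([ground_truth_cells()])
#' @export
generate_ground_truth <- function(scene,
                                  class_quotas = c(nil = 10, low = 23,
                                                   medium = 8, high = 9),
                                  interpreter_rounding = 5,
                                  seed = 1L) {
  stopifnot(inherits(scene, "synthetic_scene"),
            all(SEVERITY_LEVELS %in% names(class_quotas)) ||
              all(names(class_quotas) %in% SEVERITY_LEVELS))
  quotas <- stats::setNames(rep(0L, 4L), SEVERITY_LEVELS)
  quotas[names(class_quotas)] <- as.integer(class_quotas)
  eligible <- scene$qa$grid & scene$forest$grid
  idx <- which(eligible)
  if (sum(quotas) == 0L)
    return(ground_truth_cells(character(0), integer(0), integer(0),
                              numeric(0)))
  if (length(idx) == 0L) stop("no eligible (clear, forested) pixels")
  fvals <- scene$true_f[idx]
  pct <- if (interpreter_rounding > 0)
    interpreter_rounding * round_half_away(100 * fvals / interpreter_rounding)
  else 100 * fvals
  cls <- bin_severity(pct)
  set.seed(seed)
  picked <- integer(0)
  for (lev in SEVERITY_LEVELS) {
    pool <- which(cls == lev)
    if (length(pool) < quotas[[lev]])
      stop(sprintf("cannot satisfy quota for class '%s': need %d, %d eligible",
                   lev, quotas[[lev]], length(pool)))
    picked <- c(picked, pool[sample.int(length(pool), quotas[[lev]])])
  }
  sel <- idx[picked]
  nr <- scene$params$shape[1]
  rows <- ((sel - 1L) %% nr) + 1L
  cols <- ((sel - 1L) %/% nr) + 1L
  ground_truth_cells(
    cell_id = sprintf("cell_%03d", seq_along(sel)),
    row = rows, col = cols,
    defoliated_area_m2 = 900 * pct[picked] / 100,
    cell_area_m2 = 900,
    defoliation_pct = pct[picked])
}

#' Ready-made scene presets for tests and examples
#'
#' `"tiny"` is a 60 x 60 scene sized for unit tests; `"default"` is a
#' 300 x 300 scene mimicking a study-scale pipeline; `"stress"` is a set of
#' degenerate scenes (all-cloud QA, zero-variance constant field, boundary
#' defoliation values) for failure-path testing.
#'
#' @param preset `"tiny"`, `"default"` or `"stress"`
#' @param seed integer seed
#' @param noise_sd override of the preset's noise level (default: preset's)
#' @return for `"tiny"`/`"default"`: list with `scene` and `truth` (50
#'   ground-truth cells in the standard 10/23/8/9 class mix); for
#'   `"stress"`: named list of degenerate `synthetic_scene`s
#' @export
make_fixture <- function(preset = c("tiny", "default", "stress"),
                         seed = 1L, noise_sd = NULL) {
  preset <- match.arg(preset)
  if (preset == "stress") {
    all_cloud <- generate_scene(scene_params(shape = c(20L, 20L),
                                             cloud_fraction = 1,
                                             nonforest_fraction = 0,
                                             seed = seed))
    flat <- generate_scene(scene_params(shape = c(20L, 20L),
                                        defoliation_field = 0,
                                        noise_sd = 0, cloud_fraction = 0,
                                        nonforest_fraction = 0, seed = seed))
    full <- generate_scene(scene_params(shape = c(20L, 20L),
                                        defoliation_field = 1,
                                        noise_sd = 0, cloud_fraction = 0,
                                        nonforest_fraction = 0, seed = seed))
    return(list(all_cloud = all_cloud, zero_variance = flat,
                full_defoliation = full))
  }
  shape <- if (preset == "tiny") c(60L, 60L) else c(300L, 300L)
  p <- scene_params(shape = shape, seed = seed)
  if (!is.null(noise_sd)) p$noise_sd <- noise_sd
  scene <- generate_scene(p)
  truth <- generate_ground_truth(scene, seed = seed + 1L)
  list(scene = scene, truth = truth)
}
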