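# defolcal

Calibrating the severity of insect defoliation in pine forests from
vegetation-index change.

Winter-feeding defoliators such as the pine processionary moth
(*Thaumetopoea pityocampa*) strip pine canopies between autumn and
spring. With a pre-outbreak and a post-outbreak surface-reflectance
image, the loss is visible as a change in vegetation indices built from
the red, NIR and SWIR bands. `defolcal` implements the full
calibrate-and-map workflow for analysts who have satellite reflectance
and a limited set of interpreted ground-truth cells (e.g. from UAV
orthoimagery):

* **Indices and change.** Five indices per date — MID (`B6 + B7`), MSI
  (`B6/B5`), NDMI, NDVI, NBR — on QA- and forest-masked rasters, and
  their per-pixel change `dVI = VI_pre − VI_post` (the predictor *x*),
  plus a multi-year stability screen of the pre-outbreak series.
* **Logistic calibration.** For 30 m cells with interpreted defoliation
  fraction *y* (5% intervals), the model
  `y = 1 / (1 + exp(−(a + b·x)))` is fitted per index by maximizing the
  fractional-response Bernoulli log-likelihood; fits are ranked by
  McFadden's pseudo R² = `1 − ℓ_full/ℓ_null`.
* **Analytic thresholds.** The fitted curve is inverted at the class
  boundaries *y** ∈ {0.10, 0.35, 0.70},
  `x* = (ln(y*/(1−y*)) − a)/b`, giving dVI limits that partition pixels
  into nil (0–5%), low (10–30%), medium (35–65%) and high (70–100%)
  defoliation.
* **Severity map and accuracy.** Threshold classification of the dVI
  raster, and a 4 × 4 confusion matrix against observed classes with
  producer's, user's and overall accuracy.
* **Synthetic scenes.** A deterministic generator of paired pre/post
  band stacks over a known defoliation field — with clouds, non-forest,
  and interpreter-style ground truth — so the entire pipeline is
  testable without any imagery.

Rasters are plain matrices with a 30 m affine georeference; file I/O
uses text formats (ESRI ASCII grid, CSV, JSON).

## Worked example

The numbered scripts under `analysis/` run the workflow on the default
300 × 300 synthetic landscape (`Rscript analysis/01_simulate_scene.R`
through `05_reference_comparison.R`), writing tables to `results/`.
The same computation in a session:

```r
library(defolcal)

fx <- make_fixture("default", seed = 1)   # scene + 50 ground-truth cells
run <- run_pipeline(fx$scene$pre, fx$scene$post,
                    fx$scene$qa, fx$scene$forest, fx$truth)
run$ranking[, c("index_name", "a", "b", "r2_mcfadden", "rank")]
#>   index_name      a          b r2_mcfadden rank
#> 1       NDMI -2.527  0.0011844      0.2932    1
#> 2        NBR -2.394  0.0012068      0.2896    2
#> 3        MSI -2.244 -0.0006523      0.2877    3
#> 4        MID -2.588 -0.0062825      0.2733    4
#> 5       NDVI -1.917  0.0015503      0.2477    5
run$thresholds
#> threshold_set dNDMI (increasing): 279 / 1611 / 2849 at y = 0.1 / 0.35 / 0.7
run$accuracy$overall
#> [1] 0.82
```

Here dNDMI ranks best on this simulated draw; its fitted curve crosses
the 10/35/70% defoliation boundaries at dNDMI = 279/1611/2849, those
limits classify every forest pixel into the four severity classes, and
the map agrees with the observed class at 82% of the 50 calibration
cells. (R² magnitudes under the fractional-response likelihood are
capped by the entropy of mid-range fractions and are only comparable
between indices — see the methods vignette.)

The published reference calibration embedded in the package reproduces
its threshold table and accuracy assessment exactly:

```r
suppressWarnings(reference_threshold_table())
#>  index_name  y_10  y_35  y_70 sign_flag
#>         MID  -222  -599  -949     FALSE
#>         MSI  -125  -295  -453     FALSE
#>        NDMI   963  2081  3121     FALSE
#>        NDVI   743  1636  2466     FALSE
#>         NBR -1034 -2172 -3229      TRUE
accuracy_metrics(reference_confusion())$overall
#> [1] 0.72
```

(The flagged dNBR row: the published slope is negative while the
published limits are positive; magnitudes match exactly, so the signed
inversion is reported with a warning rather than silently corrected.)

## Layout

* `R/` — package code: raster containers and I/O, index/change engine,
  ground-truth handling, logistic calibration and thresholds, severity
  mapping and accuracy, synthetic scene generator, pipeline driver.
* `analysis/` — numbered narrative scripts running the study workflow
  on the synthetic landscape.
* `tests/testthat/` — unit, property and acceptance tests.
* `vignettes/defoliation-calibration.Rmd` — the methods vignette:
  model, assumptions, numerical choices, generator realism and
  limitations.
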