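#!/usr/bin/env Rscript
# Stage 1 — simulate the study landscape.
#
# Builds the default 300 x 300 synthetic scene: paired pre/post four-band
# reflectance stacks driven by a known defoliation gradient, a cloud patch
# masked in QA, a non-forest patch, and 50 interpreter-style ground-truth
# cells in the standard 10/23/8/9 severity mix. Small tables go to
# results/; full rasters go to scratch/ (they are cheap to regenerate).

suppressPackageStartupMessages(library(defolcal))
seed <- 1L

fx <- make_fixture("default", seed = seed)
scene <- fx$scene

dir.create("results", showWarnings = FALSE)
dir.create("scratch/rasters", recursive = TRUE, showWarnings = FALSE)

write_ground_truth(fx$truth, "results/ground_truth_cells.csv")
jsonlite::write_json(
  list(seed = seed, shape = scene$params$shape,
       defoliation_field = scene$params$defoliation_field,
       band_baselines = as.list(scene$params$band_baselines),
       response_coefs = as.list(scene$params$response_coefs),
       noise_sd = scene$params$noise_sd,
       cloud_fraction = scene$params$cloud_fraction,
       nonforest_fraction = scene$params$nonforest_fraction),
  "results/scene_params.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

write_ascii_grid(scene$true_f, "scratch/rasters/true_f.asc",
                 scene$pre$transform)
for (b in names(scene$pre$bands)) {
  write_ascii_grid(scene$pre$bands[[b]],
                   sprintf("scratch/rasters/pre_%s.asc", b),
                   scene$pre$transform)
  write_ascii_grid(scene$post$bands[[b]],
                   sprintf("scratch/rasters/post_%s.asc", b),
                   scene$pre$transform)
}

cat(sprintf("Scene: %d x %d px (30 m), %d cloud px, %d non-forest px\n",
            scene$params$shape[1], scene$params$shape[2],
            sum(!scene$qa$grid), sum(!scene$forest$grid)))
cat("Ground truth class mix:\n")
print(table(fx$truth$severity))
cat("Wrote results/ground_truth_cells.csv, results/scene_params.json\n")
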