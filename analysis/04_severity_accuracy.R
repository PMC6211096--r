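#!/usr/bin/env Rscript
# Stage 4 — severity mapping and accuracy assessment.
#
# Classifies the best index's dVI raster into the four severity classes
# with the stage-3 thresholds, and assesses agreement with the observed
# classes at the 50 ground-truth cells via a confusion matrix with
# producer's / user's / overall accuracy.

suppressPackageStartupMessages(library(defolcal))
seed <- 1L

fx <- make_fixture("default", seed = seed)
scene <- fx$scene
run <- run_pipeline(scene$pre, scene$post, scene$qa, scene$forest,
                    fx$truth)

dir.create("results", showWarnings = FALSE)
dir.create("scratch/rasters", recursive = TRUE, showWarnings = FALSE)
write_severity_map(run$severity, "scratch/rasters/severity.asc")
write_accuracy_report(run$confusion, "results/accuracy.json")

cat(sprintf("Severity map (d%s): pixel counts %s\n", run$best_index,
            paste(sprintf("%s=%d", names(run$severity$class_counts),
                          run$severity$class_counts), collapse = " ")))
cat("\nConfusion matrix (rows observed, columns predicted):\n")
print(unclass(run$confusion))
met <- run$accuracy
cat(sprintf("\nOverall accuracy: %.2f\n", met$overall))
cat("Producer's accuracy:", sprintf("%s=%.2f", names(met$producer),
                                    met$producer), "\n")
cat("User's accuracy:    ", sprintf("%s=%.2f", names(met$user),
                                    met$user), "\n")
cat("Wrote results/accuracy.json, scratch/rasters/severity.asc\n")
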