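#!/usr/bin/env Rscript
# Generate one example of each ground-truthed phantom (sheet stack, division
# image, cross-section, ablation pair) and write them, with their ground
# truth, under results/phantoms/. These are the synthetic stand-ins for the
# confocal acquisitions the pipeline targets.

suppressMessages(library(pnpolarity))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
out <- "results/phantoms"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

p <- sheet_phantom_params(border_anisotropy_a = 1.5, orientation_mean_deg = 0,
                          orientation_kappa = 4, seed = seed)
ph <- generate_sheet_stack(p)
write_stack(ph$stack, file.path(out, "sheet.tif"))
write_labels(ph$truth$cell_labels, file.path(out, "sheet_labels.tif"))
write_table(ph$truth$cell_table, file.path(out, "sheet_cells.csv"), p)
write_table(ph$truth$border_classes, file.path(out, "sheet_borders.csv"), p)
yaml::write_yaml(list(preset = "sheet", seed = seed,
                      params = unclass(p)[sapply(unclass(p), is.numeric)]),
                 file.path(out, "sheet_manifest.yaml"))
cat("sheet phantom:", nrow(ph$truth$cell_table), "cells,",
    nrow(ph$truth$border_classes), "borders; programmed ML:RC ratio",
    p$border_anisotropy_a, "\n")

d <- generate_division_image(c(0, 20, 45, 70, 90), seed = seed)
invisible(tiff::writeTIFF(d$image / max(d$image), file.path(out, "divisions.tif"),
                bits.per.sample = 16L))
write_table(d$truth, file.path(out, "division_truth.csv"))
cat("division phantom: ", nrow(d$truth), "daughter-nucleus pairs\n")

cs <- generate_cross_section(-15, seed = seed)
invisible(tiff::writeTIFF(cs$image / max(cs$image), file.path(out, "section.tif"),
                bits.per.sample = 16L))
cat("cross-section phantom: programmed elevation",
    cs$truth$programmed_elevation_um, "um (everted)\n")

ab <- generate_ablation_pair(100, 40, seed = seed)
invisible(tiff::writeTIFF(ab$pre / max(ab$pre), file.path(out, "ablation_pre.tif"),
                bits.per.sample = 16L))
invisible(tiff::writeTIFF(ab$post / max(ab$post), file.path(out, "ablation_post.tif"),
                bits.per.sample = 16L))
cat("ablation phantom: programmed widening",
    ab$truth$programmed_widening_um, "um\n")
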