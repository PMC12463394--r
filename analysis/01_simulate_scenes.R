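#!/usr/bin/env Rscript
# Builds the synthetic study set used by the downstream analyses: a panel of
# synapse scenes spanning the physiological cleft range (27-37 nm), one
# bimodal (two-plateau) cleft, and a rendered tomogram of the central
# 33 nm synapse. Membrane point tables and ground-truth tables are written
# under results/scenes/ as plain text; the volume as MRC.

suppressPackageStartupMessages(library(synquant))
out <- "results/scenes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seps <- seq(27, 37, length.out = 8)
for (i in seq_along(seps)) {
  sc <- make_synapse_scene("plane", separation = seps[i], extent = 500,
                           spacing = 9, n_clusters = 2,
                           cluster_sigma = 15, guard_distance = 200,
                           surface_noise = 1, seed = 100 + i)
  write_points(sc$presm, file.path(out, sprintf("syn%02d_presm.csv", i)))
  write_points(sc$posm, file.path(out, sprintf("syn%02d_posm.csv", i)))
  write_points(sc$receptors,
               file.path(out, sprintf("syn%02d_receptors.csv", i)))
  utils::write.csv(sc$receptor_truth,
                   file.path(out, sprintf("syn%02d_truth.csv", i)),
                   row.names = FALSE)
}
cat(sprintf("wrote %d synapse scenes (separations %.0f-%.0f nm)\n",
            length(seps), min(seps), max(seps)))

bim <- make_synapse_scene("plane", separation = c(25, 40), extent = 600,
                          spacing = 10, n_clusters = 0, seed = 2)
write_points(bim$presm, file.path(out, "bimodal_presm.csv"))
write_points(bim$posm, file.path(out, "bimodal_posm.csv"))
cat("wrote bimodal two-plateau scene (25/40 nm)\n")

sc33 <- make_synapse_scene("plane", separation = 33, extent = 300,
                           spacing = 10, n_clusters = 0, seed = 1)
vol <- render_tomogram(sc33, render_params(noise_sigma = 0.1),
                       extent = list(x = c(-420, 80), y = c(-40, 40),
                                     z = c(-21, 21)), seed = 1)
write_volume(vol, file.path(out, "synapse33.mrc"))
cat(sprintf("rendered %s voxel tomogram at %.3f nm/voxel\n",
            paste(dim(vol$grid), collapse = "x"), vol$voxel_size))
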