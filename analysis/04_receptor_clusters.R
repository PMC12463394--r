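#!/usr/bin/env Rscript
# Geodesic DBSCAN clustering of receptors on the scene panel: meshes each
# PoSM, projects receptors, clusters on Dijkstra distances (eps 70 nm,
# min size 4), classes clusters against the cleft zone, and compares the
# labels with the generator's ground truth. Expects results/scenes/ from 01.

suppressPackageStartupMessages(library(synquant))
dir.create("results", showWarnings = FALSE)

files <- list.files("results/scenes", pattern = "^syn.._presm.csv$")
ids <- sub("_presm.csv", "", files)
rows <- list()
reports <- list()
for (id in ids) {
  pre <- read_points(file.path("results/scenes", paste0(id, "_presm.csv")))
  pos <- read_points(file.path("results/scenes", paste0(id, "_posm.csv")))
  rec <- read_points(file.path("results/scenes", paste0(id, "_receptors.csv")))
  truth <- utils::read.csv(file.path("results/scenes",
                                     paste0(id, "_truth.csv")))
  zone <- cleft_zone(pos, cleft_distances(pre, pos))
  rp <- analyse_receptor_clusters(pos, rec, in_cleft = zone,
                                  target_faces = 4000)
  reports[[id]] <- rp
  same <- outer(rp$labels, rp$labels, "==")
  tru <- outer(truth$cluster, truth$cluster, "==")
  ut <- upper.tri(same)
  rows[[id]] <- data.frame(
    synapse = id, n_receptors = length(rp$labels),
    n_clusters = rp$n_clusters,
    n_clusters_truth = length(unique(truth$cluster)),
    rand_index = mean(same[ut] == tru[ut]),
    n_cleft = unname(rp$class_counts["cleft"]),
    n_boundary = unname(rp$class_counts["boundary"]),
    n_perisynaptic = unname(rp$class_counts["perisynaptic"]))
}
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/clusters_per_synapse.csv", row.names = FALSE)
agg <- aggregate_synapses(ids, clusters = reports)
cat(sprintf("clusters found in %.0f%% of synapses; %.1f clusters/synapse,\n",
            100 * agg$fraction_with_any_cluster,
            agg$mean_clusters_per_synapse))
cat(sprintf("%.1f receptors/cluster (max %d); mean Rand index vs truth %.3f\n",
            agg$mean_receptors_per_cluster, agg$max_receptors_per_cluster,
            mean(tab$rand_index)))
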