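#!/usr/bin/env Rscript
# Dataset-level summary in the per-mouse reporting style: prevalence with
# SEM over a constructed annotation table, plus the aggregate of the
# per-synapse results written by 02-04.

suppressPackageStartupMessages(library(synquant))
dir.create("results", showWarnings = FALSE)

# annotation table of 5 mice x 18 tomograms with F-actin flags drawn at a
# known per-mouse prevalence (emulating the source-data spreadsheet layout)
set.seed(23)
mice <- sprintf("mouse%d", 1:5)
p_true <- c(0.40, 0.45, 0.50, 0.55, 0.55)
ann <- do.call(rbind, lapply(seq_along(mice), function(m) {
  data.frame(tomogram_id = sprintf("%s_t%02d", mice[m], 1:18),
             mouse_id = mice[m], compartment = "PreSM",
             f_actin = runif(18) < p_true[m])
}))
utils::write.csv(ann, "results/annotations.csv", row.names = FALSE)
pr <- prevalence(ann, "f_actin", "PreSM")
cat(sprintf("PreSM F-actin prevalence: %.0f +/- %.0f%% (mean +/- SEM, n = %d mice)\n",
            pr$mean, pr$sem, pr$n_mice))

cleft_tab <- utils::read.csv("results/cleft_per_synapse.csv")
clus_tab <- utils::read.csv("results/clusters_per_synapse.csv")
crowd <- utils::read.csv("results/crowding_result.csv")
summary <- list(
  n_synapses = nrow(cleft_tab),
  cleft_mean_of_means_nm = mean(cleft_tab$mean_height_nm),
  cleft_range_nm = range(cleft_tab$mean_height_nm),
  fraction_in_10_45 = sum(cleft_tab$fraction_in_10_45 * cleft_tab$n) /
    sum(cleft_tab$n),
  clusters_per_synapse = mean(clus_tab$n_clusters),
  fraction_with_clusters = mean(clus_tab$n_clusters > 0),
  crowding_class_example = crowd$crowding_class,
  f_actin_prevalence_mean = pr$mean,
  f_actin_prevalence_sem = pr$sem
)
jsonlite::write_json(summary, "results/summary.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)
cat("wrote results/summary.json\n")
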