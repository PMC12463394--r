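# synquant

Quantitative analysis of glutamatergic synapse architecture in
cryoCLEM-targeted cryo-electron tomograms.

Fresh-tissue cryoET shows synapses without the fixation and staining
artefacts of conventional EM, but turning those maps into numbers needs
careful quantification: is the cytoplasm next to the postsynaptic membrane
(PoSM) really more crowded than the bulk (the classical "postsynaptic
density")? How tall is the synaptic cleft, and is it uniform? Do ionotropic
glutamate receptors cluster on the membrane, and where do the clusters sit
relative to the cleft? `synquant` implements these analyses for R, together
with the cryoCLEM registration used to find the synapses in the first
place, and a synthetic scene generator that provides ground truth for
validating every stage.

## The analyses

**Molecular crowding.** Voxel-intensity line profiles (36 nm wide, 450 nm
long) are taken from single tomographic slices, each aligned to its own
plasma-membrane intensity peak before averaging (projecting tilted slices
would smear membrane density into the cytoplasm; slices tilted in-plane are
excluded). Crowding is classified per synapse by a two-tailed Welch
*t*-test comparing pooled voxel intensities in the membrane-proximal window
(5–30 nm) against the distal window (50–200 nm), Bonferroni-corrected
across the synapse panel: `higher`, `lower`, or `not_different`.

**Cleft height.** The cleft is mapped by bidirectional nearest-neighbour
search between the segmented PreSM and PoSM point clouds; pooled distances
give the per-synapse height distribution, summarised by mean, range, the
fraction within 10–45 nm, and a Gaussian KDE whose modes flag bimodal
clefts. Distances beyond 60 nm are flagged out-of-cleft, and the same
cutoff delineates the cleft zone used to localise receptor clusters.

**Receptor clusters.** The PoSM is reconstructed as a triangle mesh,
receptors are projected to their nearest vertex, pairwise distances are
computed with Dijkstra's algorithm on the edge-weighted mesh graph
(distances along the membrane, not through space), and DBSCAN
(eps = 70 nm, minimum size 4) on that geodesic metric yields clusters,
each classed `cleft`, `boundary`, or `perisynaptic` by where its members
sit relative to the cleft zone.

**CryoCLEM.** Fluorescence-to-EM registration is fitted from hole-centre
fiducials (similarity model by default, least-squares, warning below 10
fiducials); Psd95-GFP puncta are segmented by watershed on the smoothed
image and quantified by integrated intensity over the original pixels.

**Reporting.** Per-mouse prevalence with SEM across mice, Pearson
correlations with two-sided *p*-values, and aggregation of per-synapse
results into one dataset summary.

## Worked example

```r
library(synquant)

# a synthetic synapse: parallel membranes 33 nm apart, two receptor
# clusters of 10 on the PoSM
sc <- make_synapse_scene("plane", separation = 33, extent = 900,
                         spacing = 20, guard_distance = 250, seed = 7)

cm <- cleft_distances(sc$presm, sc$posm)
cleft_summary(cm)
#> <cleft_summary> n=4232, mean 33.00 nm (range 33.00-33.00), 100.0% in 10-45 nm, 1 mode(s)

rep <- analyse_receptor_clusters(sc$posm, sc$receptors,
                                 in_cleft = cleft_zone(sc$posm, cm))
rep$clusters
#>   label size location_class
#> 1     1   10          cleft
#> 2     2   10          cleft
```

The cleft summary reports the pooled bidirectional nearest-neighbour
distances: for noiseless parallel planes every measurement equals the true
33 nm separation and the whole distribution falls in the physiological
10–45 nm band. The cluster report recovers the two generated nanodomains
with all 20 receptors in-cleft.

The `analysis/` directory holds the full workflow as numbered scripts
(`01_simulate_scenes.R` … `06_summarise.R`); each writes its tables under
`results/` and prints what it found. `vignettes/` documents the models,
parameters and their defaults, and the design choices.

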