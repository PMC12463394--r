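Package: synquant
Title: Quantitative Analysis of Synaptic Architecture in Cryo-Electron
    Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying glutamatergic synapse architecture in
    cryoCLEM-targeted cryo-electron tomograms: membrane-aligned molecular
    crowding profiles with a proximal-versus-distal statistical
    classification, bidirectional nearest-neighbour mapping of synaptic
    cleft height, surface reconstruction of segmented membranes with
    geodesic (Dijkstra-on-mesh) DBSCAN clustering of ionotropic glutamate
    receptors and cleft/boundary/perisynaptic classification of clusters,
    fiducial-based registration of cryo-fluorescence to cryo-EM images
    with watershed puncta quantification, and dataset-level prevalence and
    correlation summaries. A synthetic synapse-scene generator provides
    ground-truth membranes, receptor point patterns and rendered noisy
    volumes so that every stage of the pipeline can be exercised and
    validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
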