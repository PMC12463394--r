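---
title: "Methods: quantifying synaptic architecture in cryo-electron tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying synaptic architecture in cryo-electron tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synquant)
```

# Scope and conventions

`synquant` quantifies the molecular architecture of glutamatergic synapses
in cryoCLEM-targeted cryo-electron tomograms through four analyses:
membrane-aligned molecular-crowding profiles, bidirectional
nearest-neighbour cleft-height mapping, geodesic DBSCAN clustering of
ionotropic glutamate receptors on reconstructed membrane meshes, and
fiducial-based registration of cryo-fluorescence to cryo-EM images with
watershed puncta quantification. A synthetic scene generator supplies
ground truth for every stage, so the statistical behaviour of each analysis
can be measured rather than assumed.

Conventions fixed package-wide: the internal length unit is the nanometre
(Angstrom appears only inside MRC headers, where pixel size =
`10 * voxel_size`); voxel indices are 0-based with coordinates at voxel
centres; the in-memory grid is indexed `[x, y, z]`; and analyses operate on
density-positive volumes (membrane = intensity maximum), with an `invert`
flag at load time for maps in which protein is dark. Because segmentation
coordinates may refer to different binning levels of the same map, the
point-table loader always requires an explicit unit declaration and, for
voxel units, an explicit voxel size; the conversion is applied exactly
once.

# Molecular-crowding profiles

Cytoplasmic crowding next to the postsynaptic membrane (PoSM) is measured
from voxel-intensity line profiles, 36 nm wide and 450 nm long by default,
taken from *single* tomographic slices. Projecting slices before profiling
would smear membrane density into the cytoplasmic signal whenever the
membrane is slightly tilted, so each slice's profile is instead aligned to
its own plasma-membrane intensity peak (the maximum within a +/-15 nm
window around the user anchor) before averaging. Slices whose unaligned
peak deviates from the batch median by more than a tolerance (default 6 nm,
about five voxels at the 1.194 nm working voxel size) are excluded as
tilted. Profile width is averaged over `round(width / voxel_size)`
trilinearly interpolated lanes — 30 lanes at 1.194 nm — a rounding rule
fixed for reproducibility.

Crowding is classified by pooling the aligned per-slice voxel intensities
in a membrane-proximal window (5–30 nm from the peak) and a distal window
(50–200 nm), then comparing them with a two-tailed Welch *t*-test at the
Bonferroni-corrected level `alpha / m`, where `m` is the number of synapses
in the analysed panel. Welch's unequal-variance form is used because the
two windows differ roughly eight-fold in voxel count (around 650 versus
3900 at 31 slices), which makes a pooled-variance test unsafe. The
classification is `higher`, `lower`, or `not_different` according to the
sign of the mean difference and the corrected significance. The *t*
statistic is invariant to affine intensity rescaling, so the result does
not depend on the arbitrary intensity units of a reconstruction.

Calibration on synthetic flat-cytoplasm profile batches (31 slices, noise
sd 0.1, `m = 30`, 200 replicates) gives a family-wise false-classification
rate below 1%, and a +20% proximal density bump at the same geometry is
detected as `higher` in every one of 100 replicates. One subtlety the
synthetic batches exposed: the membrane ridge has Gaussian tails, and a
proximal window opening too close to the peak inherits membrane density.
With the default bilayer model (two 2 nm-wide leaflet ridges 5 nm apart)
the 5 nm window start keeps this bleed an order of magnitude below the
noise floor.

# Cleft-height mapping

The synaptic cleft is defined computationally from the two segmented
membrane point clouds: for every presynaptic-membrane (PreSM) point the
Euclidean nearest PoSM point, and vice versa. The search is exact
(exhaustive, block-wise to bound memory; ties break to the lowest index).
Pooled bidirectional distances form the cleft-height sample of a synapse:
pooling both directions keeps the measure symmetric under exchange of the
membranes. Records beyond a cutoff (default 60 nm, the largest
across-cleft distance observed in the source data) are flagged out-of-cleft
but never dropped, and the same cutoff delineates the cleft zone on the
PoSM — a definition is needed to class receptor clusters, and promoting the
observed upper bound to the zone rule is the least arbitrary choice; it is
configurable. Summaries report the mean (both per-synapse mean-of-means and
pooled, since either convention may be wanted), min/max, the fraction of
measurements in the descriptive 10–45 nm band, and a Gaussian KDE with
Silverman's bandwidth by default; modes of the KDE flag multimodal clefts.

Point-to-point rather than point-to-surface distances are used, matching
the nearest-neighbour-coordinate definition; at segmentation-scale sampling
(sub-10 nm pitch) the sampling bias this introduces is a few tenths of a
nanometre (measured on concentric-shell fixtures: within 0.5 nm at 2000+
samples per side).

# Membrane meshing and geodesic receptor clustering

Receptor clustering uses distances *along the membrane*, not through
space, because membranes fold: two receptors on opposite faces of a fold
can be within 70 nm in Euclidean distance yet far apart on the surface.
The PoSM point cloud is reconstructed as a triangle mesh; receptors are
projected to their Euclidean-nearest mesh vertex (ties to the lowest
index); pairwise distances are shortest paths along the edge-weighted mesh
graph (Dijkstra); and DBSCAN runs on that precomputed metric with the
field parameters eps = 70 nm and minimum cluster size 4 (standard DBSCAN
semantics; the eps-neighbourhood includes the point itself).

The reconstruction backend is intentionally behaviour-specified rather
than implementation-specified. Sheet-like clouds are triangulated by a 2D
Bowyer–Watson Delaunay in their principal (PCA) plane and lifted back to
the original 3D points, so the mesh interpolates the samples exactly;
clouds lying on a sphere are triangulated by stereographic projection from
one sample and closed with a fan to the projection pole — the classical
construction of the convex-hull triangulation, which guarantees a closed
surface (Euler characteristic 2). Simplification to a face budget (default
10,000 faces, chosen so edge lengths stay well below eps) is deterministic
farthest-point subsampling followed by re-triangulation, which preserves
the surface topology by construction; quadric edge collapse was rejected
as much harder to make robust without changing any tested behaviour. A
deterministic sub-nanometre jitter inside the Delaunay kernel breaks the
cocircular ties of regular segmentation grids; returned triangles always
reference the original coordinates.

Edge-graph shortest paths are an estimator of true surface geodesics with
two opposing biases: chords cut corners (underestimate) while paths must
zigzag along available edges (overestimate, by a path-dependent "stretch"
of a few percent, up to roughly 40% in the worst direction on a square
grid). Both effects are scale-free, so refining the mesh does not drive
single-pair distances to convergence — the *mean* over well-separated
point pairs is stable under edge-length halving (within 5% on sphere
fixtures) while individual pairs can move by ~10%. This is acceptable for
DBSCAN at eps = 70 nm because cluster decisions sit far from the
threshold: on flat sheets, geodesic labels are identical to Euclidean
DBSCAN labels across seeded Thomas scenes, and on folded sheets the
geodesic metric is exactly what separates the groups a Euclidean metric
would merge.

Clusters are classed against the cleft zone transferred from PoSM points
to mesh vertices by nearest-point vote: `cleft` when every member projects
to an in-cleft vertex, `perisynaptic` when none does, `boundary`
otherwise. The member-based rule (rather than a hull-based one) is the
simplest deterministic reading of a mixed cluster.

# CryoCLEM registration and puncta

Fluorescence-to-EM registration is fitted from paired hole-centre
fiducials. The default model is a similarity transform (scale + rotation +
translation, solved in closed form by orthogonal Procrustes with scale),
because the mapping between a flat grid square imaged in both modalities
is dominantly a scaled rotation; a full affine is available by flag, and a
warning is raised below 10 fiducials. Noiseless correspondences are
recovered to below 1e-9 px, and with iid Gaussian noise of sd sigma the
rms residual stays within 2 sigma in at least 95% of seeded trials.

Puncta are segmented by watershed on the Gaussian-smoothed image. Basins
are computed over the whole smoothed image so each punctum keeps its
tails; a basin counts as a punctum when its peak clears the Otsu threshold
and its above-threshold core reaches the minimum area. Integrated
intensities are summed over the *original* (unsmoothed) pixels of the
basin, and puncta plus background partition the image exactly, so total
intensity is conserved. Channel bleed-through handling is reduced to an
optional mask input, as it is acquisition-specific.

# Dataset-level reporting

Prevalence statistics are computed per mouse (the biological replicate):
per-mouse percentage of tomograms showing a feature in a compartment, with
the mean and SEM (sample sd / sqrt(n_mice)) across mice. Pearson
correlations are computed in closed form with the two-sided *p* from the
*t*-distribution on n − 2 degrees of freedom, alongside the least-squares
line. Percentages are kept at full precision internally and rounded only
for display.

# The synthetic generator

The generator emulates what the analyses assume about real data: paired
PreSM/PoSM surfaces (plane, gently undulating sheet, or concentric
spheres) at controllable separation, by default 33 nm — the centre of the
27–37 nm per-synapse range the analyses target; receptor patterns drawn
from a Thomas process (Gaussian dispersion, default sd 20 nm, around
uniformly placed centres with a configurable guard distance), the minimal
generative model for nanodomain-like clusters, with 10 receptors per
cluster by default to match the reported average cluster size; bimodal
clefts as a lateral two-plateau separation step; membranes rendered as
double-Gaussian bilayer ridges (leaflets 5 nm apart, 2 nm wide) with a
configurable cytoplasmic crowding profile, receptor ectodomain blobs
extending 14 nm into the cleft, additive Gaussian noise and an optional
anisotropic blur; and a default lateral extent of 1.3 um, the field of
view of the targeted acquisitions. Default membrane sampling pitch is
15 nm, which yields segmentation-scale point counts (thousands per
membrane). Every generator is a pure function of its seed.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data — includes the contrast transfer function and
missing wedge (beyond a coarse anisotropic blur), organelles and vesicles,
molecular shapes beyond Gaussian blobs, segmentation artefacts, and any
deviation of real receptor patterns from a Thomas process. The statistical
calibrations (type-I rate, power, recovery rates) are therefore statements
about the estimators under the stated noise models, not about biology.

# Numerical choices and problem sizes

Degenerate inputs are rejected with typed errors: collinear clouds cannot
be meshed, coincident or collinear fiducials cannot constrain a fit,
empty membranes cannot be mapped, and windows with fewer than two voxels
cannot be tested. KDE densities integrate to 1 within 1e-3 over their
grid. Distance-matrix symmetry is enforced to 1e-9 before clustering.

The shipped analyses and validation suites use deliberately desk-scale
problem sizes: membranes of a few hundred nanometres at 5–20 nm pitch
(thousands of points), meshes of 1000–10,000 faces, panels of 8–10
synapses, and 100–200 seeded replicates for the statistical calibrations.
All headline behaviours (exact parallel-plane recovery, shell separation
within 0.5 nm, cluster recovery in at least 95% of seeds with Rand index
above 0.95, type-I rate at or below 5%, power at or above 99%) are
measured at these sizes by `tests/testthat/test-acceptance.R` and
recomputed from scratch by `scripts/acceptance.R`.

# Known limitations

Membrane segmentation refinement is upstream and out of scope: the
pipeline consumes point clouds as given, and any bias a segmentation
method introduces propagates into cleft distances. Point-to-point cleft
distances carry a small positive sampling bias that shrinks with sampling
density. Edge-graph geodesics carry the stretch discussed above. The
surface reconstruction covers sheet-like and spherical topologies — the
membrane families the analyses meet — not arbitrary genus. Volume
rendering supports sheet geometries only.
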