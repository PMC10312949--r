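---
title: "Potential-connectivity cell typing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potential-connectivity cell typing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arborcode)
library(tibble)
```

## The problem

Single-neuron reconstructions registered to a common brain coordinate space
can be grouped by where their cell bodies sit (s-types), by their
morphometry (m-types), or — the idea this package implements — by where
their axons *could* make contact: a neuron's axonal arbor is intersected
with the dendritic territories of every other cell population in the brain,
and the resulting vector of overlap volumes (the **connectivity barcode**)
becomes the feature on which types and subtypes are defined (c-types).
"Potential" is the operative word: no synapses are detected; spatial
apposition of axonal and dendritic arbors at a fixed voxel resolution is
used as a stable proxy for the circuit scaffold.

The pipeline has six stages, each exposed as ordinary functions that take
and return data frames or small S3 objects:

1. **Morphology I/O and QC** — SWC reading/writing, resampling to a uniform
   inter-node distance, morphometric features, and an interval-based filter
   for automated dendritic tracings.
2. **Arbor domains** — per s-type, pooled neurite coordinates are clustered
   with Gaussian mixtures (BIC model selection) and each cluster is
   enclosed in a 3-D alpha-shape, classified dendritic or axonal, and
   voxelized.
3. **Barcodes** — per neuron, the axonal alpha-shape mask is intersected
   with the ordered whole-brain panel of dendritic domains.
4. **m/c-scores** — an exponential similarity between clusters that
   balances inter-center Manhattan distance against intra-cluster spread.
5. **Anatomy-aware soma distances** — a Mahalanobis form whose covariance
   is estimated from the voxel cloud of the soma region itself.
6. **Spatially tuned subtyping** — hierarchical clustering of the Hadamard
   product of cosine barcode similarity and a Gaussian soma-distance
   affinity, with the cluster count selected by the Calinski–Harabasz
   index.

A synthetic mirrored-hemisphere atlas and a neuron growth model make every
stage testable without any proprietary data.

## Models and formulas

### Resampling and morphometry

Reconstructions are resampled so no parent–child edge exceeds 10 µm
(default), inserting interpolated nodes on the original segments; branch
points, tips and the root are preserved exactly, and total cable length is
conserved. The feature panel is L-Measure-flavoured: tips, total length,
maximum path distance, bifurcation count, maximum branch order (root order
0; +1 per bifurcation on the root path — the soma never counts as a
bifurcation regardless of its stem count), remote bifurcation angle
(measured at each bifurcation toward the next bifurcation-or-tip of each
child branch), maximum Euclidean distance to the soma, and bounding-box
extents. The exact m-feature panel used upstream of the scores is recorded
in output metadata because no canonical panel exists; it is a deliberately
conventional stand-in.

### QC of automated dendritic tracings

Five features carry closed "realistic" intervals: tips [7, 143], length
[700, 13615] µm, max path distance [108, 1382] µm, average remote
bifurcation angle [35, 129]°, max branch order [3, 32]. A candidate tracing
is **kept iff at least 4 of the 5 features fall within their intervals**
(the threshold is configurable), and among passing candidates for one soma
the greatest-length tracing wins. The keep-direction of the rule is the
only reading under which the intervals describe realistic arbors.

### Arbor domains

Node coordinates of one s-type are pooled in voxel units (µm divided by the
voxel size) and fitted with Gaussian mixtures over a grid of component
counts (default 1–9, configurable) and covariance families (the `mclust`
default set: spherical, diagonal, ellipsoidal, with equal or varying
volume/shape/orientation). The fit maximizing `BIC = 2 ln L − p ln n` wins.
Each cluster is enclosed in the **alpha-shape**: the union of Delaunay
tetrahedra with circumradius ≤ α. As α → ∞ this is the convex hull. The
tetrahedralization is an incremental Bowyer–Watson implementation in C++
(no 3-D Delaunay library exists in the package's dependency footprint);
degeneracies are broken by a fixed, tiny internal jitter used only for the
triangulation topology, while membership tests and rasterization use the
original coordinates.

A domain is **dendritic** iff strictly more than 50 % of its member nodes
belong to neurons whose soma lies inside the domain's alpha-shape; ties go
to axonal. Pooled per-s-type dendritic domains skip the mixture step: all
dendritic nodes of one hemisphere form a single shape, and a hemisphere
with no neurons receives the mirrored copy of the other side, so homologous
contralateral territories always exist.

One deliberate departure from a naive reading of the domain decomposition:
BIC on pooled arbor clouds routinely selects the top of the k-range,
because stacked random arbors are not Gaussian — one projection system (an
axon corridor plus its terminal arbor) is then represented by several
components. Questions of the form "how many distinct places does this
s-type project to" are therefore answered at the scale of **axonal
territories** (`axonal_territories()`): connected unions of axonal domains
whose voxel masks overlap or abut within one voxel. The planted-target
recovery test operates on territories, not raw component counts.

### Barcodes

The whole-brain panel concatenates, per hemisphere, the pooled
dendrite-cohort domains and the s-type dendritic domains; its length is
`2 × (n_den + n_stype)` — with the study-scale panel of 19 + 56 domains per
hemisphere, 150. Per neuron, the **axonal** compartment (default;
whole-neuron masks behind a flag) is enclosed in its own alpha-shape and
voxelized; the mask additionally contains the voxel of every compartment
node, because locally 1-D stretches of an axon contribute no tetrahedra to
a circumradius-filtered complex yet clearly occupy their voxels. Barcode
entry *d* is the voxel count of the intersection with panel domain *d*
(raw counts by default; mm³ by flag). Neurons are never flipped — the panel
carries both hemispheres.

### m/c-score

For two clusters of feature vectors,

score = exp( −2 · D_inter / (½ · (D_intra,1 + D_intra,2)) ),

with `D_inter` the Manhattan distance between per-feature means and
`D_intra` the average over samples of the mean Manhattan distance to the
other samples of the same cluster (0 for singletons; if both intra terms
vanish the score is 1 for coincident centers and 0 otherwise). The score is
a **similarity** (identical clusters score 1) — this follows the formula,
which contradicts the prose describing it in the source material. Features
are z-scored over the pooled comparison set before distances, since the
panel spans four orders of magnitude in units; group-level matrices use
global standardization (recorded in metadata). The elementwise ratio of
c-scores to m-scores is the headline comparison: entries below 1 mean
connectivity separates a group pair more sharply than morphology.

### Anatomy-based soma distance

Somas of one s-type are mirrored to a canonical hemisphere, then

DistS(s₁, s₂) = (s₁ − s₂)ᵀ Cov⁻¹ (s₁ − s₂),

with Cov the covariance of the region's ipsilateral voxel-center
coordinates (µm). The form is squared, as printed in the source formula — a
square-rooted variant sits behind a flag. A singular covariance receives a
ridge of 10⁻⁶ × mean diagonal, with a message.

### Spatially tuned subtyping

`MC` (cosine similarity of barcode rows; all-zero rows are excluded with a
message) and `MD` (the soma distance map) are min–max normalized to [0, 1]
**over off-diagonal entries only**, so the self-similarity diagonal cannot
compress the range. The Gaussian distance affinity is `MDA = exp(−MD ∘ MD)`
— exactly 1 at distance 0 and e⁻¹ at the maximal normalized distance — and
the combined affinity is the **Hadamard product** `A = MC ∘ MDA` (a matrix
product would break pairwise semantics), diagonal forced to `max(A)`. Ward
linkage (average available by flag) on `D = 1 − A`, cut at each candidate
k (default 2…min(10, n−1)), scored by Calinski–Harabasz with the rows of
`A` as feature vectors; the arg-max k wins. Soma mirroring matters here:
on a cohort duplicated across hemispheres, raw somas make the hemisphere
split the top bipartition, and mirroring removes it — this behaviour is
exercised in the test suite.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `resample step` | 10 | µm | max inter-node distance before pooling/features |
| `voxel_size` | 25 | µm | atlas grid resolution |
| `alpha` | 0.4 | voxel units | alpha-shape detail; synthetic tests use 3 (≥ 2× node spacing) to avoid fragmentation of sparse toy clouds |
| `k_range` | 1–9 | — | GMM component grid |
| QC `min_features_within` | 4 | of 5 | keep threshold |
| SVM `cost` | 1000 | — | linear soft-margin classifier; overlap % is resubstitution error |
| `n_components` | 3 | — | connectivity PCs appended to m-features |
| subtype `k_range` | 2…min(10, n−1) | — | CH-scored cuts |

## The synthetic generator

`build_toy_atlas()` paints box/ellipsoid region primitives onto an integer
grid with a declared mirror axis; every region has a mirrored twin with the
same name on the opposite hemisphere. `grow_neuron()` is a directed random
walk: dendrites are radial branches with per-step Gaussian angular noise
whose lengths are drawn so the node cloud's RMS distance to the soma
matches `dendrite_spread_um`; each axon target gets a low-tortuosity path
from the soma to the target-region center followed by a random terminal
arbor of spread `axon_arbor_spread_um`. `generate_cohort()` places somas on
distinct voxel centers of the s-type region (optionally inside a
`soma_window`, which is how spatially segregated planted subtypes are
made), writes standard SWC, and emits a ground-truth manifest.

What this emulates: mirrored hemispheres, region-confined somas, local
dendrites, long-range axons with 1–3 planted targets, subtypes defined by
target combinations, and determinism under a seed. What it does not:
cortical layering, biophysical growth, tortuous fiber tracts, registration
error, tracing noise. Passing tests therefore demonstrate that the
machinery recovers structure that is genuinely present at toy scale — not
that real reconstructions are this clean.

Study-condition choices fixed once in the planted designs: dendrite spread
60 µm, axon arbor spread 25 µm against target separations of 300 µm (12×
spread), node caps of 150–250 per subtree, bifurcation probability 0.06,
and a 50 µm gap between the soma windows of segregated planted subtypes so
the "spatially segregated" premise actually holds at the cohort sizes used.

## Numerical choices and degenerate inputs

* Voxelization uses the voxel-center test (center inside the shape), which
  is reproducible and oracle-checkable; voxels are half-open with 0-based
  indices, `floor((coord − origin)/voxel_size)`.
* The Delaunay jitter is 10⁻⁷ of the cloud diagonal, generated from a fixed
  internal stream — runs are bit-reproducible and the jitter never touches
  reported coordinates.
* Fewer than 5 points, or a rank-deficient cloud, falls back to a union of
  balls around the points (radius = α by default), logged.
* A GMM that fails on degenerate clouds is retried with a conjugate prior
  (regularized covariances), logged.
* Edge→region attribution in projection matrices uses the child node's
  voxel; the error is bounded by the resampling step.
* Ties: exactly 50 % in-soma nodes → axonal; equal QC lengths → first of
  the maxima; `hclust` inherits its own deterministic tie-breaking.

## Problem sizes

The test suite and the acceptance script run on a 40 × 24 × 24 voxel atlas
(25 µm voxels) with cohorts of 12–36 neurons of ≤ ~600 nodes each, mixture
fits on ≤ 6000 pooled nodes, and 10-seed repetitions for the model-selection
checks; these sizes were chosen so the planted effects are comfortably
detectable while a full run stays in the minutes range on one CPU.

## Known limitations

* Overlap is voxel-count apposition; no distance decay, directionality or
  synapse model.
* The m-feature panel is a stand-in; conclusions about m- vs c-features at
  toy scale depend on the generator sharing morphology across planted
  groups by construction.
* Alpha is a single global knob; strongly non-uniform node densities would
  need per-domain alphas.
* The incremental Delaunay implementation targets point clouds up to a few
  thousand points after deduplication/subsampling — adequate here, not a
  general-purpose CGAL replacement.
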