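---
title: "Methods: the intrinsic geometry of a weighted connectome"
author: "intrinsicConnectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the intrinsic geometry of a weighted connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intrinsicConnectome)
```

## The model

A structural connectome is a weighted, symmetric graph: nodes are gray-matter
regions, edge weights are nonnegative coupling strengths (for
tractography-derived data, streamline fiber counts). The package studies the
network's *intrinsic geometry*: the low-dimensional shape implied by its
coupling pattern, independent of where the regions sit anatomically.

The construction has three steps.

1. **Graph distances.** Each edge is assigned a length equal to the inverse
   of its weight, so strongly coupled regions are close. All-pairs shortest
   paths (Dijkstra, via igraph) give the graph-distance matrix; a zero weight
   means *no edge*, not an infinitely strong one, because an absent
   reconstructed tract carries no traffic.
2. **High-dimensional representation.** Node *i* is placed at the coordinates
   given by row *i* of the graph-distance matrix — its profile of distances
   to every node. Two nodes are near each other in this space exactly when
   they hold similar coupling relations with the rest of the network.
3. **Embedding.** The representation is reduced to a few dimensions either by
   classical (Torgerson) MDS on the Euclidean distances between rows, or by
   Isomap: a union-symmetrized k-nearest-neighbour graph over the rows,
   geodesic distances along that graph, then classical MDS of the geodesics.

Classical MDS was chosen over iterative stress-majorization variants
deliberately: Isomap's own final step *is* classical MDS, so the linear and
nonlinear embeddings differ in exactly one ingredient — chordal versus
geodesic distances — which keeps the comparison between them interpretable.

### Validation statistic

A node's *nodal path length* is its mean graph distance to all other nodes
(the structural zero to itself is excluded; including it would only rescale
every value by $(n-1)/n$ and change no ordering or correlation). Efficiently
communicating nodes should sit centrally in a faithful embedding, so the
package regresses each node's Euclidean distance to the embedding centroid on
its nodal path length and reports the squared Pearson correlation
$r^2$ (identical to the OLS $R^2$ of that regression), the fitted line, and
the residual RMSE. The same regression applied to anatomic centroid
coordinates provides the baseline the embeddings are meant to beat.

### Cohesion under lesioning

The lesion statistic $\bar d$ is the mean Euclidean distance of embedded
nodes to the embedding centre. After removing a node set, the survivor
network's graph distances and Isomap embedding are recomputed *from scratch*
— each lesion is a new topology, not a projection of the old one — and
$\bar d$ is evaluated there. A normalized variant multiplies $\bar d$ by the
surviving network's mean coupling weight; the mean is taken over **all**
off-diagonal pairs, zeros included, because the multiplier is meant to track
how much total coupling the removal destroyed (a connected-pairs-only mean is
available behind a flag). Using the *surviving* network's mean rather than a
pre-removal constant lets the normalized panel reorder schemes, which is the
point of reporting it.

Targeted schemes rank nodes by nodal strength (descending), Onnela weighted
clustering (ascending), nodal path length (ascending), betweenness on edge
lengths (descending), an embeddedness score (descending), or remove a flagged
set (rich club, subcortical). Random removal draws uniform subsets of the
same size; draws that disconnect the survivors are redrawn (at most 100 per
trial) because $\bar d$ is undefined on a disconnected embedding — the redraw
count is reported so users can judge the conditioning bias. Removal counts
use round-half-away-from-zero so results do not depend on the platform's
banker's rounding.

### The embeddedness proxy

The published description of embeddedness — "a ratio between nodal efficiency
and the rate of information transfer decay" — does not pin down the shell
definition, fit range or weighting. The package therefore implements a
documented proxy: nodal efficiency $E(i) = \mathrm{mean}_{j \ne i}\,
1/d_{ij}$ divided by the decay rate $\lambda(i)$, the negative least-squares
slope of $\log(\text{mean inverse distance to the } h\text{-hop shell})$
against $h$ on the binarized graph. Nodes whose shells do not decay get an
infinite score and a warning. Any externally computed per-node ranking can be
passed through instead; the proxy is an approximation, not a claim of
equivalence to the original metric.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `d` (embedding dim) | 3 | the visualization-ready dimension; the sweep tool quantifies what higher d adds |
| `kStart` | 3 | first neighbourhood size tried by the automatic Isomap; 1–2 produce degenerate chain graphs, and the iterative growth only ever increases it |
| kNN symmetrization | union | an edge survives if either endpoint lists the other; guarantees the minimal connecting k exists |
| kNN ties | lower index | equidistant neighbour candidates resolved deterministically |
| symmetry tolerance | 1e-9 | asymmetries below it are averaged away as I/O noise; larger ones are data errors |
| removal fraction | 0.215 | the rich-club share of the upsampled 620-region cortical network this statistic was designed around |
| `threshold` (parcellation) | 800 voxels | about 1 cm³ at 1.1 mm isotropic resolution; a region of exactly the threshold size is still split ("dropped below" semantics) |

Negative eigenvalues of the double-centred matrix (graph distances need not
be Euclidean-embeddable) are clamped to zero, with the clamped count
reported. Each embedding axis is sign-flipped so its largest-magnitude
coordinate is positive, making outputs identical across platforms and runs.

## Parcellation upsampling

Atlas regions are recursively bisected by a plane perpendicular to their
principal axis (the leading eigenvector of the voxel-coordinate covariance;
coordinates are voxel indices scaled by the physical voxel size so
anisotropic voxels do not bias the axis). "Bisected" is interpreted as a
*median* split — equal voxel counts, ties to one side — rather than a plane
through the spatial centroid: the median guarantees both halves are nonempty,
hence termination, and yields the balanced region sizes that an
eightfold-ish upsampling implies. A centroid-plane mode is available behind
the `at` argument for users who prefer geometric bisection. When several
subjects' volumes are supplied, the axis comes from the pooled,
centroid-aligned group region while each subject is split at its own median
projection. Non-contiguous regions are treated as one point set; regions that
cannot be split (identical coordinates, or all projections equal) are left
whole and flagged.

## What the synthetic generator emulates

No deposited connectome accompanies the analyses this package implements, so
`makeModularConnectome()` plants the structures the method is meant to
detect:

* a **rich-club core** — a dense clique of 21.5% of the nodes with the
  strongest weights;
* **modular arms** — four communities with ring-lattice backbones radiating
  from the core, attached in a *graded* way: the probability and weight of a
  node's direct core links decay exponentially with its position along the
  arm. Proximal arm nodes blend into the core while distal ones communicate
  through their arm, which produces the funnel/flower-shaped intrinsic
  geometry (arms radiating around a central core) that makes the nonlinear
  embedding informative. An abrupt single-gateway attachment was rejected
  during design: it isolates whole arms in the k-nearest-neighbour graph and
  forces the automatic neighbourhood k to jump, short-circuiting the
  geodesics;
* **heavy-tailed weights** — log-normal edge noise and per-node log-normal
  strength propensities, mimicking right-skewed fiber-count distributions;
* **weak long-range shortcuts** — sparse, low-weight links between arms
  (`wInter = 2` versus `wIntra = 20`), so the core is the dominant
  communication backbone and its removal genuinely reroutes traffic;
* **decoupled anatomy** — reported anatomic coordinates are Gaussian
  community clusters drawn independently of the topology (core nodes are
  scattered across clusters), so anatomic distance carries essentially no
  information about graph distance.

The generator does **not** reproduce a real connectome's degree sequence,
hemispheric symmetry, lobe anatomy or absolute fiber-count scale. Tests that
pass on it demonstrate that the pipeline detects planted geometry of this
kind, not that any particular empirical brain exhibits it.

The study-scale conditions used throughout the test-suite are n = 200 nodes
with a 43-node core, 500 Monte-Carlo removal trials at fraction 0.215, and
embedding dimensions 1–8 for the sweep; the Swiss-roll benchmark uses 1000
noiseless points on the standard $(t\cos t,\, h,\, t\sin t)$ surface with the
arc-length parametrization as ground truth.

## Degenerate inputs and numerical choices

* Disconnected inputs are a hard error everywhere (reader, distance engine,
  removal): the representation requires finite distances, and silently
  propagating infinities would poison every downstream statistic.
* Diagonal noise at or below 1e-12 is zeroed on read; anything larger is an
  error, since a self-loop has no meaning for fiber counts.
* `residualVariance()` errors on constant distance sets rather than returning
  `NaN`.
* The Isomap residual variance is conventionally measured against the
  geodesic distance matrix (`isomapGeodesics()`), the MDS one against the
  ambient distances; comparing both to the same matrix would penalize Isomap
  for the very transformation it is designed to apply.
* The pipeline derives per-stage seeds as `seed + stage counter`, so any
  stage can be re-run in isolation and reproduce its numbers exactly; the
  JSON report is byte-identical across runs with the same config.

## Known limitations

* The embeddedness score is a proxy (see above); rankings from the original
  metric's implementation can be substituted via `ranking`.
* Monte-Carlo removal conditions on survivor connectivity; at aggressive
  fractions on fragile networks the redrawn distribution is biased toward
  robust subsets, and the redraw count should be inspected.
* Classical MDS on strongly non-Euclidean distance matrices discards the
  negative spectrum; the clamped count is the diagnostic.
* The command-line front end (`inst/scripts/connectome-geometry.R`) is a thin
  wrapper; programmatic use through the exported functions is the primary
  interface.
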