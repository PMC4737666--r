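# intrinsicConnectome

Tools for constructing, quantifying and perturbing the **intrinsic
geometry** of a weighted structural brain connectome — the low-dimensional
shape implied by its coupling pattern, independent of where the regions sit
anatomically. The package is aimed at connectomics researchers who work with
region-by-region coupling matrices (tractography fiber counts or any
nonnegative coupling strength) and want to analyse, visualize or stress-test
their network in its "native" topological space rather than in anatomic
coordinates.

## The method

Given a symmetric nonnegative weight matrix `W` with no isolated nodes:

1. **Graph distances.** Edge lengths are `1/W[i,j]`; `GraphDistance[i,j]` is
   the shortest-path length between `i` and `j` (Dijkstra). Zero weight means
   no edge.
2. **High-dimensional representation.** Node `i` is the vector
   `d_i = (GraphDistance[i,1], ..., GraphDistance[i,n])`; nodes with similar
   coupling profiles are close in the Euclidean metric
   `||d_k - d_l|| = sqrt(sum_i (GraphDistance[k,i] - GraphDistance[l,i])^2)`.
3. **Embedding.** Classical (Torgerson) MDS of the distances between rows, or
   Isomap: geodesic distances over the union-symmetrized k-nearest-neighbour
   graph (k grown automatically from 3 until the graph connects), then
   classical MDS of the geodesics.
4. **Validation.** Regression of each node's distance to the embedding centre
   on its nodal path length (mean graph distance to all other nodes); a high
   r² means central placement tracks communication efficiency.
5. **Lesioning.** Targeted or random node removal scored by the cohesion
   statistic **d̄**, the mean distance of the re-embedded survivors to their
   embedding centre, optionally normalized by the surviving mean coupling
   weight.

Also included: the recursive atlas-upsampling algorithm (regions bisected by
planes perpendicular to their PCA main axes until they drop below a
voxel-count threshold), fully seeded synthetic generators (modular
connectomes with a planted rich club, Swiss rolls, label volumes), a JSON
embedding export for interactive viewers, and a one-command pipeline.

## Worked example

```r
library(intrinsicConnectome)

syn <- makeModularConnectome(n = 200, seed = 1)   # planted rich-club network
syn$connectome
#> WeightedConnectome: 200 nodes, 1675 edges (density 0.084)
#>   total weight: 72513.5; labels: N000, N001, N002, N003 ...

gd  <- graphDistances(syn$connectome)
npl <- nodalPathLength(gd)
emb <- isomapEmbed(highDimRepresentation(gd), 3)
emb
#> ConnectomeEmbedding: Isomap, 200 nodes in 3 dimensions (k = 5)
#>   eigenvalues: 343.6, 167.5, 142.2

centralityValidation(emb, npl, "Isomap")$rSquared        # 0.944
centralityValidation(classicalMDS(as.matrix(dist(gd)), 3), npl)$rSquared  # 0.120
centralityValidation(as.matrix(syn$nodes[, c("x","y","z")]), npl)$rSquared # 0.002
```

The nonlinear embedding recovers the planted centrality gradient almost
perfectly (r² = 0.94), the linear one only weakly (r² = 0.12), and anatomy —
which the generator decouples from topology on purpose — not at all
(r² = 0.002). The planted core sits centrally (mean centre-distance rank 22
versus 122 for the periphery), and removing it is far more damaging than the
removal of an equal number of random nodes:

```r
rc <- targetedRemoval(syn$connectome, "rich_club", nodes = syn$nodes)
rc
#> RemovalResult: scheme 'rich_club', removed 43 nodes (21.5%)
#>   d-bar raw: 2.6181, normalized: 3.4015

rnd <- randomRemovalDistribution(syn$connectome, 0.215, trials = 500, seed = 7)
rc@dbarRaw > rnd@interval[2]   # TRUE: beyond the random 95th percentile
```

A full workflow — embeddings, validation in three spaces, the lesion suite
and the dimension sweep, with a machine-readable JSON report — is one call:

```r
runFullPipeline(syn$connectome, syn$nodes, pipelineConfig(seed = 42),
                outDir = "results")
```

A thin command-line front end over the same functions ships in
`inst/scripts/connectome-geometry.R` (subcommands `embed`, `validate`,
`lesion`, `synth`, `subdivide`, `pipeline`).

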