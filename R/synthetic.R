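#' Synthetic modular connectome with a planted rich club
#'
#' Generates a weighted, symmetric, connected network emulating a
#' group-averaged structural connectome: a densely interconnected
#' high-weight core (the planted "rich club", by default 21.5\% of the
#' nodes, the rich-club share of the upsampled 620-node cortical network
#' around which the removal experiments are framed) and modular "arm"
#' communities radiating from it. Each arm carries a ring-lattice backbone
#' (neighbours within \code{ringHalf} positions always linked) plus sparse
#' within-arm shortcuts, and attaches to the core in a graded way: the
#' probability and median weight of direct core links decay exponentially
#' with a node's position along the arm (length scale \code{anchorScale}),
#' so proximal arm nodes blend into the core while distal nodes communicate
#' mainly through their arm. Weights are log-normal (right-skewed, like
#' streamline fiber counts) with per-node log-normal strength propensities
#' (\code{strengthSd}) giving heavy-tailed nodal strengths.
#'
#' Anatomic node coordinates are drawn from per-community Gaussian clusters
#' placed independently of the topology (core nodes are scattered across the
#' clusters), so anatomic distance is deliberately decoupled from graph
#' distance — the dissociation the intrinsic-geometry analysis is designed
#' to expose. If an edge draw leaves several components they are bridged by
#' minimal extra edges of weight \code{wInter}.
#'
#' @param n node count.
#' @param nCore planted core size (default \code{round(0.215 * n)}).
#' @param communities number of arm communities.
#' @param ringHalf arm-lattice half-width (positions within this distance on
#'   the arm are always connected).
#' @param pCore core-core connection probability.
#' @param pIntra within-arm shortcut probability beyond the lattice.
#' @param pInter between-arm connection probability.
#' @param pAnchor direct core-link probability at the arm head; decays as
#'   \code{exp(-(pos - 1) / anchorScale)} along the arm.
#' @param anchorScale positions over which core attachment decays.
#' @param wCore,wIntra,wInter median weights for core-core, arm, and
#'   between-arm edges; must satisfy \code{wCore > wIntra > wInter > 0}.
#' @param noiseSd log-scale standard deviation of the weight noise.
#' @param strengthSd log-scale spread of per-node strength propensities.
#' @param seed RNG seed; identical seeds give identical outputs.
#' @return list with \code{connectome} ([WeightedConnectome-class]) and
#'   \code{nodes} (data.frame: label, lobe = community, anatomic x/y/z in mm,
#'   rich_club flag).
#' @examples
#' syn <- makeModularConnectome(n = 60, seed = 1)
#' syn$connectome
#' @export
makeModularConnectome <- function(n = 200L, nCore = NULL, communities = 4L,
                                  ringHalf = 4L,
                                  pCore = 0.9, pIntra = 0.05, pInter = 0.01,
                                  pAnchor = 0.9, anchorScale = 8,
                                  wCore = 60, wIntra = 20, wInter = 2,
                                  noiseSd = 0.5, strengthSd = 0.25,
                                  seed = 1L) {
  if (is.null(nCore)) nCore <- roundHalfUp(0.215 * n)
  stopifnot(nCore >= 1, nCore < n, communities >= 1,
            all(c(pCore, pIntra, pInter, pAnchor) > 0),
            all(c(pCore, pIntra, pInter, pAnchor) <= 1))
  if (!(wCore > wIntra && wIntra > wInter && wInter > 0))
    stop("block weights must satisfy wCore > wIntra > wInter > 0")
  set.seed(seed)
  core <- c(rep(TRUE, nCore), rep(FALSE, n - nCore))
  comm <- integer(n)
  comm[!core] <- rep_len(seq_len(communities), n - nCore)
  pos <- integer(n)
  for (c in seq_len(communities))
    pos[comm == c] <- seq_len(sum(comm == c))
  s <- rlnorm(n, 0, strengthSd)
  w <- matrix(0, n, n)
  lnw <- function(m, med) rlnorm(m, log(med), noiseSd)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  sel <- core[i] & core[j] & runif(nrow(ut)) < pCore
  w[ut[sel, , drop = FALSE]] <- lnw(sum(sel), wCore) * sqrt(s[i[sel]] * s[j[sel]])
  lattice <- !core[i] & !core[j] & comm[i] == comm[j] &
    abs(pos[i] - pos[j]) <= ringHalf
  w[ut[lattice, , drop = FALSE]] <-
    lnw(sum(lattice), wIntra) * sqrt(s[i[lattice]] * s[j[lattice]])
  short <- !core[i] & !core[j] & comm[i] == comm[j] &
    abs(pos[i] - pos[j]) > ringHalf & runif(nrow(ut)) < pIntra
  w[ut[short, , drop = FALSE]] <-
    lnw(sum(short), wIntra) * sqrt(s[i[short]] * s[j[short]])
  inter <- !core[i] & !core[j] & comm[i] != comm[j] & runif(nrow(ut)) < pInter
  w[ut[inter, , drop = FALSE]] <-
    lnw(sum(inter), wInter) * sqrt(s[i[inter]] * s[j[inter]])
  # graded direct attachment of arm nodes to the core
  per <- which(!core)
  decay <- exp(-(pos[per] - 1) / anchorScale)
  nAnchor <- ifelse(runif(length(per)) < pAnchor * decay, 2L,
                    ifelse(runif(length(per)) < pAnchor * decay, 1L, 0L))
  nAnchor[pos[per] <= 2] <- 3L        # arm heads always multiply anchored
  coreIdx <- which(core)
  for (t in seq_along(per)) {
    if (nAnchor[t] == 0L) next
    pnode <- per[t]
    wmed <- max(wInter, wIntra * decay[t])
    a <- sample(coreIdx, nAnchor[t])
    w[pnode, a] <- w[a, pnode] <- lnw(nAnchor[t], wmed) * sqrt(s[pnode] * s[a])
  }
  w[lower.tri(w)] <- 0
  w <- w + t(w)
  # bridge any stray components with minimal wInter edges
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  cmp <- igraph::components(g)
  if (cmp$no > 1L) {
    anchor <- which(cmp$membership == 1L)[1]
    for (c2 in 2:cmp$no) {
      other <- which(cmp$membership == c2)[1]
      w[anchor, other] <- w[other, anchor] <- wInter
    }
  }
  labels <- defaultNodeLabels(n)
  dimnames(w) <- list(labels, labels)
  # anatomy decoupled from topology: cluster by community, core scattered
  centers <- matrix(runif((communities + 1) * 3, -70, 70), communities + 1, 3)
  anatGroup <- ifelse(core, sample.int(communities, n, replace = TRUE), comm)
  xyz <- centers[anatGroup, , drop = FALSE] + matrix(rnorm(n * 3, 0, 10), n, 3)
  nodes <- data.frame(label = labels,
                      lobe = paste0("community", ifelse(core, 0L, comm)),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      rich_club = core, stringsAsFactors = FALSE)
  list(connectome = WeightedConnectome(w, labels), nodes = nodes)
}

#' Synthetic Swiss roll
#'
#' Samples the classic benchmark manifold: a 2-D sheet rolled up in 3-D via
#' \code{(t cos t, h, t sin t)} with \code{t} uniform on
#' \code{[1.5 pi, 4.5 pi]} and \code{h} uniform on \code{[0, 21]}. The true
#' (isometric) manifold coordinates are the arc length
#' \code{s(t) = (t sqrt(1 + t^2) + asinh(t)) / 2} and \code{h}, so Euclidean
#' distances between intrinsic rows are genuine geodesic distances along the
#' unrolled sheet.
#'
#' @param m number of points (at least 10).
#' @param noiseSd standard deviation of isotropic Gaussian ambient noise.
#' @param seed RNG seed.
#' @return list with \code{ambient} (\code{m x 3}) and \code{intrinsic}
#'   (\code{m x 2}) coordinate matrices.
#' @export
makeSwissRoll <- function(m = 1000L, noiseSd = 0, seed = 1L) {
  stopifnot(m >= 10)
  set.seed(seed)
  t_ <- runif(m, 1.5 * pi, 4.5 * pi)
  h <- runif(m, 0, 21)
  ambient <- cbind(t_ * cos(t_), h, t_ * sin(t_))
  if (noiseSd > 0) ambient <- ambient + matrix(rnorm(3 * m, 0, noiseSd), m, 3)
  s <- (t_ * sqrt(1 + t_^2) + asinh(t_)) / 2
  list(ambient = ambient, intrinsic = cbind(s, h))
}

#' Synthetic label volume
#'
#' Voronoi tessellation of a voxel grid around randomly placed seed voxels:
#' every voxel is labelled by its nearest seed (Euclidean distance on voxel
#' indices, ties to the lower label). Regions need not be contiguous in
#' pathological cases, matching the point-set treatment of the subdivision
#' algorithm.
#'
#' @param shape length-3 integer grid dimensions.
#' @param nRegions number of regions; at most \code{prod(shape)}.
#' @param seed RNG seed.
#' @param voxelSize voxel edge lengths in mm.
#' @return a [LabelVolume-class].
#' @export
makeLabelVolume <- function(shape = c(32L, 32L, 32L), nRegions = 10L,
                            seed = 1L, voxelSize = c(1, 1, 1)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, prod(shape) >= nRegions)
  set.seed(seed)
  seedLin <- sample.int(prod(shape), nRegions)
  seedIdx <- arrayInd(seedLin, shape)
  grid <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                                z = seq_len(shape[3])))
  lab <- integer(nrow(grid))
  chunk <- 65536L
  for (start in seq(1L, nrow(grid), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(grid))
    d2 <- outer(rowSums(grid[rows, , drop = FALSE]^2),
                rowSums(seedIdx^2), `+`) -
      2 * grid[rows, , drop = FALSE] %*% t(seedIdx)
    lab[rows] <- max.col(-d2, ties.method = "first")
  }
  LabelVolume(array(lab, dim = shape), voxelSize)
}
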