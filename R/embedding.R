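#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix, \code{B = -1/2 J (D * D) J}
#' with \code{J = I - 11'/n}, eigendecomposes \code{B} and scales the top
#' \code{d} eigenvectors by the square roots of their (nonnegative-clamped)
#' eigenvalues. Each coordinate axis is sign-flipped so its largest-magnitude
#' entry is positive, making the output deterministic across platforms.
#'
#' @param distances symmetric \code{n x n} distance matrix, zero diagonal,
#'   nonnegative.
#' @param d target dimension, \code{1 <= d <= n - 1}.
#' @param method label recorded on the result (internal use by Isomap).
#' @param kUsed neighbourhood size recorded on the result (internal use).
#' @return a [ConnectomeEmbedding-class]; negative eigenvalues among the
#'   retained \code{d} (non-Euclidean input) are clamped to zero and their
#'   count reported via \code{message()}.
#' @examples
#' dm <- as.matrix(dist(cbind(c(0, 0, 1, 1), c(0, 1, 1, 0))))
#' classicalMDS(dm, 2)
#' @export
classicalMDS <- function(distances, d = 3L, method = "MDS",
                         kUsed = NA_integer_) {
  dm <- as.matrix(distances)
  n <- nrow(dm)
  if (n != ncol(dm)) stop("distance matrix must be square")
  if (d < 1 || d > n - 1) stop("d must be in [1, n - 1], got ", d)
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  d2 <- dm^2
  rm_ <- rowMeans(d2)
  B <- -0.5 * (d2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(d2))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  vals <- eig$values[seq_len(d)]
  nneg <- sum(vals < 0)
  if (nneg > 0)
    message(nneg, " negative eigenvalue(s) among the retained ", d,
            " clamped to zero (input not Euclidean-embeddable)")
  vals <- pmax(vals, 0)
  co <- eig$vectors[, seq_len(d), drop = FALSE] *
    rep(sqrt(vals), each = n)
  # eigenvectors of numerically-zero eigenvalues can leak the constant
  # direction; re-centre explicitly so the centroid invariant holds exactly
  co <- sweep(co, 2, colMeans(co))
  co <- fixSigns(co)
  rownames(co) <- rownames(dm)
  ConnectomeEmbedding(co, method = method, eigenvalues = vals, kUsed = kUsed)
}

# flip each column so its largest-magnitude entry (first on ties) is positive
fixSigns <- function(co) {
  for (j in seq_len(ncol(co))) {
    i <- which.max(abs(co[, j]))
    if (co[i, j] < 0) co[, j] <- -co[, j]
  }
  co
}

#' Smallest k whose k-nearest-neighbour graph is connected
#'
#' Scans \code{k = kStart, kStart + 1, ...} until the union-symmetrized
#' k-nearest-neighbour graph on Euclidean row distances forms a single
#' connected component; \code{k = m - 1} always succeeds. This is the
#' iterative neighbourhood growth used to guarantee that every node takes
#' part in Isomap's manifold construction.
#'
#' @param points \code{m x p} coordinate matrix.
#' @param kStart first neighbourhood size to try (default 3).
#' @return the minimal connecting \code{k}.
#' @export
minConnectedK <- function(points, kStart = 3L) {
  m <- nrow(points)
  if (m < 2) stop("need at least 2 points")
  dm <- as.matrix(dist(points))
  for (k in seq(from = max(1L, kStart), to = m - 1L)) {
    if (knnIsConnected(dm, k)) return(as.integer(k))
  }
  as.integer(m - 1L)
}

# union-symmetrized kNN adjacency from a full distance matrix;
# equidistant candidates are broken toward the lower node index
knnAdjacency <- function(dm, k) {
  m <- nrow(dm)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    ord <- order(dm[i, ], seq_len(m))
    nb <- setdiff(ord, i)[seq_len(k)]
    adj[i, nb] <- TRUE
  }
  adj | t(adj)
}

knnIsConnected <- function(dm, k) {
  adj <- knnAdjacency(dm, k)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::is_connected(g)
}

#' Isomap embedding
#'
#' Nonlinear dimensionality reduction in three steps: (i) build the
#' union-symmetrized k-nearest-neighbour graph on Euclidean distances between
#' the rows of \code{points}; (ii) estimate geodesic distances along the
#' manifold as all-pairs shortest paths over that graph (edge weights =
#' neighbour Euclidean distances, Dijkstra); (iii) embed the geodesic
#' distance matrix with [classicalMDS()]. With \code{k = "auto"} the
#' neighbourhood is grown from \code{kStart} until the graph is connected.
#'
#' @param points \code{n x p} coordinate matrix — typically the
#'   high-dimensional graph-distance representation of a connectome.
#' @param d target dimension.
#' @param k neighbourhood size, or \code{"auto"} (default).
#' @param kStart first k tried when \code{k = "auto"}.
#' @return a [ConnectomeEmbedding-class] with \code{kUsed} recorded.
#' @export
isomapEmbed <- function(points, d = 3L, k = "auto", kStart = 3L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (d < 1 || d > n - 1) stop("d must be in [1, n - 1], got ", d)
  geo <- isomapGeodesics(points, k = k, kStart = kStart)
  emb <- classicalMDS(geo, d, method = "Isomap",
                      kUsed = attr(geo, "kUsed"))
  rownames(emb@coords) <- rownames(points)
  emb
}

#' Geodesic distance matrix of the Isomap neighbourhood graph
#'
#' Steps (i) and (ii) of [isomapEmbed()] alone: the all-pairs shortest-path
#' distances over the union-symmetrized k-nearest-neighbour graph. This is
#' the reference distance matrix against which an Isomap embedding's
#' [residualVariance()] is conventionally measured.
#'
#' @inheritParams isomapEmbed
#' @return symmetric \code{n x n} matrix with attribute \code{kUsed}.
#' @export
isomapGeodesics <- function(points, k = "auto", kStart = 3L) {
  points <- as.matrix(points)
  dm <- as.matrix(dist(points))
  if (identical(k, "auto")) {
    kUse <- minConnectedK(points, kStart)
  } else {
    kUse <- as.integer(k)
    if (!knnIsConnected(dm, kUse))
      stop("kNN graph disconnected at k = ", kUse,
           "; use k = \"auto\" to grow the neighbourhood until connected")
  }
  adj <- knnAdjacency(dm, kUse)
  len <- ifelse(adj, dm, Inf)
  diag(len) <- 0
  geo <- graphDistances(len)
  attr(geo, "kUsed") <- kUse
  geo
}

#' Distance of each embedded node to the embedding centre
#'
#' Euclidean norm of each coordinate row after subtracting the column-mean
#' centroid (a no-op for embeddings, whose centroid is already at the
#' origin). Rotation-invariant.
#'
#' @param embedding a [ConnectomeEmbedding-class] or coordinate matrix.
#' @return numeric vector of nonnegative distances.
#' @export
distanceToCenter <- function(embedding) {
  co <- if (is(embedding, "ConnectomeEmbedding")) embedding@coords
        else as.matrix(embedding)
  co <- sweep(co, 2, colMeans(co))
  out <- sqrt(rowSums(co^2))
  names(out) <- rownames(co)
  out
}

#' Residual variance of an embedding
#'
#' \code{1 - r^2} between the upper-triangle input distances and the embedded
#' Euclidean distances — the standard goodness-of-fit diagnostic for Isomap
#' and MDS (0 = distances perfectly reproduced).
#'
#' @param distances the \code{n x n} input distance matrix.
#' @param embedding a [ConnectomeEmbedding-class] on the same \code{n} nodes.
#' @return scalar in \code{[0, 1]}.
#' @export
residualVariance <- function(distances, embedding) {
  dm <- as.matrix(distances)
  co <- if (is(embedding, "ConnectomeEmbedding")) embedding@coords
        else as.matrix(embedding)
  if (nrow(dm) != nrow(co)) stop("distance matrix and embedding sizes differ")
  ed <- as.matrix(dist(co))
  ut <- upper.tri(dm)
  a <- dm[ut]; b <- ed[ut]
  if (sd(a) == 0 || sd(b) == 0) stop("degenerate (constant) distances")
  1 - cor(a, b)^2
}
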