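#' Edge lengths from connection weights
#'
#' Converts coupling strengths to travel costs: the length of an edge is the
#' inverse of its weight, so strongly coupled node pairs are close. A zero
#' weight means no edge (infinite length), not an infinitely strong one.
#'
#' @param x a [WeightedConnectome-class].
#' @return an \code{n x n} numeric matrix of edge lengths, \code{Inf} where no
#'   edge exists, 0 on the diagonal.
#' @export
edgeLengths <- function(x) {
  stopifnot(is(x, "WeightedConnectome"))
  w <- connWeights(x)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  len
}

lengthsToIgraph <- function(len) {
  n <- nrow(len)
  idx <- which(upper.tri(len) & is.finite(len), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(idx))
  igraph::E(g)$weight <- len[idx]
  g
}

#' All-pairs shortest-path graph distances
#'
#' Runs Dijkstra's algorithm from every node over the edge-length graph
#' (lengths = inverse weights). The rows of the resulting matrix are the
#' high-dimensional node coordinates: node \code{i} sits at the vector of its
#' graph distances to every node.
#'
#' @param x a [WeightedConnectome-class] or an edge-length matrix as returned
#'   by [edgeLengths()].
#' @return symmetric \code{n x n} matrix of finite shortest-path lengths with
#'   zero diagonal.
#' @examples
#' w <- matrix(c(0, 1, 0, 1, 0, 4, 0, 4, 0), 3, 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' graphDistances(WeightedConnectome(w))   # dist(A, C) = 1 + 0.25
#' @export
graphDistances <- function(x) {
  len <- if (is(x, "WeightedConnectome")) edgeLengths(x) else as.matrix(x)
  n <- nrow(len)
  g <- lengthsToIgraph(len)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    other <- which(comp$membership != comp$membership[1])
    labs <- rownames(len) %||% as.character(seq_len(n))
    stop("graph is disconnected: node(s) ",
         paste(labs[head(other, 5)], collapse = ", "),
         if (length(other) > 5) ", ..." else "",
         " unreachable from ", labs[1])
  }
  d <- igraph::distances(g, algorithm = "dijkstra")
  d <- (d + t(d)) / 2          # remove last-bit asymmetry from traversal order
  diag(d) <- 0
  dimnames(d) <- dimnames(len)
  d
}

#' High-dimensional node representation
#'
#' Places node \code{i} at the coordinates given by its vector of graph
#' distances to every node, so the representation is the graph-distance
#' matrix itself read row-wise as an \code{n}-dimensional point cloud.
#'
#' @param distances symmetric graph-distance matrix from [graphDistances()].
#' @return the same matrix, rows interpreted as point coordinates.
#' @export
highDimRepresentation <- function(distances) {
  distances <- as.matrix(distances)
  stopifnot(nrow(distances) == ncol(distances))
  distances
}

#' Euclidean distance between two nodes' high-dimensional representations
#'
#' \code{sqrt(sum_i (dist(k, i) - dist(l, i))^2)}: two nodes are close in the
#' intrinsic geometry when they hold similar coupling patterns with the rest
#' of the network.
#'
#' @param representation matrix from [highDimRepresentation()].
#' @param k,l node indices (1-based).
#' @return nonnegative scalar.
#' @export
representationDistance <- function(representation, k, l) {
  n <- nrow(representation)
  if (k < 1 || k > n || l < 1 || l > n)
    stop("node index out of range [1, ", n, "]")
  sqrt(sum((representation[k, ] - representation[l, ])^2))
}

#' Nodal path length
#'
#' A node's mean graph distance to all other nodes (self-distance excluded).
#' Nodes with shorter nodal path length communicate more efficiently with the
#' rest of the network.
#'
#' @param distances symmetric graph-distance matrix.
#' @return numeric vector of length \code{n}.
#' @export
nodalPathLength <- function(distances) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (n < 2) stop("nodal path length needs at least 2 nodes")
  out <- rowSums(distances) / (n - 1)
  names(out) <- rownames(distances)
  out
}
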