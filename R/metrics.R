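#' Nodal strength
#'
#' Sum of the weights incident to each node.
#'
#' @param x a [WeightedConnectome-class].
#' @return numeric vector of length \code{n}.
#' @export
nodalStrength <- function(x) {
  stopifnot(is(x, "WeightedConnectome"))
  out <- rowSums(connWeights(x))
  names(out) <- nodeLabels(x)
  out
}

#' Weighted clustering coefficient (Onnela)
#'
#' \code{c(i) = (1 / (k_i (k_i - 1))) * sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3)}
#' where \code{w' = w / max(w)} and \code{k_i} is the binary degree; nodes
#' with fewer than two neighbours get 0. Values lie in \code{[0, 1]}.
#'
#' @param x a [WeightedConnectome-class].
#' @return numeric vector of length \code{n}.
#' @export
clusteringCoefficient <- function(x) {
  stopifnot(is(x, "WeightedConnectome"))
  w <- connWeights(x)
  wn <- (w / max(w))^(1 / 3)
  k <- rowSums(w > 0)
  num <- diag(wn %*% wn %*% wn)
  denom <- k * (k - 1)
  out <- ifelse(denom > 0, num / denom, 0)
  names(out) <- nodeLabels(x)
  out
}

#' Shortest-path betweenness centrality on edge lengths
#'
#' Brandes' node betweenness over shortest paths on the edge-length graph
#' (lengths = inverse weights), endpoints excluded, equal-length path
#' multiplicities split fractionally, unnormalized.
#'
#' @param x a [WeightedConnectome-class] or edge-length matrix from
#'   [edgeLengths()].
#' @return numeric vector of length \code{n}.
#' @export
betweennessCentrality <- function(x) {
  len <- if (is(x, "WeightedConnectome")) edgeLengths(x) else as.matrix(x)
  g <- lengthsToIgraph(len)
  if (!igraph::is_connected(g)) stop("graph is disconnected")
  out <- igraph::betweenness(g, directed = FALSE,
                             weights = igraph::E(g)$weight)
  names(out) <- rownames(len)
  out
}

#' Embeddedness score (nodal efficiency over information-decay rate)
#'
#' A proxy for the embeddedness centrality described as the ratio between a
#' node's efficiency and its rate of information-transfer decay. Numerator:
#' nodal efficiency \code{E(i) = mean_{j != i} 1 / dist(i, j)}. Denominator:
#' the decay rate \code{lambda(i)}, minus the least-squares slope of
#' \code{log(mean inverse graph distance to the h-hop shell)} against hop
#' count \code{h} on the binarized graph. The exact published formula is not
#' fully specified, so this is a documented approximation; supply
#' \code{ranking} to use any externally computed per-node score instead.
#'
#' @param x a [WeightedConnectome-class].
#' @param distances optional precomputed graph-distance matrix.
#' @param ranking optional numeric vector (length \code{n}) passed through
#'   unchanged as the score.
#' @return numeric vector; nodes with non-decaying shells (\code{lambda <= 0}
#'   or fewer than 2 shells) get \code{Inf} and a warning.
#' @export
embeddednessScore <- function(x, distances = NULL, ranking = NULL) {
  stopifnot(is(x, "WeightedConnectome"))
  n <- nNodes(x)
  if (!is.null(ranking)) {
    stopifnot(length(ranking) == n)
    out <- as.numeric(ranking)
    names(out) <- nodeLabels(x)
    return(out)
  }
  if (is.null(distances)) distances <- graphDistances(x)
  eff <- vapply(seq_len(n), function(i)
    mean(1 / distances[i, -i]), numeric(1))
  # hop shells on the binarized graph
  adj <- connWeights(x) > 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  hops <- igraph::distances(g)
  lambda <- vapply(seq_len(n), function(i) {
    H <- max(hops[i, ])
    if (H < 2) return(NA_real_)
    y <- vapply(seq_len(H), function(h) {
      shell <- which(hops[i, ] == h)
      log(mean(1 / distances[i, shell]))
    }, numeric(1))
    -unname(coef(lm(y ~ seq_len(H)))[2])
  }, numeric(1))
  bad <- is.na(lambda) | lambda <= 0
  if (any(bad))
    warning(sum(bad), " node(s) with non-decaying shells; score set to Inf")
  out <- ifelse(bad, Inf, eff / lambda)
  names(out) <- nodeLabels(x)
  out
}

#' Regression of centre distance on nodal path length
#'
#' Computes each node's Euclidean distance to the centroid of the supplied
#' coordinates (anatomic positions or an embedding) and fits an ordinary
#' least-squares line of that distance on nodal path length. A high r-squared
#' means central placement tracks communication efficiency — the key
#' validation that an embedding captures intrinsic network geometry.
#'
#' @param coords \code{n x p} coordinate matrix or a
#'   [ConnectomeEmbedding-class].
#' @param npl nodal path length vector from [nodalPathLength()].
#' @param space label stored with the result (e.g. \code{"anatomic"},
#'   \code{"MDS"}, \code{"Isomap"}).
#' @return list with \code{rSquared}, \code{slope}, \code{intercept},
#'   \code{space}, \code{rmse} (root mean squared error of the residuals).
#' @export
centralityValidation <- function(coords, npl, space = "embedding") {
  dc <- distanceToCenter(coords)
  if (length(dc) != length(npl)) stop("coordinate and npl lengths differ")
  if (length(npl) < 3) stop("need at least 3 nodes")
  if (sd(dc) == 0 || sd(npl) == 0) stop("degenerate correlation: constant input")
  fit <- lm(dc ~ npl)
  list(rSquared = unname(cor(dc, npl)^2),
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       rmse = sqrt(mean(resid(fit)^2)),
       space = space)
}

#' Rank nodes by distance to the embedding centre
#'
#' Sorts nodes ascending by [distanceToCenter()] (ties broken
#' alphabetically by label), carrying rich-club flags through when present —
#' the tabular form of the "which regions are most central" ranking.
#'
#' @param embedding a [ConnectomeEmbedding-class].
#' @param nodes optional node table with \code{label} and optionally
#'   \code{rich_club}.
#' @return \code{data.frame} with columns \code{label}, \code{distance},
#'   \code{rank} and, when available, \code{rich_club}.
#' @export
rankByCenterDistance <- function(embedding, nodes = NULL) {
  dc <- distanceToCenter(embedding)
  labels <- names(dc) %||% defaultNodeLabels(length(dc))
  out <- data.frame(label = labels, distance = unname(dc),
                    stringsAsFactors = FALSE)
  if (!is.null(nodes) && "rich_club" %in% names(nodes))
    out$rich_club <- as.logical(nodes$rich_club[match(out$label, nodes$label)])
  out <- out[order(out$distance, out$label), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Embedding-dimension sweep of residual centre-distance error
#'
#' For each candidate dimension, computes the Isomap embedding of the
#' high-dimensional representation, regresses distance-to-centre on nodal
#' path length, and records the root mean squared error of the residuals.
#' The dimension where the curve levels off indicates how many dimensions
#' the intrinsic geometry needs.
#'
#' @param representation high-dimensional representation matrix.
#' @param npl nodal path length vector.
#' @param dims integer vector of dimensions to try (default \code{1:8}).
#' @param kStart first k for the automatic Isomap neighbourhood.
#' @return list with \code{dims}, \code{rmse} and \code{kUsed} (all aligned).
#' @export
dimensionSweep <- function(representation, npl, dims = 1:8, kStart = 3L) {
  n <- nrow(representation)
  stopifnot(all(dims >= 1), all(dims <= n - 1))
  rmse <- numeric(length(dims))
  kk <- integer(length(dims))
  for (i in seq_along(dims)) {
    emb <- isomapEmbed(representation, d = dims[i], k = "auto", kStart = kStart)
    v <- centralityValidation(emb, npl, space = sprintf("Isomap-%dD", dims[i]))
    rmse[i] <- v$rmse
    kk[i] <- kUsed(emb)
  }
  list(dims = as.integer(dims), rmse = rmse, kUsed = kk)
}
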