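#' Remove a set of nodes from a connectome
#'
#' Pure submatrix extraction: surviving edge weights and labels are
#' untouched. Removal that disconnects the survivor graph is an error, since
#' every downstream statistic assumes finite graph distances.
#'
#' @param x a [WeightedConnectome-class].
#' @param removed character labels or integer indices of nodes to remove;
#'   must be a nonempty proper subset.
#' @return the surviving [WeightedConnectome-class].
#' @export
removeNodes <- function(x, removed) {
  stopifnot(is(x, "WeightedConnectome"))
  n <- nNodes(x)
  idx <- if (is.character(removed)) match(removed, nodeLabels(x))
         else as.integer(removed)
  if (anyNA(idx) || any(idx < 1) || any(idx > n))
    stop("unknown node in removal set")
  idx <- unique(idx)
  if (length(idx) == 0 || length(idx) >= n)
    stop("removal set must be a nonempty proper subset of nodes")
  keep <- setdiff(seq_len(n), idx)
  w <- connWeights(x)[keep, keep, drop = FALSE]
  if (any(rowSums(w > 0) == 0) || !survivorConnected(w))
    stop("removal disconnects the survivor graph")
  WeightedConnectome(w, nodeLabels(x)[keep])
}

survivorConnected <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  igraph::is_connected(g)
}

#' Cohesion statistic d-bar
#'
#' The mean Euclidean distance from all embedded nodes to the centre of the
#' embedding: small after removals that leave the network cohesive, large
#' when the removal stretches the surviving geometry.
#'
#' @param embedding a [ConnectomeEmbedding-class].
#' @return nonnegative scalar.
#' @export
dbar <- function(embedding) mean(distanceToCenter(embedding))

#' Normalized cohesion statistic
#'
#' Multiplies d-bar by the mean coupling weight of the surviving network —
#' the average over all off-diagonal node pairs, zeros (absent edges)
#' included; set \code{includeZeros = FALSE} to average connected pairs only.
#'
#' @param d a raw d-bar value.
#' @param surviving the surviving [WeightedConnectome-class].
#' @param includeZeros average over all pairs (default) or nonzero pairs.
#' @return nonnegative scalar.
#' @export
normalizedDbar <- function(d, surviving, includeZeros = TRUE) {
  stopifnot(d >= 0, is(surviving, "WeightedConnectome"))
  w <- connWeights(surviving)
  off <- w[upper.tri(w) | lower.tri(w)]
  mult <- if (includeZeros) mean(off) else mean(off[off > 0])
  d * mult
}

# round-half-away-from-zero, platform-stable (round() rounds half to even)
roundHalfUp <- function(x) floor(x + 0.5)

.SCHEMES <- c("random", "rich_club", "strength", "clustering", "path_length",
              "betweenness", "embeddedness", "subcortical", "custom")

schemeRemovalSet <- function(x, scheme, nRemove, nodes = NULL,
                             ranking = NULL, distances = NULL) {
  labels <- nodeLabels(x)
  flagged <- function(col) {
    if (is.null(nodes) || !col %in% names(nodes))
      stop("scheme '", scheme, "' needs a node table with a '", col, "' column")
    nodes$label[as.logical(nodes[[col]]) %in% TRUE]
  }
  ord <- switch(scheme,
    strength = order(-nodalStrength(x), labels),
    clustering = order(clusteringCoefficient(x), labels),
    path_length = {
      if (is.null(distances)) distances <- graphDistances(x)
      order(nodalPathLength(distances), labels)
    },
    betweenness = order(-betweennessCentrality(x), labels),
    embeddedness = {
      s <- embeddednessScore(x, distances = distances, ranking = ranking)
      order(-s, labels)
    },
    rich_club = return(flagged("rich_club")),
    subcortical = return(flagged("subcortical")),
    custom = {
      if (is.null(ranking)) stop("scheme 'custom' needs a ranking vector")
      order(-as.numeric(ranking), labels)
    },
    stop("unknown scheme '", scheme, "'; valid: ",
         paste(.SCHEMES, collapse = ", ")))
  labels[ord[seq_len(nRemove)]]
}

#' Targeted node removal
#'
#' Ranks nodes by the chosen scheme's metric — strength (descending),
#' clustering (ascending), nodal path length (ascending), betweenness
#' (descending), embeddedness (descending), or a metadata flag
#' (\code{rich_club}, \code{subcortical}) — removes the top
#' \code{round(fraction * n)} (flag schemes remove exactly the flagged set),
#' recomputes graph distances and the Isomap embedding on the survivors from
#' scratch, and scores the result with raw and normalized d-bar.
#'
#' @param x a [WeightedConnectome-class].
#' @param scheme one of \code{"strength"}, \code{"clustering"},
#'   \code{"path_length"}, \code{"betweenness"}, \code{"embeddedness"},
#'   \code{"rich_club"}, \code{"subcortical"}, \code{"custom"}.
#' @param fraction proportion of nodes to remove (default 0.215, the
#'   rich-club share of the upsampled cortical network this statistic was
#'   designed around).
#' @param embedDim embedding dimension for the survivor Isomap (default 3).
#' @param nodes node table with flag columns (needed for flag schemes).
#' @param ranking optional per-node score for \code{"custom"} or to replace
#'   the embeddedness proxy.
#' @param kStart Isomap automatic-neighbourhood start.
#' @return a [RemovalResult-class].
#' @export
targetedRemoval <- function(x, scheme, fraction = 0.215, embedDim = 3L,
                            nodes = NULL, ranking = NULL, kStart = 3L) {
  stopifnot(is(x, "WeightedConnectome"))
  n <- nNodes(x)
  if (scheme %in% c("rich_club", "subcortical")) {
    removed <- schemeRemovalSet(x, scheme, NA, nodes = nodes)
    if (length(removed) == 0) stop("no nodes flagged for scheme '", scheme, "'")
    fraction <- length(removed) / n
  } else {
    nRemove <- roundHalfUp(fraction * n)
    if (nRemove < 1 || nRemove >= n)
      stop("fraction ", fraction, " removes ", nRemove, " of ", n, " nodes")
    removed <- schemeRemovalSet(x, scheme, nRemove, nodes = nodes,
                                ranking = ranking)
  }
  surv <- removeNodes(x, removed)
  emb <- survivorEmbedding(surv, embedDim, kStart)
  d <- dbar(emb)
  new("RemovalResult", scheme = scheme, removed = removed,
      fraction = fraction, dbarRaw = d,
      dbarNormalized = normalizedDbar(d, surv), embedding = emb)
}

survivorEmbedding <- function(surv, embedDim, kStart) {
  rep_ <- highDimRepresentation(graphDistances(surv))
  isomapEmbed(rep_, d = embedDim, k = "auto", kStart = kStart)
}

#' Monte-Carlo random-removal distribution of d-bar
#'
#' Repeatedly removes a uniformly drawn node subset of size
#' \code{round(fraction * n)} (redrawing, up to 100 times per trial, draws
#' that disconnect the survivors), recomputes the survivor Isomap embedding
#' from scratch, and collects d-bar. Fully reproducible from \code{seed}.
#'
#' @param x a [WeightedConnectome-class].
#' @param fraction proportion of nodes removed per trial.
#' @param trials number of Monte-Carlo trials.
#' @param seed RNG seed.
#' @param embedDim embedding dimension (default 3).
#' @param kStart Isomap automatic-neighbourhood start.
#' @return a [RandomRemovalDistribution-class] with the per-trial values,
#'   their mean and the (5th, 95th) percentile pair.
#' @export
randomRemovalDistribution <- function(x, fraction = 0.215, trials = 500L,
                                      seed = 1L, embedDim = 3L, kStart = 3L) {
  stopifnot(is(x, "WeightedConnectome"), trials >= 1)
  n <- nNodes(x)
  nRemove <- roundHalfUp(fraction * n)
  if (nRemove < 1 || nRemove >= n)
    stop("fraction ", fraction, " removes ", nRemove, " of ", n, " nodes")
  labels <- nodeLabels(x)
  vals <- numeric(trials)
  redraws <- 0L
  set.seed(seed)
  for (t in seq_len(trials)) {
    surv <- NULL
    for (attempt in seq_len(100L)) {
      drawn <- sample(labels, nRemove)
      surv <- tryCatch(removeNodes(x, drawn), error = function(e) NULL)
      if (!is.null(surv)) break
      redraws <- redraws + 1L
    }
    if (is.null(surv))
      stop("network too fragile for fraction ", fraction,
           ": 100 consecutive disconnecting draws")
    vals[t] <- dbar(survivorEmbedding(surv, embedDim, kStart))
  }
  if (redraws > 0)
    message(redraws, " disconnecting draw(s) redrawn across ", trials, " trials")
  qs <- unname(quantile(vals, c(0.05, 0.95), type = 7))
  new("RandomRemovalDistribution", trials = as.integer(trials),
      dbarValues = vals, mean = mean(vals), interval = qs,
      seed = as.integer(seed))
}
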