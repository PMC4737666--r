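#' @import methods
#' @importFrom stats cor dist lm median prcomp quantile resid rlnorm rnorm runif sd setNames coef
#' @importFrom utils head read.table write.table
NULL

## Symmetry / diagonal tolerances used by the WeightedConnectome validator.
.SYM_TOL <- 1e-9
.DIAG_TOL <- 1e-12

#' WeightedConnectome: a symmetric nonnegative coupling matrix with node labels
#'
#' The central container of the package: an \code{n x n} symmetric matrix of
#' nonnegative coupling strengths (for tractography data, streamline fiber
#' counts) with a zero diagonal and no isolated nodes, plus one character
#' label per node.
#'
#' @slot weights numeric matrix, \code{n x n}, symmetric, nonnegative, zero
#'   diagonal; \code{dimnames} carry the node labels.
#' @slot labels character vector of unique node labels, length \code{n}.
#'
#' @seealso [WeightedConnectome()] the constructor, [readConnectome()],
#'   [graphDistances()]
#' @export
setClass("WeightedConnectome",
  representation(weights = "matrix", labels = "character"))

setValidity("WeightedConnectome", function(object) {
  w <- object@weights
  lab <- object@labels
  msgs <- character()
  if (!is.numeric(w)) msgs <- c(msgs, "weights must be numeric")
  if (nrow(w) != ncol(w)) msgs <- c(msgs, "weights must be square")
  if (length(lab) != nrow(w)) msgs <- c(msgs, "labels length must equal node count")
  if (anyDuplicated(lab)) msgs <- c(msgs, "labels must be unique")
  if (length(msgs)) return(msgs)
  if (anyNA(w)) return("weights must not contain NA")
  if (any(w < 0)) return("weights must be nonnegative")
  if (max(abs(w - t(w))) > .SYM_TOL)
    return(sprintf("weights asymmetric beyond tolerance %g", .SYM_TOL))
  if (any(diag(w) != 0)) return("nonzero diagonal")
  deg <- rowSums(w > 0)
  if (any(deg == 0)) {
    bad <- lab[deg == 0]
    return(sprintf("isolated node(s): %s", paste(bad, collapse = ", ")))
  }
  TRUE
})

#' Construct a WeightedConnectome
#'
#' Validates and wraps a square symmetric nonnegative weight matrix.
#' Asymmetries at or below \code{1e-9} are removed by averaging with the
#' transpose; diagonal noise at or below \code{1e-12} is zeroed silently.
#' Missing labels default to \code{"N000" ... "N(n-1)"}.
#'
#' @param weights square numeric matrix of nonnegative coupling strengths.
#' @param labels optional character vector of node labels.
#' @return A [WeightedConnectome-class] object.
#' @examples
#' w <- matrix(c(0, 2, 0, 2, 0, 4, 0, 4, 0), 3, 3)
#' WeightedConnectome(w, c("A", "B", "C"))
#' @export
WeightedConnectome <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("weights must be square, got ", nrow(weights), " x ", ncol(weights))
  n <- nrow(weights)
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- defaultNodeLabels(n)
  }
  labels <- as.character(labels)
  storage.mode(weights) <- "double"
  asym <- max(abs(weights - t(weights)))
  if (asym > .SYM_TOL)
    stop(sprintf("matrix asymmetric beyond tolerance (max |w - t(w)| = %g)", asym))
  weights <- (weights + t(weights)) / 2
  d <- diag(weights)
  if (any(abs(d) > .DIAG_TOL))
    stop("nonzero diagonal (max |diag| = ", max(abs(d)), ")")
  diag(weights) <- 0
  dimnames(weights) <- list(labels, labels)
  new("WeightedConnectome", weights = weights, labels = labels)
}

defaultNodeLabels <- function(n) sprintf("N%03d", seq_len(n) - 1L)

#' @describeIn WeightedConnectome-class number of nodes
#' @param x,object a \code{WeightedConnectome}
#' @export
nNodes <- function(x) length(x@labels)

#' @describeIn WeightedConnectome-class the weight matrix
#' @export
connWeights <- function(x) x@weights

#' @describeIn WeightedConnectome-class the node labels
#' @export
nodeLabels <- function(x) x@labels

setMethod("show", "WeightedConnectome", function(object) {
  w <- object@weights
  n <- nrow(w)
  nz <- sum(w[upper.tri(w)] > 0)
  cat(sprintf("WeightedConnectome: %d nodes, %d edges (density %.3f)\n",
              n, nz, if (n > 1) nz / (n * (n - 1) / 2) else 0))
  cat(sprintf("  total weight: %.6g; labels: %s ...\n",
              sum(w) / 2, paste(head(object@labels, 4), collapse = ", ")))
})

#' ConnectomeEmbedding: a low-dimensional embedding of a connectome
#'
#' Coordinates produced by classical MDS or Isomap, with the centroid at the
#' origin and the retained spectral values in descending order.
#'
#' @slot coords numeric matrix, \code{n x d}; row names carry node labels.
#' @slot method \code{"MDS"} or \code{"Isomap"}.
#' @slot kUsed integer neighbourhood size actually used (NA for MDS).
#' @slot eigenvalues the \code{d} retained eigenvalues, descending,
#'   nonnegative (negative eigenvalues of non-Euclidean inputs are clamped).
#' @export
setClass("ConnectomeEmbedding",
  representation(coords = "matrix", method = "character",
                 kUsed = "integer", eigenvalues = "numeric"))

setValidity("ConnectomeEmbedding", function(object) {
  co <- object@coords
  ev <- object@eigenvalues
  if (!object@method %in% c("MDS", "Isomap"))
    return("method must be 'MDS' or 'Isomap'")
  if (ncol(co) != length(ev)) return("one eigenvalue per retained dimension")
  if (ncol(co) > max(nrow(co) - 1L, 1L)) return("d must be <= n - 1")
  if (nrow(co) > 0 && max(abs(colMeans(co))) > 1e-9)
    return("embedding centroid must be at the origin (within 1e-9)")
  if (is.unsorted(rev(ev))) return("eigenvalues must be sorted descending")
  if (any(ev < 0)) return("retained eigenvalues must be nonnegative")
  TRUE
})

ConnectomeEmbedding <- function(coords, method, eigenvalues,
                                kUsed = NA_integer_) {
  new("ConnectomeEmbedding", coords = coords, method = method,
      kUsed = as.integer(kUsed), eigenvalues = eigenvalues)
}

#' @describeIn ConnectomeEmbedding-class the coordinate matrix
#' @param x,object a \code{ConnectomeEmbedding}
#' @export
embeddingCoords <- function(x) x@coords

#' @describeIn ConnectomeEmbedding-class embedding dimension
#' @export
embeddingDim <- function(x) ncol(x@coords)

#' @describeIn ConnectomeEmbedding-class neighbourhood size used (Isomap)
#' @export
kUsed <- function(x) x@kUsed

#' @describeIn ConnectomeEmbedding-class retained eigenvalues, descending
#' @export
embeddingEigenvalues <- function(x) x@eigenvalues

setMethod("show", "ConnectomeEmbedding", function(object) {
  cat(sprintf("ConnectomeEmbedding: %s, %d nodes in %d dimensions%s\n",
              object@method, nrow(object@coords), ncol(object@coords),
              if (!is.na(object@kUsed)) sprintf(" (k = %d)", object@kUsed) else ""))
  cat("  eigenvalues:", paste(signif(object@eigenvalues, 4), collapse = ", "), "\n")
})

#' LabelVolume: a 3-D integer label image
#'
#' Voxelwise integer labels (0 = background) with physical voxel dimensions,
#' the unit the parcellation-upsampling algorithm consumes and produces.
#'
#' @slot labels 3-D integer array of region labels, 0 for background.
#' @slot voxelSize numeric length-3 voxel edge lengths in mm.
#' @export
setClass("LabelVolume",
  representation(labels = "array", voxelSize = "numeric"))

setValidity("LabelVolume", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3-D array")
  if (length(object@voxelSize) != 3L) return("voxelSize must have length 3")
  if (any(object@voxelSize <= 0)) return("voxelSize must be positive")
  if (any(object@labels < 0)) return("labels must be nonnegative")
  if (!any(object@labels > 0)) return("at least one nonzero label required")
  TRUE
})

#' Construct a LabelVolume
#'
#' @param labels 3-D integer array of region labels (0 = background).
#' @param voxelSize numeric length-3 voxel edge lengths in mm.
#' @return A [LabelVolume-class] object.
#' @export
LabelVolume <- function(labels, voxelSize = c(1, 1, 1)) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, voxelSize = as.numeric(voxelSize))
}

#' @describeIn LabelVolume-class the label array
#' @param x,object a \code{LabelVolume}
#' @export
labelArray <- function(x) x@labels

#' @describeIn LabelVolume-class voxel edge lengths (mm)
#' @export
voxelSize <- function(x) x@voxelSize

setMethod("show", "LabelVolume", function(object) {
  labs <- unique(as.vector(object@labels))
  cat(sprintf("LabelVolume: %s voxels (%.2f x %.2f x %.2f mm), %d regions\n",
              paste(dim(object@labels), collapse = " x "),
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
              sum(labs > 0)))
})

#' RemovalResult: outcome of one node-removal experiment
#'
#' @slot scheme removal scheme name.
#' @slot removed labels of the removed nodes.
#' @slot fraction removed proportion of nodes.
#' @slot dbarRaw mean distance of surviving embedded nodes to the embedding
#'   centre (the cohesion statistic d-bar).
#' @slot dbarNormalized d-bar multiplied by the surviving network's mean
#'   off-diagonal weight.
#' @slot embedding the post-removal [ConnectomeEmbedding-class].
#' @export
setClass("RemovalResult",
  representation(scheme = "character", removed = "character",
                 fraction = "numeric", dbarRaw = "numeric",
                 dbarNormalized = "numeric", embedding = "ConnectomeEmbedding"))

setValidity("RemovalResult", function(object) {
  if (object@fraction <= 0 || object@fraction >= 1)
    return("fraction must lie strictly between 0 and 1")
  if (object@dbarRaw < 0 || object@dbarNormalized < 0)
    return("d-bar statistics must be nonnegative")
  TRUE
})

setMethod("show", "RemovalResult", function(object) {
  cat(sprintf("RemovalResult: scheme '%s', removed %d nodes (%.1f%%)\n",
              object@scheme, length(object@removed), 100 * object@fraction))
  cat(sprintf("  d-bar raw: %.4f, normalized: %.4f\n",
              object@dbarRaw, object@dbarNormalized))
})

#' RandomRemovalDistribution: Monte-Carlo random-removal null distribution
#'
#' @slot trials number of Monte-Carlo trials.
#' @slot dbarValues per-trial cohesion statistic d-bar.
#' @slot mean mean of \code{dbarValues}.
#' @slot interval 5th and 95th percentiles of \code{dbarValues}.
#' @slot seed RNG seed used.
#' @export
setClass("RandomRemovalDistribution",
  representation(trials = "integer", dbarValues = "numeric", mean = "numeric",
                 interval = "numeric", seed = "integer"))

setValidity("RandomRemovalDistribution", function(object) {
  if (length(object@dbarValues) != object@trials)
    return("one d-bar value per trial required")
  if (length(object@interval) != 2L) return("interval must be (5th, 95th) pair")
  if (object@interval[1] > object@mean + 1e-12 ||
      object@mean > object@interval[2] + 1e-12)
    return("mean must lie within the percentile interval")
  TRUE
})

setMethod("show", "RandomRemovalDistribution", function(object) {
  cat(sprintf("RandomRemovalDistribution: %d trials, mean d-bar %.4f, 5-95%% (%.4f, %.4f)\n",
              object@trials, object@mean, object@interval[1], object@interval[2]))
})
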