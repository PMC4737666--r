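#' Read a NIfTI label volume
#'
#' @param path a \code{.nii} or \code{.nii.gz} file of integer labels.
#' @return a [LabelVolume-class] with voxel sizes taken from the header.
#' @export
readLabelVolume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  LabelVolume(array(as.integer(round(img)), dim = dim(img)), vs)
}

#' Write a label volume to NIfTI
#'
#' @param volume a [LabelVolume-class].
#' @param path output \code{.nii} / \code{.nii.gz} path.
#' @return \code{path}, invisibly.
#' @export
writeLabelVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@labels)
  RNifti::pixdim(img) <- volume@voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

# mm coordinates (voxel index scaled by voxel size) of one label's voxels
labelCoords <- function(volume, label) {
  idx <- which(volume@labels == label, arr.ind = TRUE)
  sweep(idx, 2, volume@voxelSize, `*`)
}

#' Pool one region across subjects into a centred group ROI
#'
#' Translates each subject's voxel coordinate set (voxel indices scaled to
#' mm) so its centroid sits at the origin, then pools the translated
#' coordinates — the cross-subject alignment step that precedes the
#' principal-axis computation.
#'
#' @param volumes list of [LabelVolume-class] objects.
#' @param label integer region label, present in every volume.
#' @return numeric matrix of pooled centred coordinates (one row per voxel,
#'   multiset union across subjects).
#' @export
groupROI <- function(volumes, label) {
  pooled <- lapply(seq_along(volumes), function(s) {
    co <- labelCoords(volumes[[s]], label)
    if (nrow(co) == 0)
      stop("label ", label, " absent in subject ", s)
    sweep(co, 2, colMeans(co))
  })
  do.call(rbind, pooled)
}

#' Principal axis of a voxel coordinate set
#'
#' The unit eigenvector of the coordinate covariance matrix with the largest
#' eigenvalue. Eigenvalue ties (within \code{1e-9} relative) are broken by
#' preferring the candidate with the largest |x| component, then |y|, then
#' |z|; the sign is fixed so the largest-magnitude component is positive.
#'
#' @param voxels numeric matrix of coordinates, one row per voxel; at least
#'   two distinct rows.
#' @return unit length-3 numeric vector.
#' @export
principalAxis <- function(voxels) {
  voxels <- as.matrix(voxels)
  if (nrow(unique(voxels)) < 2) stop("degenerate ROI: all coordinates identical")
  cv <- stats::cov(voxels)
  eig <- eigen(cv, symmetric = TRUE)
  tol <- 1e-9 * max(eig$values, 1e-300)
  tied <- which(eig$values >= eig$values[1] - tol)
  cand <- eig$vectors[, tied, drop = FALSE]
  pick <- 1L
  if (length(tied) > 1) {
    score <- abs(t(cand))          # rows: candidates; cols: |x|, |y|, |z|
    ord <- do.call(order, c(lapply(1:3, function(j) -score[, j])))
    pick <- ord[1]
  }
  ax <- cand[, pick]
  i <- which.max(abs(ax))
  if (ax[i] < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Bisect a voxel set by a plane perpendicular to an axis
#'
#' Projects the voxels onto the axis and splits at the median projection
#' (ties assigned to side A), so both sides are nonempty whenever the
#' projections are not all equal and the recursion in [subdivide()] always
#' terminates. With \code{at = "centroid"} the plane instead passes through
#' the projection of the centroid.
#'
#' @param voxels coordinate matrix, one row per voxel, at least 2 rows.
#' @param axis unit length-3 vector.
#' @param at \code{"median"} (default) or \code{"centroid"} split point.
#' @return list with coordinate matrices \code{A} (projections <= cut) and
#'   \code{B}, and the logical selector \code{inA}.
#' @export
bisectROI <- function(voxels, axis, at = c("median", "centroid")) {
  at <- match.arg(at)
  voxels <- as.matrix(voxels)
  stopifnot(nrow(voxels) >= 2)
  proj <- drop(voxels %*% axis)
  cut <- if (at == "median") median(proj) else mean(proj)
  inA <- proj <= cut
  list(A = voxels[inA, , drop = FALSE], B = voxels[!inA, , drop = FALSE],
       inA = inA)
}

#' Recursive principal-axis subdivision of a label volume
#'
#' Upsamples an atlas: every region whose voxel count is at least
#' \code{threshold} is bisected by a plane perpendicular to its principal
#' axis, recursively, until all pieces fall below the threshold (a region of
#' exactly \code{threshold} voxels is still split). When \code{groupVolumes}
#' is supplied, the axis at each step is computed on the pooled centred
#' group ROI ([groupROI()] semantics across the primary volume and the group
#' volumes), while the split is applied per subject at each subject's own
#' median projection; the returned volume is the subdivided primary volume.
#' Regions that cannot be split (identical coordinates, or a split that
#' leaves one side empty) are left whole and reported.
#'
#' @param volume primary [LabelVolume-class].
#' @param threshold voxel-count stopping threshold (split while
#'   \code{size >= threshold}); at least 2.
#' @param groupVolumes optional list of further [LabelVolume-class] objects
#'   defining the group ROI for axis estimation.
#' @param at split-plane placement, \code{"median"} or \code{"centroid"}.
#' @return list with \code{volume} (relabelled [LabelVolume-class]),
#'   \code{parentOf} (named integer map child label -> parent label),
#'   \code{childSizes} (named integer voxel counts), \code{threshold} and
#'   \code{degenerate} (labels left unsplit though at/above threshold).
#' @export
subdivide <- function(volume, threshold = 800L, groupVolumes = NULL,
                      at = "median") {
  stopifnot(is(volume, "LabelVolume"), threshold >= 2)
  parents <- sort(setdiff(unique(as.vector(volume@labels)), 0L))
  vols <- c(list(volume), groupVolumes)
  out <- array(0L, dim = dim(volume@labels))
  parentOf <- integer(0)
  childSizes <- integer(0)
  degenerate <- integer(0)
  nextLabel <- 0L

  for (p in parents) {
    # per-subject voxel sets for this parent; primary keeps array indices too
    primIdx <- which(volume@labels == p, arr.ind = TRUE)
    if (nrow(primIdx) == 0) next
    subjSets <- lapply(vols, function(v) {
      co <- labelCoords(v, p)
      if (nrow(co) == 0)
        stop("label ", p, " absent in a group volume")
      co
    })
    pieces <- splitRecursively(primIdx, subjSets, volume@voxelSize, threshold, at)
    for (piece in pieces$pieces) {
      nextLabel <- nextLabel + 1L
      out[piece] <- nextLabel
      parentOf[as.character(nextLabel)] <- p
      childSizes[as.character(nextLabel)] <- nrow(piece)
    }
    if (pieces$degenerate) degenerate <- c(degenerate, p)
  }
  list(volume = LabelVolume(out, volume@voxelSize),
       parentOf = parentOf, childSizes = childSizes,
       threshold = as.integer(threshold), degenerate = degenerate)
}

# depth-first recursion; returns list(pieces = list of primary arr.ind
# matrices, degenerate = TRUE if any at-threshold region could not be split)
splitRecursively <- function(primIdx, subjSets, voxelSize, threshold, at) {
  if (nrow(primIdx) < threshold)
    return(list(pieces = list(primIdx), degenerate = FALSE))
  pooled <- do.call(rbind, lapply(subjSets, function(co)
    sweep(co, 2, colMeans(co))))
  if (nrow(unique(pooled)) < 2)
    return(list(pieces = list(primIdx), degenerate = TRUE))
  axis <- principalAxis(pooled)
  primMM <- sweep(primIdx, 2, voxelSize, `*`)
  cutPrim <- bisectROI(primMM, axis, at)
  if (nrow(cutPrim$A) == 0 || nrow(cutPrim$B) == 0)
    return(list(pieces = list(primIdx), degenerate = TRUE))
  splitSubj <- lapply(subjSets, function(co) {
    b <- bisectROI(co, axis, at)
    if (nrow(b$A) == 0 || nrow(b$B) == 0) list(A = co, B = co) else b
  })
  left <- splitRecursively(primIdx[cutPrim$inA, , drop = FALSE],
                           lapply(splitSubj, `[[`, "A"),
                           voxelSize, threshold, at)
  right <- splitRecursively(primIdx[!cutPrim$inA, , drop = FALSE],
                            lapply(splitSubj, `[[`, "B"),
                            voxelSize, threshold, at)
  list(pieces = c(left$pieces, right$pieces),
       degenerate = left$degenerate || right$degenerate)
}

#' Write a subdivision genealogy table
#'
#' @param result a [subdivide()] result.
#' @param path output CSV path with columns \code{child,parent,size}.
#' @return \code{path}, invisibly.
#' @export
writeGenealogy <- function(result, path) {
  tab <- data.frame(child = as.integer(names(result$parentOf)),
                    parent = unname(result$parentOf),
                    size = unname(result$childSizes[names(result$parentOf)]))
  write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
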