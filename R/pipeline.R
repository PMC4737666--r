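#' Default pipeline configuration
#'
#' @param dim embedding dimension for the main MDS/Isomap embeddings.
#' @param kStart starting neighbourhood size for automatic Isomap.
#' @param seed global seed; per-stage seeds are derived as
#'   \code{seed + stage counter} so any stage can be reproduced alone.
#' @param fraction removal fraction for the lesion suite.
#' @param trials random-removal Monte-Carlo trials (0 skips the lesion
#'   stage's random arm and the targeted arms entirely when negative).
#' @param schemes targeted removal schemes to run.
#' @param sweepDims dimensions for the residual-error sweep.
#' @return named list of settings consumed by [runFullPipeline()].
#' @export
pipelineConfig <- function(dim = 3L, kStart = 3L, seed = 42L,
                           fraction = 0.215, trials = 100L,
                           schemes = c("strength", "clustering", "path_length",
                                       "betweenness", "embeddedness"),
                           sweepDims = 1:8) {
  list(dim = as.integer(dim), kStart = as.integer(kStart),
       seed = as.integer(seed), fraction = fraction,
       trials = as.integer(trials), schemes = schemes,
       sweepDims = as.integer(sweepDims))
}

#' Run the full intrinsic-geometry workflow on one connectome
#'
#' read -> graph distances -> high-dimensional representation -> MDS and
#' Isomap embeddings -> centrality validation in anatomic/MDS/Isomap space ->
#' centre-distance ranking -> lesion suite (random Monte-Carlo plus targeted
#' schemes, plus rich-club removal when the node table flags one) ->
#' embedding-dimension sweep. Writes a JSON report (and, when \code{outDir}
#' is given, viewer-ready embedding exports). Identical inputs, config and
#' seed give a byte-identical report.
#'
#' @param matrixPath path to a connectivity matrix file, or a
#'   [WeightedConnectome-class] directly.
#' @param nodesPath optional node table CSV path, or a \code{data.frame}.
#' @param config list from [pipelineConfig()].
#' @param outDir optional output directory; the report is written to
#'   \code{report.json} and 3-D embeddings to \code{embedding_<method>.json}.
#' @return the report as a named list (invisibly also written to disk).
#'   If a stage fails, its entry carries an \code{error} message and
#'   \code{failed} markers; completed stages are kept.
#' @export
runFullPipeline <- function(matrixPath, nodesPath = NULL,
                            config = pipelineConfig(), outDir = NULL) {
  conn <- if (is(matrixPath, "WeightedConnectome")) matrixPath
          else readConnectome(matrixPath)
  nodes <- if (is.null(nodesPath)) NULL
           else if (is.data.frame(nodesPath)) validateNodeTable(nodesPath, conn)
           else readNodeTable(nodesPath, conn)
  w <- connWeights(conn)
  report <- list(
    input = list(n = nNodes(conn),
                 density = sum(w[upper.tri(w)] > 0) /
                   (nNodes(conn) * (nNodes(conn) - 1) / 2),
                 total_weight = sum(w) / 2),
    config = config,
    failed = character(0))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      report$failed <<- c(report$failed, name)
      list(error = paste0("stage '", name, "': ", conditionMessage(e)))
    })
    report[[name]] <<- res
    res
  }

  gd <- tryCatch(graphDistances(conn), error = function(e) {
    report$failed <- c(report$failed, "graph_distances")
    report$graph_distances <- list(error = conditionMessage(e))
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(report, file.path(outDir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    stop("stage 'graph_distances': ", conditionMessage(e))
  })
  report$graph_distances <- list(max = max(gd),
                                 mean_offdiag = mean(gd[upper.tri(gd)]))
  rep_ <- highDimRepresentation(gd)
  npl <- nodalPathLength(gd)

  ambient <- as.matrix(dist(rep_))
  embs <- stage("embeddings", {
    mds <- classicalMDS(ambient, config$dim)
    iso <- isomapEmbed(rep_, config$dim, k = "auto", kStart = config$kStart)
    list(mds = mds, iso = iso,
         summary = list(
           list(method = "MDS", dim = config$dim, k_used = NA,
                residual_variance = residualVariance(ambient, mds)),
           list(method = "Isomap", dim = config$dim, k_used = kUsed(iso),
                residual_variance = residualVariance(
                  isomapGeodesics(rep_, k = kUsed(iso)), iso))))
  })
  if (!is.null(embs$summary)) report$embeddings <- embs$summary

  stage("validation", {
    out <- list()
    if (!is.null(nodes) && all(c("x", "y", "z") %in% names(nodes))) {
      anat <- centralityValidation(as.matrix(nodes[, c("x", "y", "z")]),
                                   npl, "anatomic")
      out$anatomic <- anat[c("rSquared", "slope", "intercept", "rmse")]
    }
    out$MDS <- centralityValidation(embs$mds, npl,
                                    "MDS")[c("rSquared", "slope", "intercept", "rmse")]
    out$Isomap <- centralityValidation(embs$iso, npl,
                                       "Isomap")[c("rSquared", "slope", "intercept", "rmse")]
    out
  })

  stage("center_distance_ranking", {
    rk <- rankByCenterDistance(embs$iso, nodes)
    head(rk, 25)
  })

  if (config$trials > 0) {
    stage("lesion", {
      rnd <- randomRemovalDistribution(conn, config$fraction, config$trials,
                                       seed = config$seed + 1L,
                                       embedDim = config$dim,
                                       kStart = config$kStart)
      res <- list(random = list(trials = rnd@trials, mean = rnd@mean,
                                p5 = rnd@interval[1], p95 = rnd@interval[2]))
      schemes <- config$schemes
      if (!is.null(nodes) && "rich_club" %in% names(nodes) &&
          any(nodes$rich_club)) schemes <- c(schemes, "rich_club")
      for (s in schemes) {
        tr <- targetedRemoval(conn, s, config$fraction, config$dim,
                              nodes = nodes, kStart = config$kStart)
        res[[s]] <- list(removed = tr@removed, fraction = tr@fraction,
                         dbar_raw = tr@dbarRaw,
                         dbar_normalized = tr@dbarNormalized)
      }
      res
    })
  }

  stage("dimension_sweep", {
    sw <- dimensionSweep(rep_, npl, dims = config$sweepDims,
                         kStart = config$kStart)
    list(dims = sw$dims, rmse = sw$rmse, k_used = sw$kUsed)
  })

  report$failed <- as.list(report$failed)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    if (config$dim == 3L && !is.null(nodes) && !is.null(embs$mds)) {
      exportEmbeddingJSON(embs$mds, nodes, conn,
                          file.path(outDir, "embedding_mds.json"))
      exportEmbeddingJSON(embs$iso, nodes, conn,
                          file.path(outDir, "embedding_isomap.json"))
    }
  }
  invisible(report)
}
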