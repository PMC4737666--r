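#' Read a weighted connectome from a plain-text matrix file
#'
#' Reads a square numeric matrix (CSV/TSV/whitespace-delimited) with an
#' optional header row and label column, both auto-detected, and validates it
#' as a [WeightedConnectome-class]. Asymmetries up to \code{1e-9} are
#' symmetrized by averaging with the transpose; larger ones are an error.
#' Diagonal noise up to \code{1e-12} is zeroed.
#'
#' @param path path to a text matrix file.
#' @param delimiter field delimiter; \code{"auto"} (default) tries comma, tab
#'   and whitespace.
#' @return A [WeightedConnectome-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeConnectome(WeightedConnectome(matrix(c(0, 2, 2, 0), 2)), f)
#' readConnectome(f)
#' @export
readConnectome <- function(path, delimiter = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- resolveDelimiter(path, delimiter)
  first <- strsplit(readLines(path, n = 1L), sep %||% "[ \t]+")[[1]]
  first <- first[nzchar(first)]
  hasHeader <- anyNA(suppressWarnings(as.numeric(first)))
  raw <- read.table(path, header = hasHeader,
                    sep = if (is.null(sep)) "" else sep,
                    check.names = FALSE, stringsAsFactors = FALSE)
  labels <- NULL
  # leading label column: first column non-numeric
  if (ncol(raw) > 1 && anyNA(suppressWarnings(as.numeric(raw[[1]])))) {
    labels <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
  } else if (hasHeader) {
    labels <- colnames(raw)
  }
  m <- as.matrix(raw)
  if (!is.numeric(m)) stop("matrix body must be numeric")
  if (nrow(m) != ncol(m))
    stop("matrix must be square, got ", nrow(m), " x ", ncol(m))
  if (any(m < 0)) stop("negative entry in connectivity matrix")
  WeightedConnectome(m, labels)
}

resolveDelimiter <- function(path, delimiter) {
  if (!identical(delimiter, "auto")) return(delimiter)
  line <- readLines(path, n = 1L)
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  NULL   # whitespace
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a weighted connectome as a labelled CSV matrix
#'
#' Writes the weight matrix with a header row and leading label column so
#' that \code{readConnectome(writeConnectome(x))} restores \code{x} exactly
#' (decimal text round-trip via \code{format(..., digits = 17)}).
#'
#' @param x a [WeightedConnectome-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeConnectome <- function(x, path) {
  stopifnot(is(x, "WeightedConnectome"))
  w <- x@weights
  body <- apply(w, c(1, 2), function(v) format(v, digits = 17, scientific = FALSE))
  lines <- c(paste(c("label", x@labels), collapse = ","),
             vapply(seq_len(nrow(w)), function(i)
               paste(c(x@labels[i], body[i, ]), collapse = ","), character(1)))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write to ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Read a node metadata table
#'
#' CSV with columns \code{label} (required) and any of \code{lobe},
#' \code{x}, \code{y}, \code{z}, \code{rich_club}.
#'
#' @param path CSV file path.
#' @param connectome optional [WeightedConnectome-class]; when given the
#'   table must have one row per node.
#' @return a \code{data.frame} with one row per node.
#' @export
readNodeTable <- function(path, connectome = NULL) {
  tab <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                    stringsAsFactors = FALSE)
  validateNodeTable(tab, connectome)
}

#' Write a node metadata table
#' @param tab node table \code{data.frame}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeNodeTable <- function(tab, path) {
  write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

validateNodeTable <- function(tab, connectome = NULL) {
  if (!"label" %in% names(tab)) stop("node table needs a 'label' column")
  tab$label <- as.character(tab$label)
  if (anyDuplicated(tab$label)) stop("node table labels must be unique")
  if ("rich_club" %in% names(tab)) tab$rich_club <- as.logical(tab$rich_club)
  if (!is.null(connectome)) {
    if (nrow(tab) != nNodes(connectome))
      stop("node table has ", nrow(tab), " rows but connectome has ",
           nNodes(connectome), " nodes")
    if (!setequal(tab$label, nodeLabels(connectome)))
      stop("node table labels do not match connectome labels")
    tab <- tab[match(nodeLabels(connectome), tab$label), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Export an embedding for interactive viewers
#'
#' Writes a UTF-8 JSON document with one record per node (label, lobe,
#' embedded xyz, rich-club flag) and an edge list over all nonzero weights.
#' The schema ships with the package at
#' \code{system.file("schema", "embedding-export.schema.json",
#' package = "intrinsicConnectome")}. Edge indices are 0-based.
#'
#' @param embedding a 3-D [ConnectomeEmbedding-class].
#' @param nodes node table \code{data.frame} (see [readNodeTable()]).
#' @param connectome the [WeightedConnectome-class] the embedding came from.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
exportEmbeddingJSON <- function(embedding, nodes, connectome, path) {
  stopifnot(is(embedding, "ConnectomeEmbedding"),
            is(connectome, "WeightedConnectome"))
  n <- nNodes(connectome)
  if (nrow(embedding@coords) != n || nrow(nodes) != n)
    stop("embedding, node table and connectome must have matching n")
  if (ncol(embedding@coords) != 3L)
    stop("embedding must be 3-dimensional for export")
  nodes <- validateNodeTable(nodes, connectome)
  co <- embedding@coords
  nodeRecs <- lapply(seq_len(n), function(i) list(
    label = nodes$label[i],
    lobe = if ("lobe" %in% names(nodes)) nodes$lobe[i] else NA,
    xyz = as.numeric(co[i, ]),
    rich_club = if ("rich_club" %in% names(nodes))
      isTRUE(nodes$rich_club[i]) else FALSE))
  w <- connWeights(connectome)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  edgeRecs <- lapply(seq_len(nrow(idx)), function(e) list(
    i = unname(idx[e, 1] - 1L), j = unname(idx[e, 2] - 1L),
    weight = w[idx[e, 1], idx[e, 2]]))
  doc <- list(format = "intrinsic-connectome-embedding",
              version = 1L,
              method = embedding@method,
              n = n,
              nodes = nodeRecs,
              edges = edgeRecs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Check an exported embedding JSON against the shipped schema
#'
#' Structural validation: required top-level keys, per-node record fields,
#' 3-vector coordinates, 0-based in-range edge indices with positive weights.
#'
#' @param path path to a JSON file written by [exportEmbeddingJSON()].
#' @return \code{TRUE} invisibly, or an error describing the first violation.
#' @export
validateEmbeddingExport <- function(path) {
  doc <- jsonlite::read_json(path)
  need <- c("format", "version", "method", "n", "nodes", "edges")
  missing <- setdiff(need, names(doc))
  if (length(missing)) stop("missing keys: ", paste(missing, collapse = ", "))
  if (!identical(doc$format, "intrinsic-connectome-embedding"))
    stop("unexpected format tag")
  n <- doc$n
  if (length(doc$nodes) != n) stop("node record count must equal n")
  for (rec in doc$nodes) {
    if (!all(c("label", "xyz", "rich_club") %in% names(rec)))
      stop("node record missing label/xyz/rich_club")
    if (length(rec$xyz) != 3L) stop("node xyz must have 3 components")
  }
  for (e in doc$edges) {
    if (!all(c("i", "j", "weight") %in% names(e)))
      stop("edge record missing i/j/weight")
    if (e$i < 0 || e$j < 0 || e$i >= n || e$j >= n)
      stop("edge index out of range")
    if (e$weight <= 0) stop("edge weight must be positive")
  }
  invisible(TRUE)
}
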