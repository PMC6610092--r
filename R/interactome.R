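#' Read a scored gene-gene edge list
#'
#' Loads a STRING-export style TSV of scored undirected interactions
#' (\code{node1}, \code{node2}, \code{combined_score} in 0-999). A header
#' line is auto-detected by a non-numeric score cell. Self-edges are dropped
#' and duplicate undirected pairs are collapsed keeping the maximum score;
#' the counts of dropped rows are reported via a message and stored as
#' attributes. Edge scores on a [0, 1] scale (max score <= 1) are rescaled
#' to 0-999 with a warning.
#'
#' @param path Path to a TSV file with at least three columns.
#' @param scoreColumn Column holding the confidence score: a name (matched
#'   against the header if one is present) or an index. Default 3.
#' @return A \code{data.frame} with columns \code{node_a}, \code{node_b},
#'   \code{score} (integer 0-999), plus attributes \code{n_self_dropped} and
#'   \code{n_duplicates_collapsed}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB\t700", "B\tA\t700", "A\tA\t900", "B\tC\t400"), tf)
#' e <- readEdgeList(tf)
#' nrow(e)   # 2: the A-B pair collapsed, the self-edge dropped
#' @export
readEdgeList <- function(path, scoreColumn = 3) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty edge list file: ", path)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 3L)
    stop("edge list needs >= 3 tab-separated columns, got ",
         length(fields), " in line 1")
  hasHeader <- is.na(suppressWarnings(as.numeric(fields[min(
    if (is.numeric(scoreColumn)) scoreColumn else 3L, length(fields))])))
  df <- read.delim(path, header = hasHeader, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0L) stop("edge list has no data rows: ", path)
  if (ncol(df) < 3L) stop("edge list needs >= 3 columns")
  sc <- if (is.character(scoreColumn)) {
    idx <- match(scoreColumn, colnames(df))
    if (is.na(idx)) stop("score column '", scoreColumn, "' not found")
    idx
  } else as.integer(scoreColumn)
  if (sc > ncol(df)) stop("score column index out of range")
  a <- trimws(df[[1L]]); b <- trimws(df[[2L]])
  score <- suppressWarnings(as.numeric(df[[sc]]))
  bad <- which(is.na(score) | a == "" | b == "")
  if (length(bad)) {
    stop("malformed edge row at line ", bad[1L] + as.integer(hasHeader),
         " of ", path)
  }
  if (max(score) <= 1) {
    warning("edge scores are on a [0,1] scale; rescaling to 0-999")
    score <- score * 999
  }
  score <- as.integer(round(score))
  if (any(score < 0L | score > 999L))
    stop("edge scores outside [0, 999] after rescaling")
  self <- a == b
  nSelf <- sum(self)
  a <- a[!self]; b <- b[!self]; score <- score[!self]
  if (length(a) == 0L) {
    out <- data.frame(node_a = character(0), node_b = character(0),
                      score = integer(0), stringsAsFactors = FALSE)
    attr(out, "n_self_dropped") <- nSelf
    attr(out, "n_duplicates_collapsed") <- 0L
    return(out)
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  o <- order(key, -score)
  keep <- !duplicated(key[o])
  nDup <- sum(!keep)
  out <- data.frame(node_a = lo[o][keep], node_b = hi[o][keep],
                    score = score[o][keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_self_dropped") <- nSelf
  attr(out, "n_duplicates_collapsed") <- nDup
  if (nSelf || nDup)
    cbmMessage("dropped ", nSelf, " self-edges, collapsed ", nDup,
               " duplicate pairs")
  out
}

#' Dichotomize a scored edge list into a binary interactome
#'
#' Keeps edges with confidence score greater than or equal to the threshold
#' and builds the symmetric binary adjacency matrix over the full node set.
#' Nodes whose edges all fall below the threshold stay in the node list as
#' dangling nodes, so the node indexing is identical across thresholds.
#'
#' @param edges Edge data.frame as returned by \code{\link{readEdgeList}}
#'   (columns \code{node_a}, \code{node_b}, \code{score}).
#' @param threshold Integer in [0, 999]; an edge survives iff
#'   \code{score >= threshold}, so threshold 0 keeps every edge.
#' @return An \linkS4class{Interactome} with the adjacency filled and an
#'   empty transition matrix (see \code{\link{buildTransitionMatrix}}).
#' @export
dichotomize <- function(edges, threshold) {
  stopifnot(is.data.frame(edges),
            all(c("node_a", "node_b", "score") %in% colnames(edges)))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 999)
    stop("threshold must be a single value in [0, 999]")
  nodeIds <- sort(unique(c(edges$node_a, edges$node_b)))
  if (length(nodeIds) == 0L) stop("edge list contains no nodes")
  keep <- edges$score >= threshold
  i <- match(edges$node_a[keep], nodeIds)
  j <- match(edges$node_b[keep], nodeIds)
  n <- length(nodeIds)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n, n), use.last.ij = TRUE,
                              dimnames = list(nodeIds, nodeIds))
  adj <- methods::as(adj, "generalMatrix")
  new("Interactome", nodes = nodeIds, adjacency = adj,
      transition = Matrix::Matrix(0, 0, 0), threshold = as.integer(threshold))
}

#' Build the row-stochastic transition matrix of the random walk
#'
#' The probability of stepping from node a to a neighbour b is 1 divided by
#' the degree of a, so W is the row-normalized adjacency. Dangling nodes
#' receive a self-loop (W[a, a] = 1) so every row sums to exactly 1 and
#' probability mass is conserved during propagation.
#'
#' @param graph An \linkS4class{Interactome} with adjacency built.
#' @return The same object with the \code{transition} slot filled.
#' @export
buildTransitionMatrix <- function(graph) {
  stopifnot(is(graph, "Interactome"))
  adj <- graph@adjacency
  deg <- Matrix::rowSums(adj)
  dangling <- which(deg == 0)
  n <- length(graph@nodes)
  W <- Matrix::Diagonal(x = ifelse(deg > 0, 1 / pmax(deg, 1), 0)) %*% adj
  if (length(dangling)) {
    W <- W + Matrix::sparseMatrix(i = dangling, j = dangling, x = 1,
                                  dims = c(n, n))
  }
  W <- methods::as(W, "CsparseMatrix")
  dimnames(W) <- list(graph@nodes, graph@nodes)
  graph@transition <- W
  methods::validObject(graph)
  graph
}

#' Build a walkable interactome in one call
#'
#' Convenience wrapper: \code{\link{dichotomize}} followed by
#' \code{\link{buildTransitionMatrix}}.
#'
#' @inheritParams dichotomize
#' @return An \linkS4class{Interactome} with adjacency and transition built.
#' @export
buildInteractome <- function(edges, threshold) {
  buildTransitionMatrix(dichotomize(edges, threshold))
}

#' Summarize an interactome
#'
#' @param graph An \linkS4class{Interactome}.
#' @return A list with \code{nodes}, \code{edges}, \code{dangling} and
#'   \code{threshold}, suitable for JSON export.
#' @export
graphSummary <- function(graph) {
  stopifnot(is(graph, "Interactome"))
  deg <- Matrix::rowSums(graph@adjacency)
  list(nodes = length(graph@nodes),
       edges = as.integer(sum(graph@adjacency) / 2),
       dangling = as.integer(sum(deg == 0)),
       threshold = graph@threshold)
}

#' @rdname Interactome-accessors
#' @export
setMethod("nodes", "Interactome", function(x) x@nodes)

#' @rdname Interactome-accessors
#' @export
setMethod("adjacencyMatrix", "Interactome", function(x) x@adjacency)

#' @rdname Interactome-accessors
#' @export
setMethod("transitionMatrix", "Interactome", function(x) {
  if (any(dim(x@transition) == 0))
    stop("transition matrix not built; call buildTransitionMatrix()")
  x@transition
})

#' @rdname Interactome-accessors
#' @export
setMethod("thresholdUsed", "Interactome", function(x) x@threshold)

#' @rdname Interactome-accessors
#' @export
setMethod("edgeCount", "Interactome",
          function(x) as.integer(sum(x@adjacency) / 2))

#' @rdname Interactome-accessors
#' @export
setMethod("show", "Interactome", function(object) {
  s <- graphSummary(object)
  cat("Interactome with", s$nodes, "nodes and", s$edges,
      "edges (threshold", s$threshold, ";", s$dangling, "dangling)\n")
})
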