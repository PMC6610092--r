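#' Accessors for Interactome objects
#'
#' @param x,object An \linkS4class{Interactome}.
#' @return \code{nodes}: character vector of gene ids. \code{adjacencyMatrix},
#'   \code{transitionMatrix}: sparse matrices. \code{thresholdUsed}: integer.
#'   \code{edgeCount}: number of undirected edges surviving dichotomization.
#' @examples
#' edges <- data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
#'                     score = c(900L, 700L))
#' g <- buildInteractome(edges, threshold = 400)
#' nodes(g)
#' edgeCount(g)
#' @name Interactome-accessors
#' @aliases nodes adjacencyMatrix transitionMatrix thresholdUsed edgeCount
NULL

#' @rdname Interactome-accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname Interactome-accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname Interactome-accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' @rdname Interactome-accessors
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))

#' @rdname Interactome-accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' Predict calibrated anti-cancer likeness
#'
#' Applies a trained classifier to one profile or a matrix of profiles
#' (compounds in rows, genes in columns, in the classifier's gene order) and
#' returns the calibrated probability that each compound is
#' anti-cancer-like.
#'
#' @param object A trained \linkS4class{ACLClassifier}.
#' @param X Numeric vector (one profile) or matrix (compounds x genes).
#' @return Numeric vector of probabilities in [0, 1].
#' @export
setGeneric("predictACL", function(object, X) standardGeneric("predictACL"))

#' Raw decision values of a classifier
#'
#' @param object A trained \linkS4class{ACLClassifier}.
#' @param X Profile vector or matrix (compounds x genes).
#' @return For SVM, the signed margin; for MMC, the projected coordinate(s)
#'   (a matrix with k columns).
#' @export
setGeneric("decisionValues", function(object, X)
  standardGeneric("decisionValues"))

#' Extract the compounds-by-genes profile matrix
#'
#' @param x A \linkS4class{ProfileSet}.
#' @return Dense numeric matrix with compounds in rows and genes in columns
#'   (the transpose of the stored assay).
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))
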