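#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Interactome graph
#'
#' An undirected protein-protein interaction graph after dichotomization of
#' edge confidence scores at a fixed threshold. Holds the ordered node list
#' (lexicographic over gene identifiers, fixed once per graph so that
#' matrices are reproducible), the symmetric binary adjacency matrix and,
#' once built, the row-stochastic transition matrix of the random walk.
#' Dangling nodes (zero surviving edges) are retained and receive a
#' self-loop in the transition matrix so that probability mass is conserved
#' and node indexing is stable across thresholds.
#'
#' @slot nodes Character vector of gene identifiers, sorted.
#' @slot adjacency Sparse symmetric binary adjacency matrix.
#' @slot transition Row-stochastic transition matrix W (possibly empty
#'   until \code{\link{buildTransitionMatrix}} is called).
#' @slot threshold Integer confidence threshold used for dichotomization.
#'
#' @seealso \code{\link{dichotomize}}, \code{\link{buildTransitionMatrix}},
#'   \code{\link{buildInteractome}}
#' @export
setClass("Interactome",
  representation(nodes = "character", adjacency = "Matrix",
                 transition = "Matrix", threshold = "integer"))

setValidity("Interactome", function(object) {
  n <- length(object@nodes)
  msg <- character(0)
  if (n == 0L) msg <- c(msg, "node list is empty")
  if (any(object@nodes == "")) msg <- c(msg, "empty gene id in node list")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicated gene ids")
  if (!all(dim(object@adjacency) == c(n, n)))
    msg <- c(msg, "adjacency dimensions do not match node count")
  if (!Matrix::isSymmetric(object@adjacency, tol = 0))
    msg <- c(msg, "adjacency matrix is not symmetric")
  if (any(Matrix::diag(object@adjacency) != 0))
    msg <- c(msg, "adjacency has nonzero diagonal")
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold < 0L || object@threshold > 999L)
    msg <- c(msg, "threshold must be a single integer in [0, 999]")
  if (all(dim(object@transition) > 0)) {
    if (!all(dim(object@transition) == c(n, n)))
      msg <- c(msg, "transition dimensions do not match node count")
    rs <- Matrix::rowSums(object@transition)
    if (max(abs(rs - 1)) > 1e-12)
      msg <- c(msg, "transition matrix rows do not sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Propagated profile container
#'
#' A \linkS4class{SummarizedExperiment} holding genome-wide propagated
#' profiles: rows are genes (the interactome node order), columns are
#' compounds. The single assay \code{"profiles"} stores the converged
#' random-walk probability distribution of each compound; \code{colData}
#' carries per-compound labels, entry-point counts and convergence
#' diagnostics.
#'
#' @seealso \code{\link{propagateProfiles}}, \code{\link{profileMatrix}}
#' @export
setClass("ProfileSet", contains = "SummarizedExperiment")

#' Classifier classes
#'
#' \code{ACLClassifier} is the virtual parent of trained classifiers that
#' emit a calibrated anti-cancer likeness (ACL) probability for a propagated
#' profile. \code{MMCClassifier} holds a maximum margin criterion projection
#' (top eigenvectors of the between-class minus within-class scatter
#' difference) plus a logistic calibration on the projected coordinates.
#' \code{SVMClassifier} holds the weight vector and bias of a class-weighted
#' soft-margin linear support vector machine plus a Platt-style logistic
#' calibration on the decision values.
#'
#' @slot geneIds Character vector naming the feature space (gene order).
#' @slot calibration Numeric coefficients (intercept then slopes) of the
#'   logistic probability calibration.
#' @slot logTransformed Logical; whether the model was trained on
#'   log-transformed profiles (recorded so prediction can match).
#'
#' @aliases MMCClassifier-class SVMClassifier-class
#' @export
setClass("ACLClassifier", representation("VIRTUAL",
  geneIds = "character", calibration = "numeric",
  logTransformed = "logical"))

#' @rdname ACLClassifier-class
#' @slot projection Matrix (genes x k) of orthonormal eigenvectors of
#'   (Sb - Sw), eigenvalues in descending order.
#' @slot eigenvalues Numeric, descending.
#' @slot classMeans Matrix (2 x genes): mean profile of the negative (row 1)
#'   and positive (row 2) class.
#' @slot k Integer, retained dimensions.
#' @export
setClass("MMCClassifier", contains = "ACLClassifier",
  representation(projection = "matrix", eigenvalues = "numeric",
                 classMeans = "matrix", k = "integer"))

setValidity("MMCClassifier", function(object) {
  msg <- character(0)
  k <- object@k
  if (ncol(object@projection) != k) msg <- c(msg, "projection has wrong k")
  G <- crossprod(object@projection)
  if (max(abs(G - diag(k))) > 1e-8)
    msg <- c(msg, "projection columns are not orthonormal")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues not in descending order")
  if (length(msg)) msg else TRUE
})

#' @rdname ACLClassifier-class
#' @slot weights Numeric weight vector over genes (oriented so larger
#'   decision values mean more anti-cancer-like).
#' @slot bias Numeric intercept of the decision function.
#' @slot cost Numeric soft-margin cost C used for training.
#' @export
setClass("SVMClassifier", contains = "ACLClassifier",
  representation(weights = "numeric", bias = "numeric", cost = "numeric"))
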