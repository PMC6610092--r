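#' @useDynLib cbmNet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Random-walk parameters
#'
#' @param c Restart probability in (0, 1]. c = 1 means no propagation beyond
#'   the entry points; c close to 0 lets the walker reach the furthest
#'   connected nodes, giving a smoother genome-wide profile.
#' @param tol Convergence tolerance on the L1 change between successive
#'   iterates; default 1e-6.
#' @param maxIter Iteration cap; default 10000.
#' @return A validated \code{PropagationParams} list.
#' @export
propagationParams <- function(c = 0.02, tol = 1e-6, maxIter = 10000) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0 || c > 1)
    stop("restart probability c must be in (0, 1]")
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive")
  if (!is.numeric(maxIter) || maxIter < 1) stop("maxIter must be >= 1")
  structure(list(c = c, tol = tol, maxIter = as.integer(maxIter)),
            class = "PropagationParams")
}

#' Canonical restart-probability grid
#'
#' The 14-value grid of restart probabilities explored during model
#' selection.
#'
#' @return Numeric vector.
#' @export
defaultCValues <- function() {
  c(0.0001, 0.001, 0.002, 0.004, 0.01, 0.015, 0.02, 0.03, 0.035, 0.04,
    0.05, 0.076, 0.1, 0.2)
}

newProfile <- function(values, nodes, iterations, converged, params,
                       diffTrace = numeric(0), maxSumDev = NA_real_) {
  values <- as.numeric(values)
  names(values) <- nodes
  if (min(values) < -1e-10)
    stop("propagated profile has negative entries beyond tolerance")
  values[values < 0] <- 0
  structure(list(values = values, iterations = as.integer(iterations),
                 converged = converged, params = params,
                 diffTrace = diffTrace, maxSumDeviation = maxSumDev),
            class = "PropagatedProfile")
}

#' @export
print.PropagatedProfile <- function(x, ...) {
  cat("PropagatedProfile over", length(x$values), "genes; c =", x$params$c,
      "; iterations =", x$iterations,
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

#' Propagate a seed vector by random walk with restarts
#'
#' Iterates \code{p_i = p_{i-1} W (1 - c) + c p_0} from the seed until the
#' L1 change between successive iterates drops below \code{params$tol} or
#' \code{params$maxIter} is reached. Because W is row-stochastic, every
#' iterate is a probability distribution; the per-iterate L1 changes are
#' returned when \code{keepTrace = TRUE} (they contract geometrically at
#' rate 1 - c).
#'
#' @param seed Seed vector from \code{\link{buildSeedVector}} (same node
#'   ordering as the graph).
#' @param graph An \linkS4class{Interactome} with transition built.
#' @param params \code{\link{propagationParams}}.
#' @param keepTrace Record the L1 change at every iteration.
#' @return A \code{PropagatedProfile}: list with \code{values} (named,
#'   sums to 1), \code{iterations}, \code{converged}, \code{params},
#'   \code{diffTrace} and \code{maxSumDeviation} (largest observed
#'   deviation of an iterate's total mass from 1).
#' @export
propagate <- function(seed, graph, params = propagationParams(),
                      keepTrace = FALSE) {
  stopifnot(is(graph, "Interactome"), inherits(params, "PropagationParams"))
  W <- transitionMatrix(graph)
  if (length(seed) != nrow(W))
    stop("seed length does not match graph node count")
  res <- cpp_propagate(W, as.numeric(seed), params$c, params$tol,
                       params$maxIter, keepTrace)
  if (!res$converged)
    warning("propagation did not converge within ", params$maxIter,
            " iterations (c = ", params$c, ")")
  newProfile(res$values, graph@nodes, res$iterations, res$converged, params,
             diffTrace = res$diff_trace, maxSumDev = res$max_sum_dev)
}

#' Closed-form stationary profile of the restarted walk
#'
#' The fixed point of the iteration is \code{p = c p0 (I - (1-c) W)^{-1}},
#' computed here by one sparse direct solve. Available for graphs up to
#' 5000 nodes (above that the memory cost of the factorization is not worth
#' it and the iterative walker should be used).
#'
#' @param seed Seed vector (same node ordering as the graph).
#' @param graph An \linkS4class{Interactome} with transition built.
#' @param c Restart probability; must be > 0 for the fixed point to be
#'   unique.
#' @return A \code{PropagatedProfile} with \code{iterations = 0} and
#'   \code{converged = TRUE}.
#' @export
propagateClosedForm <- function(seed, graph, c) {
  stopifnot(is(graph, "Interactome"))
  if (c <= 0) stop("closed form requires c > 0 (unique fixed point)")
  if (c > 1) stop("restart probability c must be in (0, 1]")
  W <- transitionMatrix(graph)
  n <- nrow(W)
  if (length(seed) != n) stop("seed length does not match graph node count")
  if (n > 5000)
    stop("closed-form solver disabled above 5000 nodes; use propagate()")
  if (c == 1)
    return(newProfile(as.numeric(seed), graph@nodes, 0L, TRUE,
                      propagationParams(c = 1), maxSumDev = 0))
  A <- Matrix::Diagonal(n) - (1 - c) * W
  x <- Matrix::solve(Matrix::t(A), matrix(c * as.numeric(seed), ncol = 1))
  newProfile(as.numeric(x), graph@nodes, 0L, TRUE,
             propagationParams(c = c),
             maxSumDev = abs(sum(as.numeric(x)) - 1))
}

#' Propagate a batch of seed vectors
#'
#' Order-preserving batch wrapper around \code{\link{propagate}}. Per-seed
#' errors are caught and returned in place of the profile, so one degenerate
#' compound does not abort the batch.
#'
#' @param seeds List of seed vectors on the same graph.
#' @param graph An \linkS4class{Interactome}.
#' @param params \code{\link{propagationParams}}.
#' @return List of \code{PropagatedProfile} objects (or \code{simpleError}
#'   entries for failed seeds), same order and names as \code{seeds}.
#' @export
propagateBatch <- function(seeds, graph, params = propagationParams()) {
  stopifnot(is.list(seeds))
  lapply(seeds, function(s)
    tryCatch(propagate(s, graph, params), error = function(e) e))
}

#' Propagate all compounds of a target table into a ProfileSet
#'
#' Builds the sparse seed matrix for every usable compound and converges the
#' restarted walk for each, either by one sparse closed-form solve per batch
#' (default, exact) or by the compiled iterative walker. Returns the
#' genome-wide profiles as a \linkS4class{ProfileSet}.
#'
#' @param targets data.frame (\code{compound_id}, \code{gene_id},
#'   \code{score}) after any confidence filtering.
#' @param graph An \linkS4class{Interactome} with transition built.
#' @param c Restart probability.
#' @param method \code{"closed_form"} (default) or \code{"iterative"}.
#' @param params \code{\link{propagationParams}} used by the iterative
#'   method (its \code{c} is overridden by the \code{c} argument).
#' @param labels Optional data.frame (\code{compound_id}, \code{label})
#'   copied into \code{colData}.
#' @return A \linkS4class{ProfileSet} (genes x compounds).
#' @export
propagateProfiles <- function(targets, graph, c,
                              method = c("closed_form", "iterative"),
                              params = propagationParams(),
                              labels = NULL) {
  method <- match.arg(method)
  stopifnot(is(graph, "Interactome"))
  S <- buildSeedMatrix(targets, graph)
  W <- transitionMatrix(graph)
  n <- nrow(W)
  m <- nrow(S)
  if (method == "closed_form" && n <= 5000 && c > 0) {
    if (c == 1) {
      P <- as.matrix(S)
    } else {
      A <- Matrix::Diagonal(n) - (1 - c) * W
      B <- as.matrix(Matrix::t(S)) * c
      P <- t(as.matrix(Matrix::solve(Matrix::t(A), B)))
    }
    iters <- rep(0L, m); conv <- rep(TRUE, m)
  } else {
    pp <- propagationParams(c = c, tol = params$tol, maxIter = params$maxIter)
    res <- cpp_propagate_batch(W, as.matrix(S), pp$c, pp$tol, pp$maxIter)
    P <- res$values
    iters <- res$iterations; conv <- as.logical(res$converged)
    if (!all(conv))
      warning(sum(!conv), " compound(s) did not converge at c = ", c)
  }
  P[P < 0 & P > -1e-10] <- 0
  dimnames(P) <- list(rownames(S), graph@nodes)
  cd <- S4Vectors::DataFrame(compound_id = rownames(S),
                             n_entry = as.integer(Matrix::rowSums(S > 0)),
                             iterations = iters, converged = conv,
                             row.names = rownames(S))
  if (!is.null(labels))
    cd$label <- labels$label[match(rownames(S), labels$compound_id)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(profiles = t(P)),
    rowData = S4Vectors::DataFrame(gene_id = graph@nodes,
                                   row.names = graph@nodes),
    colData = cd,
    metadata = list(c = c, threshold = graph@threshold, method = method,
                    excluded = attr(S, "excluded")))
  methods::new("ProfileSet", se)
}

#' @rdname profileMatrix
#' @export
setMethod("profileMatrix", "ProfileSet", function(x)
  t(SummarizedExperiment::assay(x, "profiles")))

#' @describeIn profileMatrix Compact display of a ProfileSet.
#' @param object A \linkS4class{ProfileSet}.
#' @export
setMethod("show", "ProfileSet", function(object) {
  cat("ProfileSet:", ncol(object), "compounds x", nrow(object),
      "genes (c =", S4Vectors::metadata(object)$c, ")\n")
})
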