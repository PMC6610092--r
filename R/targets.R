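#' Read a scored compound-gene interaction table
#'
#' STITCH-style TSV with columns compound id (or InChIKey), gene id and an
#' interaction confidence score in 0-999. Header auto-detected by a
#' non-numeric score cell. Compound identifiers are matched downstream by
#' exact full-string equality (no InChIKey connectivity-layer fallback).
#'
#' @param path Path to the TSV.
#' @return data.frame with columns \code{compound_id}, \code{gene_id},
#'   \code{score}.
#' @export
readCompoundTargets <- function(path) {
  if (!file.exists(path)) stop("compound-target file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(first) < 3L) stop("compound-target table needs >= 3 columns")
  hasHeader <- is.na(suppressWarnings(as.numeric(first[3L])))
  df <- read.delim(path, header = hasHeader, sep = "\t",
                   stringsAsFactors = FALSE, colClasses = "character")
  out <- data.frame(compound_id = trimws(df[[1L]]),
                    gene_id = trimws(df[[2L]]),
                    score = suppressWarnings(as.numeric(df[[3L]])),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$score) | out$compound_id == "" | out$gene_id == "")
  if (length(bad))
    stop("malformed compound-target row at line ",
         bad[1L] + as.integer(hasHeader), " of ", path)
  if (any(out$score < 0 | out$score > 999))
    stop("target scores outside [0, 999]")
  out$score <- as.integer(round(out$score))
  out
}

#' Read a compound label table
#'
#' @param path TSV with columns compound id and label; labels must be one of
#'   \code{positive}, \code{negative}, \code{unlabeled}.
#' @return data.frame with columns \code{compound_id}, \code{label}.
#' @export
readCompoundLabels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("compound_id", "label") %in% colnames(df))) {
    df <- read.delim(path, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE, colClasses = "character")
    colnames(df)[1:2] <- c("compound_id", "label")
  }
  ok <- df$label %in% c("positive", "negative", "unlabeled")
  if (!all(ok))
    stop("unknown label(s): ", paste(unique(df$label[!ok]), collapse = ", "))
  df[, c("compound_id", "label")]
}

#' Filter compound targets by interaction confidence
#'
#' Retains compound-gene interactions with score greater than or equal to
#' the threshold (threshold 0 is the identity). Compounds losing all their
#' targets simply disappear from the table; seed construction reports them
#' as unusable.
#'
#' @param targets data.frame (\code{compound_id}, \code{gene_id},
#'   \code{score}).
#' @param threshold Integer in [0, 999]. The canonical compound-gene grid is
#'   \code{c(0, 100, 200, 325, 400, 500, 600, 700)}.
#' @return Filtered data.frame of the same shape.
#' @export
filterTargets <- function(targets, threshold) {
  stopifnot(is.data.frame(targets),
            all(c("compound_id", "gene_id", "score") %in% colnames(targets)))
  if (threshold < 0 || threshold > 999)
    stop("threshold must be in [0, 999]")
  out <- targets[targets$score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the seed (restart) vector of a compound
#'
#' Every gene the compound targets is an entry point of the random walk; the
#' restart distribution puts mass 1/k on each of the k entry points that map
#' onto the interactome node list and 0 elsewhere.
#'
#' @param geneIds Character vector of target gene ids for one compound.
#' @param graph An \linkS4class{Interactome}.
#' @return Named numeric vector over the graph nodes summing to 1, with the
#'   index set of entry points as attribute \code{support}.
#' @export
buildSeedVector <- function(geneIds, graph) {
  stopifnot(is(graph, "Interactome"))
  idx <- sort(unique(match(geneIds, graph@nodes)))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L)
    stop("no entry points: none of the targets map onto the interactome")
  p0 <- numeric(length(graph@nodes))
  names(p0) <- graph@nodes
  p0[idx] <- 1 / length(idx)
  attr(p0, "support") <- idx
  p0
}

#' Build a sparse seed matrix for a batch of compounds
#'
#' @param targets data.frame (\code{compound_id}, \code{gene_id},
#'   \code{score}); scores are ignored here (seeds are unweighted).
#' @param graph An \linkS4class{Interactome}.
#' @return Sparse matrix (compounds x genes), each row a seed vector.
#'   Compounds with no mappable target are dropped with a warning and listed
#'   in attribute \code{excluded}.
#' @export
buildSeedMatrix <- function(targets, graph) {
  stopifnot(is(graph, "Interactome"))
  gi <- match(targets$gene_id, graph@nodes)
  mapped <- !is.na(gi)
  tt <- unique(data.frame(compound = targets$compound_id[mapped],
                          gene = gi[mapped], stringsAsFactors = FALSE))
  compoundsAll <- unique(targets$compound_id)
  compounds <- unique(tt$compound)
  excluded <- setdiff(compoundsAll, compounds)
  if (length(excluded))
    warning(length(excluded),
            " compound(s) had no entry points and were excluded")
  if (length(compounds) == 0L)
    stop("no entry points: no compound has a mappable target")
  ci <- match(tt$compound, compounds)
  k <- tabulate(ci, nbins = length(compounds))
  S <- Matrix::sparseMatrix(i = ci, j = tt$gene, x = 1 / k[ci],
                            dims = c(length(compounds), length(graph@nodes)),
                            dimnames = list(compounds, graph@nodes))
  attr(S, "excluded") <- excluded
  S
}

#' Log-transform a propagated profile
#'
#' Returns \code{log(x + epsilon)} elementwise (natural log). The transform
#' is monotone and order-preserving; it damps the very large values of
#' isolated non-propagating genes relative to the rest of the profile.
#'
#' @param x Nonnegative numeric vector or matrix.
#' @param epsilon Small positive offset guarding zeros; default 1e-12.
#' @return Transformed object of the same shape.
#' @export
logTransform <- function(x, epsilon = 1e-12) {
  if (any(x < 0)) stop("log transform requires a nonnegative profile")
  if (epsilon <= 0) stop("epsilon must be positive")
  log(x + epsilon)
}
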