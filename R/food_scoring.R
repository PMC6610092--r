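#' Read a compound-to-food membership table
#'
#' FooDB-style TSV with columns \code{compound_id}, \code{food_id},
#' \code{food_name} (third column optional; defaults to the food id).
#' Duplicate (compound, food) pairs are collapsed.
#'
#' @param path Path to the TSV (header required).
#' @return data.frame with columns \code{compound_id}, \code{food_id},
#'   \code{food_name}, \code{excluded} (all FALSE), \code{exclusion_reason}.
#' @export
readFoodMap <- function(path) {
  if (!file.exists(path)) stop("food map file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("compound_id", "food_id") %in% colnames(df)))
    stop("food map needs columns compound_id and food_id")
  if (!"food_name" %in% colnames(df)) df$food_name <- df$food_id
  df <- df[!duplicated(df[, c("compound_id", "food_id")]), ]
  df$excluded <- FALSE
  df$exclusion_reason <- ""
  rownames(df) <- NULL
  df[, c("compound_id", "food_id", "food_name", "excluded",
         "exclusion_reason")]
}

#' Flag curated exclusions in a food map
#'
#' Marks compounds that must not count as cancer-beating molecules: known
#' toxic or cancer-promoting compounds (by id) and compounds belonging to
#' normal cellular metabolism (by chemical class, e.g. the nucleosides,
#' nucleotides and analogues superclass that contains dCTP). Flagged rows
#' are retained in the table but excluded from CBM counting; the curation
#' lists are plain-text inputs so the manual step is reproducible and
#' diffable.
#'
#' @param map Food map data.frame (see \code{\link{readFoodMap}}).
#' @param toxinIds Character vector of compound ids to flag as toxic.
#' @param metaboliteClasses Character vector of chemical classes to flag as
#'   normal metabolites.
#' @param compoundClasses Optional data.frame (\code{compound_id},
#'   \code{class}) giving each compound's chemical class annotation; needed
#'   only when \code{metaboliteClasses} is non-empty.
#' @return The map with \code{excluded} and \code{exclusion_reason} updated.
#' @export
flagExclusions <- function(map, toxinIds = character(0),
                           metaboliteClasses = character(0),
                           compoundClasses = NULL) {
  stopifnot(is.data.frame(map))
  if (!"excluded" %in% colnames(map)) {
    map$excluded <- FALSE
    map$exclusion_reason <- ""
  }
  tox <- map$compound_id %in% toxinIds
  map$excluded[tox] <- TRUE
  map$exclusion_reason[tox] <- "toxic"
  if (length(metaboliteClasses)) {
    if (is.null(compoundClasses))
      stop("metaboliteClasses given but compoundClasses annotation missing")
    cls <- compoundClasses$class[match(map$compound_id,
                                       compoundClasses$compound_id)]
    met <- !is.na(cls) & cls %in% metaboliteClasses & !map$excluded
    map$excluded[met] <- TRUE
    map$exclusion_reason[met] <- "normal_metabolite"
  }
  map
}

#' Count cancer-beating molecules per food
#'
#' A compound is a CBM when its ensemble anti-cancer likeness is strictly
#' above the threshold (canonical cutoff 0.7) and it is not excluded by
#' curation. Counts are of distinct compounds per food; foods whose
#' compounds all fall below the cutoff keep a zero count.
#'
#' @param acl Named numeric vector of ACL per compound, or the data.frame
#'   from \code{\link{ensemblePredictACL}}.
#' @param map Food map data.frame (possibly after
#'   \code{\link{flagExclusions}}).
#' @param threshold ACL cutoff in [0, 1]; default 0.7, comparison strict.
#' @return data.frame (\code{food_id}, \code{food_name}, \code{cbm_count}),
#'   sorted by count descending.
#' @export
countCBMs <- function(acl, map, threshold = 0.7) {
  if (is.data.frame(acl)) {
    v <- acl$acl; names(v) <- acl$compound_id; acl <- v
  }
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  a <- acl[map$compound_id]
  isCBM <- !map$excluded & !is.na(a) & a > threshold
  foods <- unique(map[, c("food_id", "food_name")])
  cnt <- vapply(foods$food_id, function(f)
    length(unique(map$compound_id[isCBM & map$food_id == f])), integer(1))
  out <- data.frame(food_id = foods$food_id, food_name = foods$food_name,
                    cbm_count = cnt, stringsAsFactors = FALSE)
  out <- out[order(-out$cbm_count, out$food_id), ]
  rownames(out) <- NULL
  out
}

#' Extract the CBM table
#'
#' @param acl ACL data.frame from \code{\link{ensemblePredictACL}}.
#' @param map Food map data.frame.
#' @param threshold ACL cutoff (strict); default 0.7.
#' @return data.frame of non-excluded compounds with ACL above the cutoff:
#'   \code{compound_id}, \code{acl}, \code{foods} (comma-separated food
#'   names).
#' @export
cbmTable <- function(acl, map, threshold = 0.7) {
  keep <- !is.na(acl$acl) & acl$acl > threshold
  cbms <- acl[keep, , drop = FALSE]
  excludedIds <- unique(map$compound_id[map$excluded])
  cbms <- cbms[!(cbms$compound_id %in% excludedIds), , drop = FALSE]
  foods <- vapply(cbms$compound_id, function(cp)
    paste(sort(unique(map$food_name[map$compound_id == cp & !map$excluded])),
          collapse = ","), character(1))
  out <- data.frame(compound_id = cbms$compound_id, acl = cbms$acl,
                    foods = foods, stringsAsFactors = FALSE)
  out <- out[order(-out$acl, out$compound_id), ]
  rownames(out) <- NULL
  out
}

#' Food-by-food correlation of CBM incidence profiles
#'
#' Builds the binary food x CBM incidence matrix (which CBMs occur in which
#' food) and the pairwise Pearson correlation (phi coefficient) between the
#' food rows, the quantity that links foods with molecular commonality in
#' the food map. Foods without any CBM are excluded from the matrix (with a
#' message). Incidence is binary by default; set \code{weighted = TRUE} to
#' weight by ACL instead.
#'
#' @param map Food map data.frame.
#' @param acl ACL vector or data.frame as in \code{\link{countCBMs}}.
#' @param threshold ACL cutoff (strict); default 0.7.
#' @param corCutoff Optional correlation cutoff for the emitted edge list
#'   (edges with correlation >= cutoff); no canonical default, NULL emits
#'   all pairs.
#' @param weighted Use ACL-weighted incidence instead of binary.
#' @return List with \code{correlation} (symmetric matrix, unit diagonal),
#'   \code{incidence} (food x compound), and \code{edges} (data.frame
#'   \code{food_a}, \code{food_b}, \code{correlation}).
#' @export
foodCorrelationMap <- function(map, acl, threshold = 0.7, corCutoff = NULL,
                               weighted = FALSE) {
  if (is.data.frame(acl)) {
    v <- acl$acl; names(v) <- acl$compound_id; acl <- v
  }
  a <- acl[map$compound_id]
  isCBM <- !map$excluded & !is.na(a) & a > threshold
  cbms <- sort(unique(map$compound_id[isCBM]))
  if (length(cbms) == 0L) stop("no CBMs at threshold ", threshold)
  foods <- sort(unique(map$food_id))
  inc <- matrix(0, nrow = length(foods), ncol = length(cbms),
                dimnames = list(foods, cbms))
  sel <- map[isCBM & map$compound_id %in% cbms, , drop = FALSE]
  inc[cbind(match(sel$food_id, foods), match(sel$compound_id, cbms))] <-
    if (weighted) acl[sel$compound_id] else 1
  zero <- rowSums(inc) == 0
  if (any(zero)) {
    cbmMessage(sum(zero), " food(s) with zero CBMs excluded from the ",
               "correlation map: ", paste(foods[zero], collapse = ", "))
    inc <- inc[!zero, , drop = FALSE]
  }
  if (nrow(inc) < 2L)
    stop("need at least 2 foods with at least 1 CBM")
  cm <- suppressWarnings(cor(t(inc)))
  diag(cm) <- 1
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  edges <- data.frame(food_a = rownames(cm)[ut[, 1]],
                      food_b = rownames(cm)[ut[, 2]],
                      correlation = cm[ut], stringsAsFactors = FALSE)
  edges <- edges[!is.na(edges$correlation), , drop = FALSE]
  if (!is.null(corCutoff))
    edges <- edges[edges$correlation >= corCutoff, , drop = FALSE]
  rownames(edges) <- NULL
  list(correlation = cm, incidence = inc, edges = edges)
}

#' Write the food map as node/edge tables or GraphML
#'
#' @param counts Per-food CBM counts from \code{\link{countCBMs}}.
#' @param corMap Result of \code{\link{foodCorrelationMap}}.
#' @param dir Output directory (created if needed).
#' @param graphml Also write \code{food_map.graphml} (requires the igraph
#'   package).
#' @return Invisibly, the paths written.
#' @export
writeFoodMapGraph <- function(counts, corMap, dir, graphml = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodePath <- file.path(dir, "food_nodes.tsv")
  edgePath <- file.path(dir, "food_edges.tsv")
  write.table(counts, nodePath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(corMap$edges, edgePath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(nodePath, edgePath)
  if (graphml) {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop("GraphML export requires the igraph package")
    g <- igraph::graph_from_data_frame(
      corMap$edges, directed = FALSE,
      vertices = data.frame(name = counts$food_id,
                            cbm_count = counts$cbm_count))
    gp <- file.path(dir, "food_map.graphml")
    igraph::write_graph(g, gp, format = "graphml")
    paths <- c(paths, gp)
  }
  invisible(paths)
}
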