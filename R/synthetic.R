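#' Specification of a synthetic benchmark dataset
#'
#' Describes a fully synthetic interactome with a planted "disease module"
#' and compound cohorts with known ground truth, emulating the structure of
#' the real inputs: a sparse undirected scored interactome, positive
#' compounds whose 20-30 targets are enriched in the module, negative
#' compounds with diffuse targets, and a 1:9 positive:negative ratio.
#' Module edges draw scores from a high-score distribution and background
#' edges from a lower, overlapping one, so the gene-gene threshold grid has
#' a detectable optimum; target scores are uniform so the compound-gene
#' thresholds bite.
#'
#' @param nGenes Number of genes; default 500.
#' @param moduleSize Planted module size; default 40.
#' @param moduleDensity,backgroundDensity Edge probabilities inside the
#'   module and elsewhere; defaults 0.3 and 0.01.
#' @param nPositive,nNegative Cohort sizes; defaults 100 and 900 (1:9).
#' @param targetsPerCompound Inclusive range of targets per compound;
#'   default c(20, 30).
#' @param moduleTargetFraction Fraction of a positive compound's targets
#'   drawn from the module; default 0.7.
#' @param edgeScoreModule,edgeScoreBackground Mean and sd of the (clipped,
#'   rounded) normal score distributions for module and background edges.
#' @param targetScoreRange Inclusive integer range of compound-target
#'   scores; default c(100, 999).
#' @param seed Master RNG seed; every generator stage derives its own
#'   substream from it.
#' @return Validated \code{SyntheticSpec} list.
#' @export
syntheticSpec <- function(nGenes = 500, moduleSize = 40,
                          moduleDensity = 0.3, backgroundDensity = 0.01,
                          nPositive = 100, nNegative = 900,
                          targetsPerCompound = c(20, 30),
                          moduleTargetFraction = 0.7,
                          edgeScoreModule = c(mean = 800, sd = 90),
                          edgeScoreBackground = c(mean = 480, sd = 160),
                          targetScoreRange = c(100, 999),
                          seed = 0) {
  if (moduleSize >= nGenes) stop("module_size must be < n_genes")
  if (moduleDensity <= 0 || moduleDensity > 1 ||
      backgroundDensity <= 0 || backgroundDensity > 1)
    stop("densities must be in (0, 1]")
  if (length(targetsPerCompound) != 2L ||
      targetsPerCompound[1] > targetsPerCompound[2])
    stop("targetsPerCompound must be an increasing range")
  if (moduleTargetFraction < 0 || moduleTargetFraction > 1)
    stop("moduleTargetFraction must be in [0, 1]")
  structure(list(nGenes = as.integer(nGenes),
                 moduleSize = as.integer(moduleSize),
                 moduleDensity = moduleDensity,
                 backgroundDensity = backgroundDensity,
                 nPositive = as.integer(nPositive),
                 nNegative = as.integer(nNegative),
                 targetsPerCompound = as.integer(targetsPerCompound),
                 moduleTargetFraction = moduleTargetFraction,
                 edgeScoreModule = edgeScoreModule,
                 edgeScoreBackground = edgeScoreBackground,
                 targetScoreRange = as.integer(targetScoreRange),
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

clipScore <- function(x) as.integer(pmin(999, pmax(0, round(x))))

#' Generate a synthetic scored interactome with a planted module
#'
#' Planted-partition graph: node pairs inside the module are connected with
#' \code{moduleDensity}, all other pairs with \code{backgroundDensity}.
#' Module edges draw high confidence scores, background edges lower ones
#' (overlapping distributions). A random spanning chain over the non-module
#' nodes is added (scores from the background distribution) so the graph is
#' connected outside pathological thresholds; the number of added edges is
#' reported.
#'
#' @param spec A \code{\link{syntheticSpec}}.
#' @return List with \code{edges} (data.frame \code{node_a}, \code{node_b},
#'   \code{score}) and \code{truth} (list with \code{moduleGenes},
#'   \code{genes}, \code{spec}).
#' @export
generateInteractome <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(deriveSeed(spec$seed, 1), {
    genes <- sprintf("G%05d", seq_len(spec$nGenes))
    moduleGenes <- sort(sample(genes, spec$moduleSize))
    inMod <- genes %in% moduleGenes
    pairs <- utils::combn(spec$nGenes, 2)
    bothMod <- inMod[pairs[1, ]] & inMod[pairs[2, ]]
    p <- ifelse(bothMod, spec$moduleDensity, spec$backgroundDensity)
    keep <- runif(ncol(pairs)) < p
    ka <- pairs[1, keep]; kb <- pairs[2, keep]; km <- bothMod[keep]
    score <- integer(sum(keep))
    score[km] <- clipScore(rnorm(sum(km), spec$edgeScoreModule["mean"],
                                 spec$edgeScoreModule["sd"]))
    score[!km] <- clipScore(rnorm(sum(!km), spec$edgeScoreBackground["mean"],
                                  spec$edgeScoreBackground["sd"]))
    edges <- data.frame(node_a = genes[ka], node_b = genes[kb],
                        score = score, stringsAsFactors = FALSE)
    # spanning chain over non-module nodes for connectivity
    nonMod <- which(!inMod)
    perm <- nonMod[sample.int(length(nonMod))]
    ta <- perm[-length(perm)]; tb <- perm[-1]
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    have <- key(ka, kb)
    want <- key(ta, tb)
    add <- !(want %in% have)
    nAdded <- sum(add)
    if (nAdded) {
      treeEdges <- data.frame(
        node_a = genes[pmin(ta, tb)[add]],
        node_b = genes[pmax(ta, tb)[add]],
        score = clipScore(rnorm(nAdded, spec$edgeScoreBackground["mean"],
                                spec$edgeScoreBackground["sd"])),
        stringsAsFactors = FALSE)
      edges <- rbind(edges, treeEdges)
    }
    cbmMessage("synthetic interactome: ", nrow(edges), " edges (",
               nAdded, " spanning-chain edges added)")
    edges <- edges[order(edges$node_a, edges$node_b), ]
    rownames(edges) <- NULL
    list(edges = edges,
         truth = list(moduleGenes = moduleGenes, genes = genes, spec = spec))
  })
}

sampleCompoundTargets <- function(truth, positiveLike, spec) {
  k <- sample(seq(spec$targetsPerCompound[1], spec$targetsPerCompound[2]), 1)
  if (positiveLike) {
    nMod <- round(spec$moduleTargetFraction * k)
    if (nMod > length(truth$moduleGenes))
      stop("module smaller than the required target draw (",
           nMod, " > ", length(truth$moduleGenes),
           "); sampling with replacement is not allowed")
    mod <- sample(truth$moduleGenes, nMod)
    rest <- sample(setdiff(truth$genes, mod), k - nMod)
    c(mod, rest)
  } else {
    sample(truth$genes, k)
  }
}

#' Generate labeled synthetic compounds
#'
#' Positive compounds draw \code{moduleTargetFraction} of their targets from
#' the planted module (the rest uniformly from the remaining genes);
#' negatives draw all targets uniformly. Target scores are uniform over
#' \code{targetScoreRange}.
#'
#' @param spec A \code{\link{syntheticSpec}}.
#' @param truth The \code{truth} element from
#'   \code{\link{generateInteractome}}.
#' @return List with \code{targets} (data.frame \code{compound_id},
#'   \code{gene_id}, \code{score}), \code{labels} (data.frame
#'   \code{compound_id}, \code{label}) and \code{truth} (per-compound class).
#' @export
generateCompounds <- function(spec, truth) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(deriveSeed(spec$seed, 2), {
    n <- spec$nPositive + spec$nNegative
    ids <- sprintf("CPD%05d", seq_len(n))
    cls <- c(rep("positive", spec$nPositive), rep("negative", spec$nNegative))
    rows <- lapply(seq_len(n), function(i) {
      tg <- sampleCompoundTargets(truth, cls[i] == "positive", spec)
      data.frame(compound_id = ids[i], gene_id = tg,
                 score = sample(seq(spec$targetScoreRange[1],
                                    spec$targetScoreRange[2]),
                                length(tg), replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    list(targets = do.call(rbind, rows),
         labels = data.frame(compound_id = ids, label = cls,
                             stringsAsFactors = FALSE),
         truth = data.frame(compound_id = ids, true_class = cls,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic food map with planted CBM richness
#'
#' Creates unlabeled "food compounds" from a mixture of the positive-like
#' and negative-like target samplers and assigns them to foods whose
#' positive-like fraction declines linearly from the first food to the
#' last, planting a known CBM-richness ordering.
#'
#' @param spec A \code{\link{syntheticSpec}}.
#' @param truth Interactome truth (see \code{\link{generateInteractome}}).
#' @param nFoods Number of foods; default 10.
#' @param compoundsPerFood Compounds linked to each food; default 10.
#' @param richnessRange Positive-like probability of the first and last
#'   food; default c(0.8, 0).
#' @return List with \code{map} (data.frame \code{compound_id},
#'   \code{food_id}, \code{food_name}), \code{targets} for the food
#'   compounds, and \code{truth} (per-compound kind and per-food planted
#'   richness).
#' @export
generateFoodMap <- function(spec, truth, nFoods = 10, compoundsPerFood = 10,
                            richnessRange = c(0.8, 0)) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (nFoods == 0)
    return(list(map = data.frame(compound_id = character(0),
                                 food_id = character(0),
                                 food_name = character(0),
                                 stringsAsFactors = FALSE),
                targets = data.frame(compound_id = character(0),
                                     gene_id = character(0),
                                     score = integer(0),
                                     stringsAsFactors = FALSE),
                truth = data.frame(compound_id = character(0),
                                   kind = character(0),
                                   stringsAsFactors = FALSE)))
  withSeed(deriveSeed(spec$seed, 3), {
    richness <- seq(richnessRange[1], richnessRange[2], length.out = nFoods)
    mapRows <- list(); tgtRows <- list(); kindRows <- list()
    cpt <- 0L
    for (f in seq_len(nFoods)) {
      foodId <- sprintf("FOOD%03d", f)
      for (j in seq_len(compoundsPerFood)) {
        cpt <- cpt + 1L
        cid <- sprintf("FCPD%05d", cpt)
        posLike <- runif(1) < richness[f]
        tg <- sampleCompoundTargets(truth, posLike, spec)
        mapRows[[cpt]] <- data.frame(compound_id = cid, food_id = foodId,
                                     food_name = paste0("food_", f),
                                     stringsAsFactors = FALSE)
        tgtRows[[cpt]] <- data.frame(
          compound_id = cid, gene_id = tg,
          score = sample(seq(spec$targetScoreRange[1],
                             spec$targetScoreRange[2]),
                         length(tg), replace = TRUE),
          stringsAsFactors = FALSE)
        kindRows[[cpt]] <- data.frame(
          compound_id = cid,
          kind = if (posLike) "positive_like" else "negative_like",
          stringsAsFactors = FALSE)
      }
    }
    list(map = do.call(rbind, mapRows),
         targets = do.call(rbind, tgtRows),
         truth = list(kinds = do.call(rbind, kindRows),
                      richness = data.frame(
                        food_id = sprintf("FOOD%03d", seq_len(nFoods)),
                        planted_richness = richness,
                        stringsAsFactors = FALSE)))
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the TSV dialects the readers consume (scored edge list,
#' compound-target table, label table, food map and food-compound targets)
#' plus a ground-truth JSON.
#'
#' @param spec A \code{\link{syntheticSpec}}.
#' @param dir Output directory (created).
#' @param nFoods,compoundsPerFood Food-map size (see
#'   \code{\link{generateFoodMap}}).
#' @return Invisibly, a named list of the paths written.
#' @export
writeSyntheticData <- function(spec, dir, nFoods = 10,
                               compoundsPerFood = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- generateInteractome(spec)
  cpds <- generateCompounds(spec, net$truth)
  food <- generateFoodMap(spec, net$truth, nFoods = nFoods,
                          compoundsPerFood = compoundsPerFood)
  paths <- list(edges = file.path(dir, "edges.tsv"),
                targets = file.path(dir, "targets.tsv"),
                labels = file.path(dir, "labels.tsv"),
                food_map = file.path(dir, "food_map.tsv"),
                food_targets = file.path(dir, "food_targets.tsv"),
                truth = file.path(dir, "ground_truth.json"))
  wt <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(net$edges, paths$edges)
  wt(cpds$targets, paths$targets)
  wt(cpds$labels, paths$labels)
  wt(food$map, paths$food_map)
  wt(food$targets, paths$food_targets)
  jsonlite::write_json(
    list(module_genes = net$truth$moduleGenes,
         compound_classes = cpds$truth,
         food_compound_kinds = food$truth$kinds,
         food_richness = food$truth$richness,
         seed = spec$seed),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
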