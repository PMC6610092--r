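#' Stratified fold assignment
#'
#' Assigns samples to k folds preserving class proportions: within each
#' class, shuffled indices are dealt round-robin, so every fold's positive
#' count is within one of exact proportionality.
#'
#' @param y Binary label vector.
#' @param k Number of folds.
#' @param seed Integer RNG seed (required: fold assignment is the only
#'   stochastic step of cross-validation and must be reproducible).
#' @return Integer vector of fold ids in 1..k, same length as \code{y}.
#' @export
stratifiedFolds <- function(y, k, seed) {
  y <- as.integer(y)
  if (min(table(y)) < k)
    stop("too few samples in the minority class to stratify ", k,
         " folds (need >= ", k, " per class)")
  fold <- integer(length(y))
  withSeed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' The full canonical parameter grid
#'
#' The complete model-selection grid: compound-gene confidence thresholds
#' {0, 100, 200, 325, 400, 500, 600, 700}; gene-gene confidence thresholds
#' {400, 600, 700, 800, 850} plus the unscored experimental-interactome
#' level (exposed as 999, since unscored curated edges enter with the
#' maximal score); restart probabilities \code{\link{defaultCValues}}; and
#' the log-transform toggle. 8 x 6 x 14 x 2 = 1344 propagation /
#' preprocessing combinations per classifier. Grids used at desk scale are
#' subsets of this.
#'
#' @return Named list with elements \code{drugGeneThresholds},
#'   \code{geneGeneThresholds}, \code{cValues}, \code{logTransform},
#'   \code{classifiers}.
#' @export
defaultParameterGrid <- function() {
  list(drugGeneThresholds = c(0, 100, 200, 325, 400, 500, 600, 700),
       geneGeneThresholds = c(400, 600, 700, 800, 850, 999),
       cValues = defaultCValues(),
       logTransform = c(TRUE, FALSE),
       classifiers = c("linear_svm", "mmc"))
}

defaultHyperGrid <- function(classifier) {
  switch(classifier,
         linear_svm = c(0.1, 1, 10),
         mmc = 1,
         stop("unknown classifier kind: ", classifier))
}

fitClassifier <- function(classifier, X, y, hp, logTransformed = FALSE) {
  switch(classifier,
         linear_svm = fitLinearSVM(X, y, C = hp,
                                   logTransformed = logTransformed),
         mmc = fitMMC(X, y, k = hp, logTransformed = logTransformed),
         stop("unknown classifier kind: ", classifier))
}

#' Nested stratified cross-validation of one parameter setting
#'
#' Outer stratified folds (default 10) estimate the generalization F score;
#' within each outer training set, inner stratified folds (default 5) pick
#' the classifier hyperparameter (soft-margin cost C for the SVM, projection
#' dimension k for MMC) by mean inner F1. Probability calibration is fitted
#' on the out-of-fold decision values collected during the inner loop (so
#' calibration never sees its own training scores); when the hyperparameter
#' grid has a single candidate the inner loop is vacuous and is skipped,
#' with calibration falling back to training decision values. The final
#' model is refit on all data with the averaged best hyperparameter
#' (geometric mean for C, which lives on a log scale; rounded median for k).
#'
#' @param X Numeric matrix, compounds x genes (already preprocessed).
#' @param y Binary labels (1 = anti-cancer), at least \code{outerK} per
#'   class.
#' @param classifier \code{"linear_svm"} or \code{"mmc"}.
#' @param hyperGrid Numeric vector of hyperparameter candidates; default
#'   C in {0.1, 1, 10} for the SVM, k = 1 for MMC.
#' @param outerK,innerK Fold counts (default 10 and 5).
#' @param seed Integer RNG seed controlling all fold assignments.
#' @return A \code{ModelRecord} list: \code{outer_cv_f1} (mean F1 across
#'   outer folds), \code{per_class_accuracy}, \code{f1_per_fold},
#'   \code{best_inner_hyperparams}, \code{final_model}, \code{oof_prob}
#'   (out-of-fold calibrated probabilities, one per compound), \code{folds}
#'   (outer assignment), and \code{inner_bookkeeping} proving that
#'   inner-loop selection only ever saw outer-training compounds.
#' @export
nestedCrossValidate <- function(X, y, classifier = c("linear_svm", "mmc"),
                                hyperGrid = NULL, outerK = 10, innerK = 5,
                                seed = 0) {
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (is.null(hyperGrid)) hyperGrid <- defaultHyperGrid(classifier)
  if (length(unique(y)) < 2 || min(table(y)) < outerK)
    stop("too few samples per class for ", outerK, "-fold outer CV (need >= ",
         outerK, " in each class)")
  folds <- stratifiedFolds(y, outerK, seed)
  perFold <- vector("list", outerK)
  innerBook <- vector("list", outerK)
  oofProb <- rep(NA_real_, length(y))
  for (f in seq_len(outerK)) {
    testIdx <- which(folds == f)
    trainIdx <- which(folds != f)
    Xtr <- X[trainIdx, , drop = FALSE]; ytr <- y[trainIdx]
    bestHp <- hyperGrid[1L]
    oofScores <- NULL; oofY <- NULL
    if (length(hyperGrid) > 1L) {
      innerSeed <- deriveSeed(seed, f)
      inner <- stratifiedFolds(ytr, innerK, innerSeed)
      if (length(hyperGrid) > 1L) {
        meanF <- vapply(hyperGrid, function(hp) {
          fs <- vapply(seq_len(innerK), function(g) {
            m <- fitClassifier(classifier, Xtr[inner != g, , drop = FALSE],
                               ytr[inner != g], hp)
            pr <- predictACL(m, Xtr[inner == g, , drop = FALSE])
            fScore(ytr[inner == g], as.integer(pr > 0.5))$f1
          }, numeric(1))
          mean(fs)
        }, numeric(1))
        bestHp <- hyperGrid[which.max(meanF)]
      }
      # out-of-fold decision values at the chosen hyperparameter, used for
      # leak-free probability calibration
      sc <- vector("list", innerK)
      for (g in seq_len(innerK)) {
        m <- fitClassifier(classifier, Xtr[inner != g, , drop = FALSE],
                           ytr[inner != g], bestHp)
        sc[[g]] <- decisionValues(m, Xtr[inner == g, , drop = FALSE])
      }
      ordIdx <- order(unlist(lapply(seq_len(innerK),
                                    function(g) which(inner == g))))
      oofScores <- do.call(rbind, lapply(sc, as.matrix))[ordIdx, ,
                                                         drop = FALSE]
      oofY <- ytr
    }
    model <- fitClassifier(classifier, Xtr, ytr, bestHp)
    if (!is.null(oofScores))
      model@calibration <- plattCalibrate(oofScores, oofY)
    pr <- predictACL(model, X[testIdx, , drop = FALSE])
    oofProb[testIdx] <- pr
    m <- fScore(y[testIdx], as.integer(pr > 0.5))
    perFold[[f]] <- list(best_hp = bestHp, f1 = m$f1,
                         accPositive = m$accPositive,
                         accNegative = m$accNegative)
    innerBook[[f]] <- list(outer_test = testIdx, inner_seen = trainIdx)
  }
  f1s <- vapply(perFold, `[[`, numeric(1), "f1")
  bestHps <- vapply(perFold, `[[`, numeric(1), "best_hp")
  finalHp <- if (classifier == "linear_svm")
    exp(mean(log(bestHps))) else as.integer(round(median(bestHps)))
  finalModel <- fitClassifier(classifier, X, y, finalHp)
  structure(list(
    classifier = classifier,
    outer_cv_f1 = mean(f1s),
    f1_per_fold = f1s,
    per_class_accuracy = c(
      positive = mean(vapply(perFold, `[[`, numeric(1), "accPositive"),
                      na.rm = TRUE),
      negative = mean(vapply(perFold, `[[`, numeric(1), "accNegative"),
                      na.rm = TRUE)),
    best_inner_hyperparams = bestHps,
    final_hyperparam = finalHp,
    final_model = finalModel,
    oof_prob = oofProb,
    folds = folds,
    inner_bookkeeping = innerBook,
    seed = seed), class = "ModelRecord")
}

#' @export
print.ModelRecord <- function(x, ...) {
  cat("ModelRecord:", x$classifier, "| mean outer F1 =",
      round(x$outer_cv_f1, 4), "| per-class acc =",
      round(x$per_class_accuracy[1], 3), "/",
      round(x$per_class_accuracy[2], 3), "\n")
  invisible(x)
}

# Fetch (building and caching if needed) the raw propagated profile matrix
# for one (gene-gene threshold, drug-gene threshold, c) setting. `tag`
# namespaces the cache by compound table (training vs scoring).
getProfiles <- function(edges, targets, gg, dg, cc, cache, tag = "train") {
  gKey <- paste0("graph|", gg)
  if (is.null(cache[[gKey]]))
    cache[[gKey]] <- buildInteractome(edges, gg)
  graph <- cache[[gKey]]
  pKey <- paste0("prof|", tag, "|", gg, "|", dg, "|",
                 format(cc, digits = 15, scientific = FALSE))
  if (is.null(cache[[pKey]])) {
    ft <- filterTargets(targets, dg)
    if (nrow(ft) == 0L) stop("no targets survive drug-gene threshold ", dg)
    cache[[pKey]] <- suppressWarnings(propagateProfiles(ft, graph, cc))
  }
  cache[[pKey]]
}

#' Grid search with nested cross-validation
#'
#' Evaluates every combination of gene-gene threshold, compound-gene
#' threshold, restart probability c, log-transform toggle and classifier
#' kind. Each grid point rebuilds the graph, re-filters the targets,
#' re-propagates and nested-cross-validates; graphs and raw propagated
#' profiles are cached by their settings so points differing only in the
#' log flag or classifier reuse the propagation. Per-point failures are
#' recorded and the grid continues.
#'
#' @param edges Scored edge list (see \code{\link{readEdgeList}}).
#' @param targets Compound-target table (see
#'   \code{\link{readCompoundTargets}}).
#' @param labels Label table (\code{compound_id}, \code{label}); only
#'   compounds labeled positive or negative enter training.
#' @param grid Named list as in \code{\link{defaultParameterGrid}} (use a
#'   subset for desk-scale runs).
#' @param seed Integer RNG seed; the same seed (hence identical folds) is
#'   used at every grid point so F scores are comparable.
#' @param hyperGrids Optional named list of hyperparameter candidate vectors
#'   per classifier.
#' @param cache Optional environment reused across calls.
#' @param verbose Print one line per grid point.
#' @return List of \code{ModelRecord}s, each with a \code{settings} element
#'   and \code{settings_key}; failed points carry an \code{error} string.
#' @export
runGrid <- function(edges, targets, labels, grid, seed = 0,
                    hyperGrids = NULL, cache = NULL, verbose = FALSE) {
  stopifnot(all(c("drugGeneThresholds", "geneGeneThresholds", "cValues",
                  "logTransform", "classifiers") %in% names(grid)))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  labeled <- labels[labels$label %in% c("positive", "negative"), ]
  records <- list()
  for (gg in grid$geneGeneThresholds) for (dg in grid$drugGeneThresholds)
    for (cc in grid$cValues) for (lg in grid$logTransform)
      for (cls in grid$classifiers) {
    settings <- list(gene_gene_threshold = gg, drug_gene_threshold = dg,
                     c = cc, log_transform = lg, classifier = cls)
    key <- settingsKey(settings)
    rec <- tryCatch({
      ps <- getProfiles(edges, targets, gg, dg, cc, cache)
      ids <- intersect(colnames(ps), labeled$compound_id)
      X <- profileMatrix(ps)[ids, , drop = FALSE]
      if (lg) X <- logTransform(X)
      yv <- as.integer(labeled$label[match(ids, labeled$compound_id)] ==
                         "positive")
      hg <- if (!is.null(hyperGrids)) hyperGrids[[cls]] else NULL
      r <- nestedCrossValidate(X, yv, classifier = cls, hyperGrid = hg,
                               seed = seed)
      r$final_model@logTransformed <- lg
      r$settings <- settings
      r$settings_key <- key
      r$compound_ids <- ids
      r
    }, error = function(e) {
      structure(list(settings = settings, settings_key = key,
                     outer_cv_f1 = NA_real_, error = conditionMessage(e)),
                class = "ModelRecord")
    })
    if (verbose)
      cbmMessage(key, " -> F1 = ",
                 if (is.na(rec$outer_cv_f1)) paste0("ERROR: ", rec$error)
                 else round(rec$outer_cv_f1, 4))
    records[[key]] <- rec
  }
  records
}

#' Tabulate grid-search results
#'
#' @param records List of \code{ModelRecord}s from \code{\link{runGrid}}.
#' @return data.frame with one row per grid point: settings columns, mean
#'   outer F1 and per-class accuracies, sorted by F1 descending (ties broken
#'   by settings key).
#' @export
resultsTable <- function(records) {
  rows <- lapply(records, function(r) {
    data.frame(gene_gene_threshold = r$settings$gene_gene_threshold,
               drug_gene_threshold = r$settings$drug_gene_threshold,
               c = r$settings$c, log_transform = r$settings$log_transform,
               classifier = r$settings$classifier,
               outer_cv_f1 = r$outer_cv_f1,
               acc_positive = if (is.null(r$error))
                 r$per_class_accuracy["positive"] else NA_real_,
               acc_negative = if (is.null(r$error))
                 r$per_class_accuracy["negative"] else NA_real_,
               error = if (is.null(r$error)) "" else r$error,
               settings_key = r$settings_key,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$outer_cv_f1, df$settings_key, na.last = TRUE), ]
  rownames(df) <- NULL
  df
}

#' Select the model ensemble
#'
#' Keeps the models used for ensemble anti-cancer likeness averaging: either
#' every model with mean outer F1 at or above \code{minF1} (canonical 0.84),
#' or the \code{topN} best (canonical 700 at full scale). Members are sorted
#' by F1 descending with ties broken deterministically by settings key.
#'
#' @param records List of \code{ModelRecord}s.
#' @param minF1 F1 cutoff (used when \code{topN} is NULL); default 0.84.
#' @param topN Optional count of best models to keep.
#' @return An \code{EnsembleModel} list with \code{members} and
#'   \code{selection_rule}.
#' @export
selectModels <- function(records, minF1 = 0.84, topN = NULL) {
  ok <- Filter(function(r) is.null(r$error) && !is.na(r$outer_cv_f1), records)
  if (length(ok) == 0L) stop("no successful model records to select from")
  f1 <- vapply(ok, `[[`, numeric(1), "outer_cv_f1")
  keys <- vapply(ok, `[[`, character(1), "settings_key")
  ord <- order(-f1, keys)
  ok <- ok[ord]; f1 <- f1[ord]
  if (!is.null(topN)) {
    members <- ok[seq_len(min(topN, length(ok)))]
    rule <- list(top_n = topN)
  } else {
    members <- ok[f1 >= minF1]
    rule <- list(min_f1 = minF1)
  }
  if (length(members) == 0L)
    stop("no model reaches F1 >= ", minF1,
         "; relax the threshold or use topN")
  structure(list(members = members, selection_rule = rule),
            class = "EnsembleModel")
}

#' @export
print.EnsembleModel <- function(x, ...) {
  f1 <- vapply(x$members, `[[`, numeric(1), "outer_cv_f1")
  cat("EnsembleModel with", length(x$members), "members; F1 range [",
      round(min(f1), 3), ",", round(max(f1), 3), "]\n")
  invisible(x)
}

#' Ensemble anti-cancer likeness prediction
#'
#' Scores new compounds with every ensemble member in that member's own
#' feature space: the member's settings are replayed (graph threshold,
#' target filtering, restart probability, log transform) on the new
#' compound-target table, and the member's final model emits a calibrated
#' probability. The anti-cancer likeness (ACL) is the arithmetic mean across
#' members; the member count and standard deviation are reported per
#' compound. Compounds unusable under some members (no surviving entry
#' points) skip those members; compounds unusable under every member get a
#' missing ACL with a reason.
#'
#' @param ensemble An \code{EnsembleModel} from \code{\link{selectModels}}.
#' @param newTargets Compound-target table for the compounds to score.
#' @param edges The scored edge list the ensemble was trained on.
#' @param cache Optional environment (reuse the one from
#'   \code{\link{runGrid}} to skip re-propagation).
#' @return data.frame: \code{compound_id}, \code{acl}, \code{n_members},
#'   \code{sd}, \code{reason} (empty unless ACL is missing).
#' @export
ensemblePredictACL <- function(ensemble, newTargets, edges, cache = NULL) {
  stopifnot(inherits(ensemble, "EnsembleModel"))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  compounds <- unique(newTargets$compound_id)
  probs <- matrix(NA_real_, nrow = length(compounds),
                  ncol = length(ensemble$members),
                  dimnames = list(compounds, NULL))
  for (mi in seq_along(ensemble$members)) {
    mem <- ensemble$members[[mi]]
    s <- mem$settings
    ps <- tryCatch(
      getProfiles(edges, newTargets, s$gene_gene_threshold,
                  s$drug_gene_threshold, s$c, cache,
                  tag = paste0("score", length(compounds))),
      error = function(e) NULL)
    if (is.null(ps)) next
    X <- profileMatrix(ps)
    if (s$log_transform) X <- logTransform(X)
    pr <- predictACL(mem$final_model, X)
    probs[match(rownames(X), compounds), mi] <- pr
  }
  nMem <- rowSums(!is.na(probs))
  acl <- ifelse(nMem > 0, rowMeans(probs, na.rm = TRUE), NA_real_)
  sds <- apply(probs, 1, function(r)
    if (sum(!is.na(r)) > 1) sd(r, na.rm = TRUE) else NA_real_)
  data.frame(compound_id = compounds, acl = acl,
             n_members = as.integer(nMem), sd = sds,
             reason = ifelse(nMem == 0, "no entry points under any member",
                             ""),
             stringsAsFactors = FALSE, row.names = NULL)
}
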