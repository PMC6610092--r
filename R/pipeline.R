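#' Read and validate a pipeline run configuration
#'
#' The YAML config declares input paths, the parameter grid, propagation
#' defaults, the model-selection rule, the ACL threshold, the RNG seed and
#' the output directory. Every stage echoes the config (with the effective
#' seed) into the output directory, so each run is self-describing.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the config's.
#' @param outputDir Optional output directory overriding the config's.
#' @return Validated \code{RunConfig} list.
#' @export
readRunConfig <- function(path, seed = NULL, outputDir = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) cfg$seed <- 0L
  if (!is.null(outputDir)) cfg$output_dir <- outputDir
  if (is.null(cfg$output_dir)) stop("config must declare output_dir")
  if (is.null(cfg$grid)) cfg$grid <- list()
  g <- cfg$grid
  cfg$grid <- list(
    drugGeneThresholds = unlist(g$drug_gene_thresholds) %||% 0,
    geneGeneThresholds = unlist(g$gene_gene_thresholds) %||% 600,
    cValues = unlist(g$c_values) %||% 0.02,
    logTransform = unlist(g$log_transform) %||% TRUE,
    classifiers = unlist(g$classifiers) %||% c("linear_svm", "mmc"))
  if (is.null(cfg$acl_threshold)) cfg$acl_threshold <- 0.7
  if (is.null(cfg$selection)) cfg$selection <- list(min_f1 = 0.84)
  structure(cfg, class = "RunConfig")
}

echoConfig <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir,
                                           "config_echo.yaml"))
}

requireInputs <- function(cfg, what) {
  for (w in what) {
    p <- cfg$inputs[[w]]
    if (is.null(p)) stop("config is missing inputs$", w)
    if (!file.exists(p)) stop("input file not found: ", p, " (inputs$",
                              w, ")")
  }
}

#' Pipeline stage: simulate
#'
#' Generates a synthetic benchmark dataset (see
#' \code{\link{writeSyntheticData}}) under \code{output_dir/data} and points
#' the config's inputs at it.
#'
#' @param cfg A \code{RunConfig} (or path to one).
#' @return The updated config, invisibly.
#' @export
runSimulateStage <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  sy <- cfg$synthetic %||% list()
  spec <- syntheticSpec(
    nGenes = sy$n_genes %||% 500, moduleSize = sy$module_size %||% 40,
    moduleDensity = sy$module_density %||% 0.3,
    backgroundDensity = sy$background_density %||% 0.01,
    nPositive = sy$n_positive %||% 100, nNegative = sy$n_negative %||% 900,
    moduleTargetFraction = sy$module_target_fraction %||% 0.7,
    seed = cfg$seed)
  paths <- writeSyntheticData(spec, file.path(cfg$output_dir, "data"),
                              nFoods = sy$n_foods %||% 10,
                              compoundsPerFood = sy$compounds_per_food %||% 10)
  cfg$inputs <- list(edges = paths$edges, targets = paths$targets,
                     labels = paths$labels, food_map = paths$food_map,
                     food_targets = paths$food_targets)
  echoConfig(cfg)
  invisible(cfg)
}

profilePath <- function(cfg, gg, dg, cc) {
  file.path(cfg$output_dir, "profiles",
            sprintf("profiles_gg%s_dg%s_c%s.tsv", gg, dg,
                    format(cc, scientific = FALSE)))
}

#' Pipeline stage: propagate
#'
#' Computes and writes the propagated profile matrix (compounds x genes) for
#' every (gene-gene threshold, compound-gene threshold, c) combination of
#' the grid, plus a per-compound convergence log. Re-running is a cache
#' no-op: existing profile files are kept.
#'
#' @param cfg A \code{RunConfig} (or path).
#' @return Invisibly, the paths of the profile files.
#' @export
runPropagateStage <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  requireInputs(cfg, c("edges", "targets"))
  echoConfig(cfg)
  edges <- readEdgeList(cfg$inputs$edges)
  targets <- readCompoundTargets(cfg$inputs$targets)
  dir.create(file.path(cfg$output_dir, "profiles"), showWarnings = FALSE,
             recursive = TRUE)
  cache <- new.env(parent = emptyenv())
  logRows <- list()
  paths <- character(0)
  for (gg in cfg$grid$geneGeneThresholds) {
    sPath <- file.path(cfg$output_dir, "profiles",
                       sprintf("graph_summary_gg%s.json", gg))
    if (!file.exists(sPath)) {
      gKey <- paste0("graph|", gg)
      if (is.null(cache[[gKey]]))
        cache[[gKey]] <- buildInteractome(edges, gg)
      jsonlite::write_json(graphSummary(cache[[gKey]]), sPath,
                           auto_unbox = TRUE)
    }
    for (dg in cfg$grid$drugGeneThresholds)
      for (cc in cfg$grid$cValues) {
        p <- profilePath(cfg, gg, dg, cc)
        if (!file.exists(p)) {
          ps <- getProfiles(edges, targets, gg, dg, cc, cache)
          m <- profileMatrix(ps)
          write.table(data.frame(compound_id = rownames(m), m,
                                 check.names = FALSE),
                      p, sep = "\t", quote = FALSE, row.names = FALSE)
          cd <- SummarizedExperiment::colData(ps)
          logRows[[p]] <- data.frame(
            gene_gene_threshold = gg, drug_gene_threshold = dg, c = cc,
            compound_id = cd$compound_id, n_entry = cd$n_entry,
            iterations = cd$iterations, converged = cd$converged,
            stringsAsFactors = FALSE)
        }
        paths <- c(paths, p)
      }
  }
  if (length(logRows)) {
    logPath <- file.path(cfg$output_dir, "convergence_log.tsv")
    write.table(do.call(rbind, logRows), logPath, sep = "\t", quote = FALSE,
                row.names = FALSE,
                append = file.exists(logPath),
                col.names = !file.exists(logPath))
  }
  invisible(paths)
}

#' Pipeline stage: train
#'
#' Runs the nested cross-validated grid search, writes the results table
#' (one row per grid point per classifier), selects the ensemble per the
#' config's selection rule and writes its manifest (member settings, F
#' scores and serialized final models) as JSON.
#'
#' @param cfg A \code{RunConfig} (or path).
#' @return Invisibly, a list with \code{records}, \code{ensemble} and the
#'   output paths.
#' @export
runTrainStage <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  requireInputs(cfg, c("edges", "targets", "labels"))
  echoConfig(cfg)
  edges <- readEdgeList(cfg$inputs$edges)
  targets <- readCompoundTargets(cfg$inputs$targets)
  labels <- readCompoundLabels(cfg$inputs$labels)
  records <- runGrid(edges, targets, labels, cfg$grid, seed = cfg$seed)
  tab <- resultsTable(records)
  resPath <- file.path(cfg$output_dir, "results.tsv")
  write.table(tab, resPath, sep = "\t", quote = FALSE, row.names = FALSE)
  ensemble <- if (!is.null(cfg$selection$top_n))
    selectModels(records, topN = cfg$selection$top_n)
  else selectModels(records, minF1 = cfg$selection$min_f1 %||% 0.84)
  manifest <- list(
    selection_rule = ensemble$selection_rule,
    seed = cfg$seed,
    members = lapply(ensemble$members, function(m)
      list(settings = m$settings, outer_cv_f1 = m$outer_cv_f1,
           final_hyperparam = m$final_hyperparam,
           model = modelToList(m$final_model))))
  manPath <- file.path(cfg$output_dir, "ensemble.json")
  jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, digits = NA)
  invisible(list(records = records, ensemble = ensemble,
                 results_path = resPath, manifest_path = manPath))
}

readEnsembleManifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame =
                             FALSE, simplifyMatrix = FALSE)
  members <- lapply(m$members, function(x) {
    x$model <- lapply(x$model, function(v) if (is.list(v)) unlist(v) else v)
    structure(list(settings = x$settings, outer_cv_f1 = x$outer_cv_f1,
                   final_hyperparam = x$final_hyperparam,
                   final_model = modelFromList(x$model),
                   settings_key = settingsKey(x$settings)),
              class = "ModelRecord")
  })
  structure(list(members = members, selection_rule = m$selection_rule),
            class = "EnsembleModel")
}

#' Pipeline stage: score
#'
#' Applies the trained ensemble to the food-compound table: writes the
#' per-compound ACL predictions, the curated CBM table at the configured
#' threshold, and the food map (per-food CBM counts plus the food-food
#' correlation edge list).
#'
#' @param cfg A \code{RunConfig} (or path).
#' @return Invisibly, the ACL data.frame.
#' @export
runScoreStage <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  manPath <- file.path(cfg$output_dir, "ensemble.json")
  if (!file.exists(manPath))
    stop("no ensemble manifest at ", manPath,
         "; run the train stage (runTrainStage) first")
  requireInputs(cfg, c("edges", "food_map", "food_targets"))
  echoConfig(cfg)
  edges <- readEdgeList(cfg$inputs$edges)
  foodTargets <- readCompoundTargets(cfg$inputs$food_targets)
  map <- readFoodMap(cfg$inputs$food_map)
  if (!is.null(cfg$inputs$toxins) && file.exists(cfg$inputs$toxins)) {
    tox <- read.delim(cfg$inputs$toxins, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
    map <- flagExclusions(map, toxinIds = tox)
  }
  ensemble <- readEnsembleManifest(manPath)
  acl <- ensemblePredictACL(ensemble, foodTargets, edges)
  write.table(acl, file.path(cfg$output_dir, "acl.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  thr <- cfg$acl_threshold %||% 0.7
  write.table(cbmTable(acl, map, thr),
              file.path(cfg$output_dir, "cbm_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts <- countCBMs(acl, map, thr)
  corMap <- tryCatch(foodCorrelationMap(map, acl, thr,
                                        corCutoff = cfg$correlation_cutoff),
                     error = function(e) NULL)
  if (is.null(corMap))
    corMap <- list(edges = data.frame(food_a = character(0),
                                      food_b = character(0),
                                      correlation = numeric(0)))
  writeFoodMapGraph(counts, corMap, cfg$output_dir)
  invisible(acl)
}
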