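test_that("stratified folds keep class proportions and respond to the seed", {
  y <- c(rep(1, 23), rep(0, 205))
  f <- stratifiedFolds(y, 10, seed = 1)
  posPerFold <- tapply(y, f, sum)
  expect_true(all(abs(posPerFold - 2.3) <= 1))
  negPerFold <- tapply(1 - y, f, sum)
  expect_true(all(abs(negPerFold - 20.5) <= 1))
  expect_identical(f, stratifiedFolds(y, 10, seed = 1))
  expect_false(identical(f, stratifiedFolds(y, 10, seed = 2)))
  expect_error(stratifiedFolds(c(1, 0, 0, 0), 3, 1), "too few")
})

test_that("nested CV is deterministic and leak-free", {
  td <- tinyData()
  g <- buildInteractome(td$net$edges, 0)
  ps <- propagateProfiles(td$cpds$targets, g, c = 0.05)
  X <- logTransform(profileMatrix(ps))
  y <- as.integer(td$cpds$labels$label[
    match(rownames(X), td$cpds$labels$compound_id)] == "positive")
  r1 <- nestedCrossValidate(X, y, "mmc", outerK = 10, innerK = 5, seed = 3)
  r2 <- nestedCrossValidate(X, y, "mmc", outerK = 10, innerK = 5, seed = 3)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$f1_per_fold, r2$f1_per_fold)
  r3 <- nestedCrossValidate(X, y, "mmc", seed = 4)
  expect_false(identical(r1$folds, r3$folds))
  # hygiene: inner selection never sees the outer test fold
  for (b in r1$inner_bookkeeping) {
    expect_length(intersect(b$outer_test, b$inner_seen), 0)
  }
  # on well-separated planted-module data both linear models do well
  expect_gte(r1$outer_cv_f1, 0.9)
  rs <- nestedCrossValidate(X, y, "linear_svm", hyperGrid = c(0.1, 1),
                            seed = 3)
  expect_gte(rs$outer_cv_f1, 0.9)
  expect_error(nestedCrossValidate(X[1:15, ], y[1:15], "mmc"), "too few")
})

test_that("the printed full grid has the documented shape", {
  g <- defaultParameterGrid()
  expect_length(g$drugGeneThresholds, 8)
  expect_length(g$geneGeneThresholds, 6)
  expect_length(g$cValues, 14)
  expect_length(g$logTransform, 2)
  expect_equal(8 * 6 * 14 * 2, 1344)
})

test_that("grid search caches propagation and matches a direct nested CV", {
  td <- tinyData()
  grid <- list(drugGeneThresholds = 0, geneGeneThresholds = 400,
               cValues = 0.05, logTransform = TRUE, classifiers = "mmc")
  cache <- new.env(parent = emptyenv())
  recs <- runGrid(td$net$edges, td$cpds$targets, td$cpds$labels, grid,
                  seed = 3, cache = cache)
  expect_length(recs, 1)
  # a grid of one point equals calling nestedCrossValidate directly
  g <- buildInteractome(td$net$edges, 400)
  ps <- propagateProfiles(td$cpds$targets, g, c = 0.05)
  X <- logTransform(profileMatrix(ps))
  y <- as.integer(td$cpds$labels$label[
    match(rownames(X), td$cpds$labels$compound_id)] == "positive")
  direct <- nestedCrossValidate(X, y, "mmc", seed = 3)
  expect_equal(recs[[1]]$outer_cv_f1, direct$outer_cv_f1)
  # two log flags share one cached propagation
  grid2 <- modifyList(grid, list(logTransform = c(TRUE, FALSE)))
  cache2 <- new.env(parent = emptyenv())
  recs2 <- runGrid(td$net$edges, td$cpds$targets, td$cpds$labels, grid2,
                   seed = 3, cache = cache2)
  profKeys <- grep("^prof", ls(cache2), value = TRUE)
  expect_length(profKeys, 1)
  expect_length(recs2, 2)
  tab <- resultsTable(recs2)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$error == ""))
})

test_that("model selection applies min-F1 and top-n rules deterministically", {
  mkrec <- function(f1, key) structure(
    list(outer_cv_f1 = f1, settings_key = key, error = NULL,
         settings = list(k = key)), class = "ModelRecord")
  recs <- lapply(1:10, function(i) mkrec(i / 10, sprintf("k%02d", i)))
  top3 <- selectModels(recs, topN = 3)
  expect_equal(vapply(top3$members, `[[`, numeric(1), "outer_cv_f1"),
               c(1, 0.9, 0.8))
  sel <- selectModels(recs, minF1 = 0.84)
  expect_equal(length(sel$members), 2)
  expect_error(selectModels(recs, minF1 = 1.01), "no model reaches")
  # ties broken by settings key
  recs2 <- list(mkrec(0.9, "b"), mkrec(0.9, "a"))
  expect_equal(selectModels(recs2, topN = 1)$members[[1]]$settings_key, "a")
})

test_that("ensemble ACL averages members and flags unusable compounds", {
  td <- tinyData()
  grid <- list(drugGeneThresholds = c(0, 400), geneGeneThresholds = 400,
               cValues = 0.05, logTransform = TRUE,
               classifiers = c("mmc", "linear_svm"))
  recs <- runGrid(td$net$edges, td$cpds$targets, td$cpds$labels, grid,
                  seed = 3, hyperGrids = list(mmc = 1, linear_svm = 1))
  ens <- selectModels(recs, topN = 2)
  # score a few held-out synthetic food compounds
  fm <- generateFoodMap(td$spec, td$net$truth, nFoods = 2,
                        compoundsPerFood = 5)
  acl <- ensemblePredictACL(ens, fm$targets, td$net$edges)
  expect_equal(nrow(acl), length(unique(fm$targets$compound_id)))
  expect_true(all(acl$acl >= 0 & acl$acl <= 1, na.rm = TRUE))
  expect_true(all(acl$n_members <= 2))
  # single-member ensemble equals that member's own prediction
  one <- selectModels(recs, topN = 1)
  mem <- one$members[[1]]
  aclOne <- ensemblePredictACL(one, fm$targets, td$net$edges)
  s <- mem$settings
  g <- buildInteractome(td$net$edges, s$gene_gene_threshold)
  ps <- propagateProfiles(filterTargets(fm$targets, s$drug_gene_threshold),
                          g, s$c)
  Xnew <- profileMatrix(ps)
  if (s$log_transform) Xnew <- logTransform(Xnew)
  direct <- predictACL(mem$final_model, Xnew)
  expect_equal(aclOne$acl[match(rownames(Xnew), aclOne$compound_id)],
               unname(direct), tolerance = 1e-12)
  # a compound with no mappable targets is reported, not dropped
  ghost <- data.frame(compound_id = "GHOST", gene_id = "NOPE", score = 900L)
  acl2 <- suppressWarnings(
    ensemblePredictACL(one, rbind(fm$targets, ghost), td$net$edges))
  expect_true(is.na(acl2$acl[acl2$compound_id == "GHOST"]))
  expect_match(acl2$reason[acl2$compound_id == "GHOST"], "no entry points")
})
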