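test_that("F score follows the confusion-matrix arithmetic", {
  expect_equal(fScore(c(1, 1, 0, 0), c(1, 1, 0, 0))$f1, 1)
  # TP=8, FP=2, FN=2: P = R = 0.8 => F1 = 0.8
  yt <- c(rep(1, 10), rep(0, 10))
  yp <- c(rep(1, 8), 0, 0, rep(0, 8), 1, 1)
  m <- fScore(yt, yp)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$accPositive, 0.8)
  expect_equal(m$accNegative, 0.8)
  # all-negative prediction with positives present
  expect_equal(fScore(c(1, 0, 0), c(0, 0, 0))$f1, 0)
  # degenerate: no positives anywhere -> F defined as 0 with warning
  expect_warning(z <- fScore(c(0, 0), c(0, 0)), "F defined as 0")
  expect_equal(z$f1, 0)
})

test_that("MMC solves the hand example exactly", {
  # class 0: (0,0), (0,1); class 1: (4,0), (4,1)
  X <- rbind(c(0, 0), c(0, 1), c(4, 0), c(4, 1))
  colnames(X) <- c("f1", "f2")
  y <- c(0, 0, 1, 1)
  m <- fitMMC(X, y, k = 2)
  # Sb = diag(4, 0), Sw = diag(0, 1/4): eigenvalues of Sb - Sw are 4, -1/4
  expect_equal(m@eigenvalues, c(4, -0.25))
  expect_equal(abs(m@projection[, 1]), c(1, 0))
  # projection oriented so the positive class projects higher
  expect_gt(mean(decisionValues(m, X)[y == 1, 1]),
            mean(decisionValues(m, X)[y == 0, 1]))
})

test_that("MMC recovers the discriminant axis of two Gaussians", {
  set.seed(31)
  n <- 2000
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c(0, 1), each = n / 2)
  X[y == 1, 1] <- X[y == 1, 1] + 2
  m <- fitMMC(X, y, k = 1)
  cosine <- abs(sum(m@projection[, 1] * c(1, rep(0, 9))))
  expect_gte(cosine, 0.99)
})

test_that("identical class means give non-positive MMC eigenvalues", {
  set.seed(8)
  X <- matrix(rnorm(200), 100, 2)
  y <- rep(c(0, 1), 50)
  m <- fitMMC(X, y, k = 2)
  expect_true(all(m@eigenvalues <= 1e-8))
})

test_that("MMC is equivariant under feature permutation", {
  set.seed(12)
  X <- matrix(rnorm(300), 60, 5)
  colnames(X) <- paste0("g", 1:5)
  y <- rep(c(0, 1), 30)
  X[y == 1, 3] <- X[y == 1, 3] + 3
  perm <- c(4, 2, 5, 1, 3)
  m1 <- fitMMC(X, y)
  m2 <- fitMMC(X[, perm], y)
  expect_equal(decisionValues(m1, X), decisionValues(m2, X[, perm]),
               tolerance = 1e-8)
})

test_that("linear SVM separates a separable toy set with balanced weights", {
  X <- rbind(c(0, 0), c(0, 1), c(4, 0), c(4, 1))
  colnames(X) <- c("f1", "f2")
  y <- c(0, 0, 1, 1)
  m <- fitLinearSVM(X, y, C = 10)
  pr <- predictACL(m, X)
  expect_equal(fScore(y, as.integer(pr > 0.5))$f1, 1)
  # flipping all labels flips the separator
  m2 <- fitLinearSVM(X, 1 - y, C = 10)
  cosine <- sum(m@weights * m2@weights) /
    (sqrt(sum(m@weights^2)) * sqrt(sum(m2@weights^2)))
  expect_lt(cosine, -0.99)
})

test_that("predictions are calibrated probabilities and deterministic", {
  td <- tinyData()
  g <- buildInteractome(td$net$edges, 400)
  ps <- propagateProfiles(td$cpds$targets, g, c = 0.05)
  X <- logTransform(profileMatrix(ps))
  y <- as.integer(td$cpds$labels$label[
    match(rownames(X), td$cpds$labels$compound_id)] == "positive")
  for (m in list(fitMMC(X, y), fitLinearSVM(X, y))) {
    pr1 <- predictACL(m, X)
    pr2 <- predictACL(m, X)
    expect_identical(pr1, pr2)
    expect_true(all(pr1 >= 0 & pr1 <= 1))
    # calibrated probability is monotone in the raw decision value
    dv <- as.numeric(as.matrix(decisionValues(m, X))[, 1])
    expect_true(all(diff(pr1[order(dv)]) >= 0))
    expect_error(predictACL(m, X[, 1:10]), "dimension")
  }
})

test_that("gene importance is a guarded Pearson correlation", {
  set.seed(3)
  X <- cbind(a = rnorm(30), b = rnorm(30), const = rep(2, 30))
  pred <- X[, "a"]
  imp <- geneImportance(pred, X)
  expect_equal(unname(imp["a"]), 1)
  expect_equal(unname(imp["const"]), 0)
  # invariant to shifting a column; sign-equivariant to negating it
  X2 <- X; X2[, "b"] <- X2[, "b"] + 100
  expect_equal(geneImportance(pred, X2)["b"], imp["b"])
  X3 <- X; X3[, "b"] <- -X3[, "b"]
  expect_equal(geneImportance(pred, X3)["b"], -imp["b"])
  expect_error(geneImportance(pred[1:2], X[1:2, ]), "at least 3")
  # ensemble importance is the arithmetic mean
  expect_equal(ensembleImportance(list(imp, 3 * imp)), 2 * imp)
})

test_that("model JSON round trip preserves predictions", {
  set.seed(21)
  X <- matrix(rnorm(200), 40, 5)
  colnames(X) <- paste0("g", 1:5)
  y <- rep(c(0, 1), 20)
  X[y == 1, 2] <- X[y == 1, 2] + 2
  for (m in list(fitMMC(X, y), fitLinearSVM(X, y, C = 0.5))) {
    tf <- tempfile(fileext = ".json")
    writeModelJSON(m, tf)
    m2 <- readModelJSON(tf)
    expect_equal(predictACL(m2, X), predictACL(m, X), tolerance = 1e-12)
  }
})

test_that("ranked gene list export is sorted descending", {
  imp <- c(g2 = 0.5, g1 = 0.9, g3 = -0.2)
  tf <- tempfile(fileext = ".rnk")
  writeRnk(imp, tf)
  rnk <- read.delim(tf, header = FALSE)
  expect_equal(rnk[[1]], c("g1", "g2", "g3"))
  expect_true(all(diff(rnk[[2]]) <= 0))
  tf2 <- tempfile(fileext = ".tsv")
  writeImportance(imp, tf2)
  tab <- read.delim(tf2)
  expect_equal(tab$gene_id, c("g1", "g2", "g3"))
  expect_equal(tab$rank, 1:3)
})
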