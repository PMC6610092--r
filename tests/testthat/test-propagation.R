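test_that("c = 1 returns the seed exactly after one iteration", {
  g <- buildInteractome(pathGraphEdges(c("A", "B", "C")), 0)
  s <- buildSeedVector("A", g)
  p <- propagate(s, g, propagationParams(c = 1))
  expect_identical(unname(p$values), c(1, 0, 0))
  expect_equal(p$iterations, 1L)
  expect_true(p$converged)
  pc <- propagateClosedForm(s, g, 1)
  expect_identical(unname(pc$values), c(1, 0, 0))
})

test_that("a dangling node's self-loop is a fixed point", {
  e <- rbind(pathGraphEdges(c("A", "B")),
             data.frame(node_a = "B", node_b = "D", score = 100L))
  g <- buildInteractome(e, 500)  # D dangling
  s <- buildSeedVector("D", g)
  p <- propagate(s, g, propagationParams(c = 0.3))
  expect_equal(unname(p$values[c("A", "B", "D")]), c(0, 0, 1))
})

test_that("two-node walk matches the hand-solved fixed point", {
  # A-B, seed {A}, c = 0.5: pA = 0.5 pB + 0.5, pB = 0.5 pA => (2/3, 1/3)
  g <- buildInteractome(pathGraphEdges(c("A", "B")), 0)
  s <- buildSeedVector("A", g)
  p <- propagate(s, g, propagationParams(c = 0.5, tol = 1e-12))
  expect_equal(unname(p$values), c(2 / 3, 1 / 3), tolerance = 1e-9)
  pc <- propagateClosedForm(s, g, 0.5)
  expect_equal(unname(pc$values), c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("iterative propagation matches an independent dense solve", {
  # 3-node path, seed {A}, c = 0.5, oracle: base-R solve of the fixed point
  g <- buildInteractome(pathGraphEdges(c("A", "B", "C")), 0)
  s <- buildSeedVector("A", g)
  W <- as.matrix(transitionMatrix(g))
  oracle <- drop(0.5 * as.numeric(s) %*% solve(diag(3) - 0.5 * W))
  p <- propagate(s, g, propagationParams(c = 0.5, tol = 1e-12))
  expect_lt(max(abs(p$values - oracle)), 1e-8)
})

test_that("iterates conserve probability mass", {
  e <- randomEdgeList(60, 0.05, seed = 4)
  e$score <- sample(0:999, nrow(e), replace = TRUE)
  g <- buildInteractome(e, 600)  # has dangling nodes
  expect_gt(graphSummary(g)$dangling, 0)
  s <- buildSeedVector(nodes(g)[1:5], g)
  for (cc in c(0.01, 0.1, 0.5)) {
    p <- propagate(s, g, propagationParams(c = cc))
    expect_lt(p$maxSumDeviation, 1e-10)
    expect_equal(sum(p$values), 1, tolerance = 1e-10)
  }
})

test_that("L1 changes contract at rate (1 - c)", {
  g <- buildInteractome(randomEdgeList(30, 0.15, seed = 9), 0)
  s <- buildSeedVector(nodes(g)[1:3], g)
  for (cc in c(0.05, 0.2, 0.5)) {
    p <- propagate(s, g, propagationParams(c = cc, tol = 1e-10),
                   keepTrace = TRUE)
    d <- p$diffTrace
    d <- d[d > 1e-14]
    ratios <- d[-1] / d[-length(d)]
    expect_true(all(ratios <= (1 - cc) + 1e-9))
    # iteration count consistent with the geometric bound
    bound <- ceiling(log(1e-10 / d[1]) / log(1 - cc)) + 2
    expect_lte(p$iterations, bound)
  }
})

test_that("seed-node mass is non-increasing as c shrinks", {
  g <- buildInteractome(pathGraphEdges(sprintf("V%02d", 1:8)), 0)
  s <- buildSeedVector("V01", g)
  cs <- sort(c(0.001, 0.01, 0.1, 0.5, 1), decreasing = TRUE)
  mass <- vapply(cs, function(cc)
    propagateClosedForm(s, g, cc)$values[["V01"]], numeric(1))
  expect_true(all(diff(mass) <= 1e-12))
})

test_that("closed form requires c > 0 and bounded graph size", {
  g <- buildInteractome(pathGraphEdges(c("A", "B")), 0)
  s <- buildSeedVector("A", g)
  expect_error(propagateClosedForm(s, g, 0), "c > 0")
  expect_error(propagate(c(1, 0, 0), g), "length")
})

test_that("batch propagation preserves order and isolates failures", {
  g <- buildInteractome(randomEdgeList(25, 0.2, seed = 6), 0)
  s1 <- buildSeedVector(nodes(g)[1:3], g)
  s2 <- buildSeedVector(nodes(g)[10:12], g)
  params <- propagationParams(c = 0.1)
  b1 <- propagateBatch(list(a = s1, b = s2), g, params)
  expect_identical(b1$a$values, propagate(s1, g, params)$values)
  # permuting the batch permutes the outputs identically
  b2 <- propagateBatch(list(b = s2, a = s1), g, params)
  expect_identical(b2$a$values, b1$a$values)
  expect_identical(b2$b$values, b1$b$values)
  # a bad seed yields an error object, not a batch failure
  b3 <- propagateBatch(list(ok = s1, bad = s1[-1]), g, params)
  expect_s3_class(b3$ok, "PropagatedProfile")
  expect_s3_class(b3$bad, "simpleError")
})

test_that("ProfileSet construction agrees between solvers", {
  td <- tinyData()
  g <- buildInteractome(td$net$edges, 400)
  tg <- td$cpds$targets
  tg <- tg[tg$compound_id %in% sprintf("CPD%05d", 1:10), ]
  psC <- propagateProfiles(tg, g, c = 0.05, method = "closed_form")
  psI <- propagateProfiles(tg, g, c = 0.05, method = "iterative",
                           params = propagationParams(tol = 1e-12))
  expect_s4_class(psC, "ProfileSet")
  expect_equal(dim(psC), dim(psI))
  expect_lt(max(abs(profileMatrix(psC) - profileMatrix(psI))), 1e-8)
  cd <- SummarizedExperiment::colData(psC)
  expect_true(all(cd$converged))
  expect_true(all(cd$n_entry >= 1))
  expect_equal(unname(rowSums(profileMatrix(psC))), rep(1, ncol(psC)),
               tolerance = 1e-10)
})
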