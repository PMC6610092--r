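test_that("edge loading collapses duplicates, drops self-edges, checks rows", {
  tf <- writeTempTSV(c("A\tB\t700", "B\tA\t700", "A\tA\t900", "B\tC\t400"))
  e <- suppressMessages(readEdgeList(tf))
  expect_equal(nrow(e), 2L)
  expect_equal(e$score[e$node_a == "A" & e$node_b == "B"], 700L)
  expect_equal(attr(e, "n_self_dropped"), 1L)

  # 10 rows, 2 duplicate pairs scored 400/600: 9 edges, duplicate keeps 600
  rows <- c("G1\tG2\t400", "G2\tG1\t600", "G1\tG3\t100", "G2\tG3\t200",
            "G3\tG4\t300", "G4\tG5\t500", "G5\tG6\t700", "G6\tG7\t800",
            "G7\tG8\t900", "G1\tG4\t250")
  e2 <- suppressMessages(readEdgeList(writeTempTSV(rows)))
  expect_equal(nrow(e2), 9L)
  expect_equal(e2$score[e2$node_a == "G1" & e2$node_b == "G2"], 600L)

  # header auto-detection
  e3 <- readEdgeList(writeTempTSV(c("node1\tnode2\tcombined_score",
                                    "A\tB\t500")))
  expect_equal(nrow(e3), 1L)

  # malformed row names its line; empty file errors
  expect_error(readEdgeList(writeTempTSV(c("A\tB\t500", "A\tC\tno"))),
               "line 2")
  empty <- tempfile(); file.create(empty)
  expect_error(readEdgeList(empty), "empty")

  # [0,1]-scaled scores are rescaled with a warning
  expect_warning(e4 <- readEdgeList(writeTempTSV(c("A\tB\t0.7"))),
                 "rescal")
  expect_equal(e4$score, as.integer(round(0.7 * 999)))
})

test_that("dichotomization respects the threshold and keeps dangling nodes", {
  e <- data.frame(node_a = c("A", "B", "C", "D", "E"),
                  node_b = c("B", "C", "D", "E", "A"),
                  score = c(300L, 400L, 600L, 850L, 900L))
  expect_equal(edgeCount(dichotomize(e, 0)), 5L)
  g <- dichotomize(e, 600)
  expect_equal(edgeCount(g), 3L)
  expect_equal(length(nodes(g)), 5L)  # all nodes retained
  expect_error(dichotomize(e, 1000), "threshold")
  expect_error(dichotomize(e, -1), "threshold")
  # canonical gene-gene threshold grid is accepted
  for (thr in c(400, 600, 700, 800, 850)) {
    expect_s4_class(dichotomize(e, thr), "Interactome")
  }
})

test_that("edge count is non-increasing in the threshold", {
  e <- randomEdgeList(40, 0.2, seed = 3)
  e$score <- sample(0:999, nrow(e), replace = TRUE)
  counts <- vapply(c(0, 200, 400, 600, 800, 999),
                   function(t) edgeCount(dichotomize(e, t)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("adjacency is symmetric and W is row-stochastic with self-loops", {
  g <- buildInteractome(pathGraphEdges(c("A", "B", "C")), 0)
  W <- as.matrix(transitionMatrix(g))
  expect_equal(unname(W), rbind(c(0, 1, 0), c(0.5, 0, 0.5), c(0, 1, 0)))

  # node D dangling after thresholding: self-loop row
  e <- rbind(pathGraphEdges(c("A", "B", "C")),
             data.frame(node_a = "C", node_b = "D", score = 100L))
  g2 <- buildInteractome(e, 500)
  W2 <- transitionMatrix(g2)
  expect_equal(W2["D", "D"], 1)

  # random graph with dangling nodes: all rows sum to 1 within 1e-12
  e3 <- randomEdgeList(50, 0.05, seed = 11)
  e3$score <- sample(0:999, nrow(e3), replace = TRUE)
  g3 <- buildInteractome(e3, 700)
  adj <- adjacencyMatrix(g3)
  expect_true(Matrix::isSymmetric(adj, tol = 0))
  rs <- Matrix::rowSums(transitionMatrix(g3))
  expect_lt(max(abs(rs - 1)), 1e-12)
})

test_that("protein record matching tiers behave as specified", {
  aa <- function(n, seed) {
    set.seed(seed)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                 replace = TRUE), collapse = "")
  }
  base <- aa(100, 1)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- seq_len(k)
    v[idx] <- ifelse(v[idx] == "A", "C", "A")
    paste(v, collapse = "")
  }
  long <- aa(200, 2)
  left <- c(p_exact = aa(120, 3),
            p_sub = substr(long, 61, 140),
            p_fuzzy5 = mut(base, 5),
            p_fuzzy6 = mut(base, 6))
  right <- c(r_exact = left[["p_exact"]],
             r_long = long,
             r_base = base)
  m <- matchProteinRecords(left, right, maxMismatchFrac = 0.05)
  expect_equal(m$tier[m$left_id == "p_exact"], "exact")
  expect_equal(m$right_id[m$left_id == "p_exact"], "r_exact")
  expect_equal(m$tier[m$left_id == "p_sub"], "substring")
  expect_equal(m$tier[m$left_id == "p_fuzzy5"], "fuzzy")
  expect_equal(m$mismatch_frac[m$left_id == "p_fuzzy5"], 0.05)
  expect_equal(m$tier[m$left_id == "p_fuzzy6"], "unmatched")
  # tiers are disjoint and exhaustive: one row per left record
  expect_equal(nrow(m), length(left))
  expect_true(all(m$tier %in% c("exact", "substring", "fuzzy", "unmatched")))

  expect_error(matchProteinRecords(c(a = "ACD", a = "ACD"), right),
               "duplicate")
})

test_that("graph summary reports nodes, edges and dangling count", {
  e <- rbind(pathGraphEdges(c("A", "B", "C")),
             data.frame(node_a = "C", node_b = "D", score = 100L))
  s <- graphSummary(buildInteractome(e, 500))
  expect_equal(s$nodes, 4L)
  expect_equal(s$edges, 2L)
  expect_equal(s$dangling, 1L)
  expect_equal(s$threshold, 500L)
})
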