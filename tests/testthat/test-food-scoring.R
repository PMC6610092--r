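toyMap <- function() {
  data.frame(compound_id = c("c1", "c2", "c2", "c3", "c3", "c4", "c5"),
             food_id = c("F1", "F1", "F2", "F2", "F3", "F3", "F3"),
             food_name = c("apple", "apple", "tea", "tea", "dill", "dill",
                           "dill"),
             excluded = FALSE, exclusion_reason = "",
             stringsAsFactors = FALSE)
}

toyACL <- c(c1 = 0.9, c2 = 0.8, c3 = 0.75, c4 = 0.6, c5 = 0.2)

test_that("exclusion flags mark compounds without dropping rows", {
  m <- flagExclusions(toyMap())
  expect_false(any(m$excluded))
  m2 <- flagExclusions(toyMap(), toxinIds = "c2")
  expect_equal(sum(m2$excluded), 2)  # c2 appears under two foods
  expect_true(all(m2$exclusion_reason[m2$excluded] == "toxic"))
  expect_equal(nrow(m2), nrow(toyMap()))
  # metabolite class flagging (dCTP-style)
  cls <- data.frame(compound_id = "c4",
                    class = "nucleosides, nucleotides, and analogues")
  m3 <- flagExclusions(toyMap(),
                       metaboliteClasses =
                         "nucleosides, nucleotides, and analogues",
                       compoundClasses = cls)
  expect_equal(m3$exclusion_reason[m3$compound_id == "c4"],
               "normal_metabolite")
  expect_error(flagExclusions(toyMap(), metaboliteClasses = "x"),
               "compoundClasses")
})

test_that("CBM counting uses a strict threshold and skips exclusions", {
  counts <- countCBMs(toyACL, toyMap(), threshold = 0.7)
  expect_equal(counts$cbm_count[counts$food_id == "F1"], 2L)  # c1, c2
  expect_equal(counts$cbm_count[counts$food_id == "F2"], 2L)  # c2, c3
  expect_equal(counts$cbm_count[counts$food_id == "F3"], 1L)  # c3 only
  # ACL exactly at the threshold does not count (strict >)
  expect_equal(countCBMs(c(c1 = 0.7), data.frame(
    compound_id = "c1", food_id = "F", food_name = "f", excluded = FALSE,
    exclusion_reason = ""), 0.7)$cbm_count, 0L)
  # threshold 1.0 zeroes everything
  expect_true(all(countCBMs(toyACL, toyMap(), 1)$cbm_count == 0))
  # monotone non-increasing in the threshold
  thr <- c(0, 0.3, 0.6, 0.79, 0.95)
  tot <- vapply(thr, function(t) sum(countCBMs(toyACL, toyMap(), t)$cbm_count),
                integer(1))
  expect_true(all(diff(tot) <= 0))
  # an excluded toxin never counts anywhere
  m2 <- flagExclusions(toyMap(), toxinIds = "c2")
  c2 <- countCBMs(toyACL, m2, 0.7)
  expect_equal(c2$cbm_count[c2$food_id == "F1"], 1L)
  expect_equal(c2$cbm_count[c2$food_id == "F2"], 1L)
})

test_that("food correlation map reproduces 2x2 phi arithmetic", {
  # disjoint CBM sets over 4 compounds, 2 each -> phi = -1
  map <- data.frame(compound_id = c("a", "b", "c", "d"),
                    food_id = c("X", "X", "Y", "Y"),
                    food_name = c("x", "x", "y", "y"),
                    excluded = FALSE, exclusion_reason = "")
  acl <- c(a = 0.9, b = 0.9, c = 0.9, d = 0.9)
  fc <- foodCorrelationMap(map, acl, 0.7)
  expect_equal(unname(fc$correlation["X", "Y"]), -1)
  expect_equal(unname(diag(fc$correlation)), c(1, 1))
  # identical CBM sets -> 1 (build two foods sharing both compounds)
  map2 <- rbind(map, data.frame(compound_id = c("a", "b"), food_id = "Z",
                                food_name = "z", excluded = FALSE,
                                exclusion_reason = ""))
  fc2 <- foodCorrelationMap(map2, acl, 0.7)
  expect_equal(unname(fc2$correlation["X", "Z"]), 1)
  # correlation matrix is positive semidefinite within tolerance
  ev <- eigen(fc2$correlation, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10))
  # zero-CBM foods are excluded with a message
  aclLow <- c(a = 0.9, b = 0.9, c = 0.1, d = 0.1)
  expect_message(fc3 <- foodCorrelationMap(map2, aclLow, 0.7), "zero CBMs")
  expect_false("Y" %in% rownames(fc3$correlation))
  expect_error(
    suppressMessages(foodCorrelationMap(map, c(a = 0.1, b = 0.1, c = 0.9,
                                               d = 0.9), 0.7)),
    "at least 2")
})

test_that("CBM table lists qualifying compounds with their foods", {
  tab <- cbmTable(data.frame(compound_id = names(toyACL), acl = toyACL),
                  toyMap(), 0.7)
  expect_equal(tab$compound_id, c("c1", "c2", "c3"))
  expect_equal(tab$foods[tab$compound_id == "c2"], "apple,tea")
  # excluded compounds never appear
  m2 <- flagExclusions(toyMap(), toxinIds = "c2")
  tab2 <- cbmTable(data.frame(compound_id = names(toyACL), acl = toyACL),
                   m2, 0.7)
  expect_false("c2" %in% tab2$compound_id)
})

test_that("food map graph export writes node and edge tables", {
  counts <- countCBMs(toyACL, toyMap(), 0.7)
  fc <- foodCorrelationMap(toyMap(), toyACL, 0.7)
  dir <- file.path(tempdir(), "foodgraph")
  paths <- writeFoodMapGraph(counts, fc, dir)
  expect_true(all(file.exists(paths)))
  nodesTab <- read.delim(paths[1])
  expect_equal(sort(nodesTab$food_id), c("F1", "F2", "F3"))
})
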