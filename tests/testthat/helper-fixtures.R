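# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# A small planted-module benchmark, cheap enough for per-module tests.
tinySpec <- function(seed = 7, ...) {
  syntheticSpec(nGenes = 120, moduleSize = 25, moduleDensity = 0.35,
                backgroundDensity = 0.02, nPositive = 20, nNegative = 80,
                seed = seed, ...)
}

tinyData <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      spec <- tinySpec()
      net <- suppressMessages(generateInteractome(spec))
      cpds <- generateCompounds(spec, net$truth)
      cached <<- list(spec = spec, net = net, cpds = cpds)
    }
    cached
  }
})

# Undirected Erdos-Renyi edge list with uniform scores.
randomEdgeList <- function(n, p, seed, score = 900L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  ids <- sprintf("N%03d", seq_len(n))
  data.frame(node_a = ids[pairs[1, keep]], node_b = ids[pairs[2, keep]],
             score = score, stringsAsFactors = FALSE)
}

pathGraphEdges <- function(nodeIds, score = 900L) {
  data.frame(node_a = nodeIds[-length(nodeIds)], node_b = nodeIds[-1],
             score = score, stringsAsFactors = FALSE)
}

writeTempTSV <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
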