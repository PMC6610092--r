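#' @importFrom stats rnorm runif rbinom plogis cor sd quantile median
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic steps in the package go
# through this so that a single integer seed makes a whole run reproducible.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a substream seed from a base seed and a stage offset, kept inside
# 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647)
}

# Deterministic key string for a settings list (used for caching and for
# tie-breaking model selection).
settingsKey <- function(settings) {
  nm <- sort(names(settings))
  paste(vapply(nm, function(k) {
    v <- settings[[k]]
    paste0(k, "=", paste(format(v, digits = 15, scientific = FALSE,
                                trim = TRUE), collapse = ","))
  }, character(1)), collapse = "|")
}

# Messages that callers may want to silence go through here.
cbmMessage <- function(...) message("[cbmNet] ", ...)
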