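#' Read protein records from FASTA
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return Named character vector of sequences; names are record ids (the
#'   first whitespace-separated token of each FASTA header).
#' @export
readProteinRecords <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  seqs
}

# Minimum Hamming distance of the shorter sequence slid (ungapped) along the
# longer one, requiring full containment of the shorter sequence.
bestOffsetMismatches <- function(s, l) {
  sv <- utf8ToInt(s); lv <- utf8ToInt(l)
  ns <- length(sv); nl <- length(lv)
  best <- ns
  for (off in 0:(nl - ns)) {
    m <- sum(sv != lv[(off + 1L):(off + ns)])
    if (m < best) best <- m
    if (best == 0L) break
  }
  best
}

#' Match protein records across databases by sequence
#'
#' Establishes correspondence between two sets of protein records using a
#' three-tier sequence-based scheme: (1) exact sequence equality;
#' (2) containment, where one sequence is a contiguous substring of the
#' other; (3) fuzzy, where the best ungapped alignment of the shorter
#' sequence against the longer has a mismatch fraction (relative to the
#' shorter length) no larger than \code{maxMismatchFrac}. Records matched in
#' an earlier tier are excluded from later tiers; left records with no match
#' are reported with tier \code{"unmatched"}. Matching within a tier is
#' greedy and one-to-one (fuzzy pairs are assigned in order of increasing
#' mismatch fraction, ties broken by record id).
#'
#' @param left,right Named character vectors of amino-acid sequences
#'   (names are record ids), e.g. from \code{\link{readProteinRecords}}.
#' @param maxMismatchFrac Maximum tolerated mismatch fraction for the fuzzy
#'   tier; default 0.05 (up to 5 percent amino-acid mismatch).
#' @return data.frame with columns \code{left_id}, \code{right_id},
#'   \code{tier} (one of exact, substring, fuzzy, unmatched) and
#'   \code{mismatch_frac} (NA for unmatched).
#' @export
matchProteinRecords <- function(left, right, maxMismatchFrac = 0.05) {
  for (side in list(left = left, right = right)) {
    if (is.null(names(side)) || any(names(side) == ""))
      stop("records must be named by record id")
  }
  if (anyDuplicated(names(left))) stop("duplicate record_id in left set")
  if (anyDuplicated(names(right))) stop("duplicate record_id in right set")
  bad <- grepl("[^A-Za-z*]", c(left, right))
  if (any(bad)) stop("sequences must contain only amino-acid letters")
  res <- data.frame(left_id = names(left), right_id = NA_character_,
                    tier = "unmatched", mismatch_frac = NA_real_,
                    stringsAsFactors = FALSE)
  freeR <- rep(TRUE, length(right))

  # tier 1: exact equality
  for (i in seq_along(left)) {
    j <- which(freeR & right == left[[i]])
    if (length(j)) {
      j <- j[1L]
      res$right_id[i] <- names(right)[j]
      res$tier[i] <- "exact"; res$mismatch_frac[i] <- 0
      freeR[j] <- FALSE
    }
  }
  # tier 2: contiguous substring containment (either direction)
  for (i in which(res$tier == "unmatched")) {
    for (j in which(freeR)) {
      if (grepl(left[[i]], right[[j]], fixed = TRUE) ||
          grepl(right[[j]], left[[i]], fixed = TRUE)) {
        res$right_id[i] <- names(right)[j]
        res$tier[i] <- "substring"; res$mismatch_frac[i] <- 0
        freeR[j] <- FALSE
        break
      }
    }
  }
  # tier 3: fuzzy, best ungapped offset, fraction over the shorter length
  cand <- list()
  for (i in which(res$tier == "unmatched")) {
    for (j in which(freeR)) {
      a <- left[[i]]; b <- right[[j]]
      s <- if (nchar(a) <= nchar(b)) a else b
      l <- if (nchar(a) <= nchar(b)) b else a
      frac <- bestOffsetMismatches(s, l) / nchar(s)
      if (frac <= maxMismatchFrac)
        cand[[length(cand) + 1L]] <- list(i = i, j = j, frac = frac)
    }
  }
  if (length(cand)) {
    ord <- order(vapply(cand, `[[`, numeric(1), "frac"),
                 vapply(cand, function(x) res$left_id[x$i], character(1)),
                 vapply(cand, function(x) names(right)[x$j], character(1)))
    for (k in ord) {
      ck <- cand[[k]]
      if (res$tier[ck$i] == "unmatched" && freeR[ck$j]) {
        res$right_id[ck$i] <- names(right)[ck$j]
        res$tier[ck$i] <- "fuzzy"; res$mismatch_frac[ck$i] <- ck$frac
        freeR[ck$j] <- FALSE
      }
    }
  }
  res
}
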