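#' Positive-class F score and per-class accuracy
#'
#' F1 of the positive class, \code{2PR / (P + R)}, the main selection metric
#' under strong class imbalance, plus the recall of each class (per-class
#' accuracy).
#'
#' @param yTrue,yPred Binary vectors (1 = anti-cancer, 0 = other) of equal
#'   length.
#' @return List with \code{f1}, \code{precision}, \code{recall},
#'   \code{accPositive}, \code{accNegative}.
#' @examples
#' fScore(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
fScore <- function(yTrue, yPred) {
  stopifnot(length(yTrue) == length(yPred))
  yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  if (!all(c(yTrue, yPred) %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  tp <- sum(yTrue == 1 & yPred == 1)
  fp <- sum(yTrue == 0 & yPred == 1)
  fn <- sum(yTrue == 1 & yPred == 0)
  tn <- sum(yTrue == 0 & yPred == 0)
  if (tp + fp + fn == 0) {
    warning("no positive predictions and no positive truths; F defined as 0")
    return(list(f1 = 0, precision = NA_real_, recall = NA_real_,
                accPositive = NA_real_, accNegative = tn / max(tn + fp, 1)))
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(f1 = f1, precision = precision, recall = recall,
       accPositive = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       accNegative = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# Platt-style logistic calibration of decision scores. Uses the regularized
# targets (N+ + 1)/(N+ + 2) and 1/(N- + 2) so the fit is well defined even
# on separable data, and balanced class weights to respect the 1:9
# imbalance. `scores` may have several columns (MMC with k > 1).
plattCalibrate <- function(scores, y) {
  scores <- as.matrix(scores)
  y <- as.integer(y)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) stop("calibration needs both classes")
  t <- ifelse(y == 1, (npos + 1) / (npos + 2), 1 / (nneg + 2))
  w <- ifelse(y == 1, length(y) / (2 * npos), length(y) / (2 * nneg))
  df <- data.frame(t = t, scores)
  fit <- suppressWarnings(stats::glm(t ~ ., data = df,
                                     family = stats::quasibinomial(),
                                     weights = w))
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  unname(co)
}

applyCalibration <- function(calibration, scores) {
  scores <- as.matrix(scores)
  eta <- calibration[1] + scores %*% calibration[-1]
  as.numeric(plogis(eta))
}

# Balanced class scatter matrices: between-class Sb and within-class Sw with
# equal class priors (compensating the label imbalance).
scatterMatrices <- function(X, y) {
  X <- as.matrix(X)
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  mu <- (mu0 + mu1) / 2
  Sb <- 0.5 * tcrossprod(mu0 - mu) + 0.5 * tcrossprod(mu1 - mu)
  cw <- function(cls, muc) {
    Xc <- sweep(X[y == cls, , drop = FALSE], 2, muc)
    crossprod(Xc) / nrow(Xc)
  }
  Sw <- 0.5 * cw(0, mu0) + 0.5 * cw(1, mu1)
  list(Sb = Sb, Sw = Sw, mu0 = mu0, mu1 = mu1)
}

#' Fit a maximum margin criterion classifier
#'
#' Computes the between-class scatter Sb and within-class scatter Sw (with
#' balanced class priors) and projects onto the top-k eigenvectors of
#' (Sb - Sw), the directions maximizing the margin between class means
#' after discounting within-class spread. A logistic calibration on the
#' projected coordinates turns the decision score into a probability.
#' Each eigenvector is oriented so the positive class projects higher.
#'
#' @param X Numeric matrix, compounds x genes.
#' @param y Binary labels (1 = anti-cancer), at least 2 samples per class.
#' @param k Retained projection dimensions; default 1 for a binary problem.
#' @param logTransformed Bookkeeping flag: were the profiles
#'   log-transformed? Recorded so prediction-time preprocessing can match.
#' @return An \linkS4class{MMCClassifier}.
#' @export
fitMMC <- function(X, y, k = 1, logTransformed = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (any(!is.finite(X))) stop("non-finite features")
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("need at least 2 samples per class")
  if (k < 1 || k > ncol(X)) stop("k must be in [1, ncol(X)]")
  sm <- scatterMatrices(X, y)
  eig <- eigen(sm$Sb - sm$Sw, symmetric = TRUE)
  proj <- eig$vectors[, seq_len(k), drop = FALSE]
  # orient: positive class mean projects at least as high as negative
  d <- (sm$mu1 - sm$mu0) %*% proj
  flip <- which(as.numeric(d) < 0)
  if (length(flip)) proj[, flip] <- -proj[, flip]
  scores <- X %*% proj
  calib <- plattCalibrate(scores, y)
  new("MMCClassifier",
      geneIds = colnames(X) %||% as.character(seq_len(ncol(X))),
      calibration = calib, logTransformed = logTransformed,
      projection = proj, eigenvalues = eig$values[seq_len(k)],
      classMeans = rbind(negative = sm$mu0, positive = sm$mu1),
      k = as.integer(k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a class-weighted linear support vector machine
#'
#' Soft-margin linear SVM with "balanced" class weights (each class weighted
#' by the inverse of its frequency, so a 1:9 positive:negative imbalance
#' gives the positive class a 9-fold weight). The decision function is
#' extracted as an explicit weight vector and bias, oriented so larger
#' values mean more anti-cancer-like, and calibrated with a Platt-style
#' logistic fit on the training decision values (replaced by out-of-fold
#' values inside cross-validation).
#'
#' @param X Numeric matrix, compounds x genes.
#' @param y Binary labels (1 = anti-cancer), both classes present.
#' @param C Soft-margin cost; default 1.
#' @param logTransformed Bookkeeping flag, see \code{\link{fitMMC}}.
#' @return An \linkS4class{SVMClassifier}.
#' @export
fitLinearSVM <- function(X, y, C = 1, logTransformed = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (any(!is.finite(X))) stop("non-finite features")
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stop("both classes must be present")
  n <- length(y)
  cw <- c("0" = n / (2 * sum(y == 0)), "1" = n / (2 * sum(y == 1)))
  fit <- e1071::svm(x = X, y = factor(y, levels = c("0", "1")),
                    kernel = "linear", cost = C, scale = FALSE,
                    class.weights = cw)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  dv <- as.numeric(X %*% w + b)
  if (mean(dv[y == 1]) < mean(dv[y == 0])) { w <- -w; b <- -b; dv <- -dv }
  calib <- plattCalibrate(dv, y)
  new("SVMClassifier",
      geneIds = colnames(X) %||% as.character(seq_len(ncol(X))),
      calibration = calib, logTransformed = logTransformed,
      weights = w, bias = b, cost = C)
}

checkProfileDim <- function(object, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != length(object@geneIds))
    stop("profile dimension (", ncol(X), ") does not match model (",
         length(object@geneIds), ")")
  X
}

#' @rdname decisionValues
#' @export
setMethod("decisionValues", "MMCClassifier", function(object, X) {
  X <- checkProfileDim(object, X)
  X %*% object@projection
})

#' @rdname decisionValues
#' @export
setMethod("decisionValues", "SVMClassifier", function(object, X) {
  X <- checkProfileDim(object, X)
  as.numeric(X %*% object@weights + object@bias)
})

#' @rdname predictACL
#' @export
setMethod("predictACL", "ACLClassifier", function(object, X) {
  applyCalibration(object@calibration, decisionValues(object, X))
})

#' @describeIn predictACL Compact display of a trained classifier.
#' @export
setMethod("show", "ACLClassifier", function(object) {
  cat(class(object), "over", length(object@geneIds), "genes",
      if (object@logTransformed) "(log-transformed features)", "\n")
})

#' Gene importance by correlation with prediction outcomes
#'
#' Pearson correlation between each gene's profile values and the model's
#' prediction outcomes across compounds. Genes with zero variance get an
#' importance of 0 by convention. The gene representation should match the
#' one the model was trained on (log-transformed or raw).
#'
#' @param predictions Numeric vector of prediction outcomes (calibrated
#'   probabilities by default, or hard labels), one per compound.
#' @param X Numeric matrix, compounds x genes, rows aligned with
#'   \code{predictions}.
#' @return Named numeric vector of per-gene importance in column order
#'   (sortable descending by the caller).
#' @export
geneImportance <- function(predictions, X) {
  X <- as.matrix(X)
  if (nrow(X) != length(predictions))
    stop("predictions must align with the rows of X")
  if (nrow(X) < 3) stop("need at least 3 compounds")
  sds <- apply(X, 2, stats::sd)
  imp <- rep(0, ncol(X))
  ok <- sds > 0 & stats::sd(predictions) > 0
  if (any(ok))
    imp[ok] <- as.numeric(cor(X[, ok, drop = FALSE], predictions))
  names(imp) <- colnames(X)
  imp
}

#' Average gene importance over an ensemble
#'
#' @param importanceList List of per-model importance vectors on the same
#'   gene set.
#' @return Arithmetic mean importance vector.
#' @export
ensembleImportance <- function(importanceList) {
  stopifnot(length(importanceList) > 0)
  Reduce(`+`, importanceList) / length(importanceList)
}

#' Write a gene-importance table
#'
#' @param importance Named numeric vector (single model or ensemble mean).
#' @param path Output TSV path; columns \code{gene_id},
#'   \code{mean_importance}, \code{rank} (1 = most important).
#' @return Invisibly, the path.
#' @export
writeImportance <- function(importance, path) {
  o <- order(importance, decreasing = TRUE)
  write.table(data.frame(gene_id = names(importance)[o],
                         mean_importance = unname(importance[o]),
                         rank = seq_along(o)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a ranked gene list (.rnk) for preranked enrichment tools
#'
#' @param importance Named numeric vector (e.g. from
#'   \code{\link{geneImportance}}).
#' @param path Output path; tab-separated gene / score, sorted descending.
#' @return Invisibly, the path.
#' @export
writeRnk <- function(importance, path) {
  o <- order(importance, decreasing = TRUE)
  write.table(data.frame(gene = names(importance)[o],
                         score = unname(importance[o])),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# --- model (de)serialization -------------------------------------------------

modelToList <- function(model) {
  common <- list(geneIds = model@geneIds, calibration = model@calibration,
                 logTransformed = model@logTransformed)
  if (is(model, "MMCClassifier")) {
    c(common, list(kind = "mmc", projection = as.numeric(model@projection),
                   k = model@k, eigenvalues = model@eigenvalues,
                   classMeans = as.numeric(model@classMeans)))
  } else if (is(model, "SVMClassifier")) {
    c(common, list(kind = "linear_svm", weights = model@weights,
                   bias = model@bias, C = model@cost))
  } else stop("unknown model class")
}

modelFromList <- function(x) {
  p <- length(x$geneIds)
  if (x$kind == "mmc") {
    new("MMCClassifier", geneIds = x$geneIds, calibration = x$calibration,
        logTransformed = x$logTransformed,
        projection = matrix(x$projection, nrow = p, ncol = x$k),
        eigenvalues = x$eigenvalues,
        classMeans = matrix(x$classMeans, nrow = 2, ncol = p,
                            dimnames = list(c("negative", "positive"),
                                            x$geneIds)),
        k = as.integer(x$k))
  } else if (x$kind == "linear_svm") {
    new("SVMClassifier", geneIds = x$geneIds, calibration = x$calibration,
        logTransformed = x$logTransformed, weights = x$weights,
        bias = x$bias, cost = x$C)
  } else stop("unknown model kind: ", x$kind)
}

#' Write / read a trained classifier as JSON
#'
#' A documented plain-text container for a trained classifier: common fields
#' \code{kind}, \code{geneIds}, \code{calibration}, \code{logTransformed},
#' plus kind-specific fields (projection, eigenvalues, class means and k for
#' MMC; weights, bias and C for the linear SVM).
#'
#' @param model A trained \linkS4class{ACLClassifier}.
#' @param path JSON file path.
#' @return \code{writeModelJSON}: the path, invisibly.
#'   \code{readModelJSON}: the reconstructed classifier.
#' @export
writeModelJSON <- function(model, path) {
  jsonlite::write_json(modelToList(model), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  modelFromList(x)
}
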