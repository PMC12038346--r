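# Linear-SVM classification of connectivity features with stratified
# cross-validation and ranked-weight extraction.

standardizeFit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

standardizeApply <- function(X, sc) scale(X, center = sc$mu, scale = sc$sd)

# Stratified fold assignment: within each class, subjects are shuffled
# (seeded) and dealt to folds round-robin, so every training fold contains
# both classes whenever each class has >= k subjects... classes smaller than
# k raise a stratification error.
stratifiedFolds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withSeed(as.integer(seed), {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      stopIfNot(length(idx) >= 2L, "need >= 2 subjects per class")
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

fitLinearSvm <- function(X, y, cost = 1) {
  e1071::svm(x = X, y = y, kernel = "linear", cost = cost, scale = FALSE)
}

svmWeights <- function(model) {
  w <- drop(t(model$coefs) %*% model$SV)
  stats::setNames(as.numeric(w), colnames(model$SV))
}

#' Cross-validated linear SVM on connectivity features
#'
#' Stratified k-fold cross-validation of a linear support vector machine
#' (fixed cost C = 1). Features are standardized to zero mean / unit
#' variance using statistics fitted on each training fold only; metrics are
#' pooled over all held-out predictions. Sensitivity treats the
#' \code{positiveClass} (the impaired group) as cases. Deterministic given
#' the seed.
#'
#' @param X subjects x features numeric matrix (finite entries).
#' @param y group label per subject (two classes, each >= 2 subjects).
#' @param kFolds folds (default 10).
#' @param seed fold-assignment seed.
#' @param positiveClass label counted as positive; default the first level
#'   encountered.
#' @param band band name recorded in the report.
#' @param topFrac fraction of features kept in the top set (default 0.05,
#'   i.e. 13 of 276).
#' @param cost SVM cost parameter.
#' @return a \code{\link{ClassifierReport}}; ranked weights come from a
#'   single fit on the fully standardized table (see
#'   \code{\link{rankWeights}}).
#' @export
crossvalSvm <- function(X, y, kFolds = 10L, seed = 1L, positiveClass = NULL,
                        band = NA_character_, topFrac = 0.05, cost = 1) {
  X <- as.matrix(X)
  stopIfNot(all(is.finite(X)), "feature table contains non-finite entries")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.character(y)
  classes <- unique(y)
  stopIfNot(length(classes) == 2L, "exactly two classes required")
  if (is.null(positiveClass)) positiveClass <- classes[1L]
  stopIfNot(positiveClass %in% classes, "unknown 'positiveClass'")
  negativeClass <- setdiff(classes, positiveClass)
  yf <- factor(y, levels = c(negativeClass, positiveClass))
  folds <- stratifiedFolds(y, kFolds, seed)
  pred <- character(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    stopIfNot(length(unique(y[tr])) == 2L,
              "a training fold lost a class: reduce kFolds or add subjects")
    sc <- standardizeFit(X[tr, , drop = FALSE])
    model <- fitLinearSvm(standardizeApply(X[tr, , drop = FALSE], sc),
                          droplevels(yf[tr]), cost)
    pred[te] <- as.character(
      stats::predict(model, standardizeApply(X[te, , drop = FALSE], sc)))
  }
  tp <- sum(pred == positiveClass & y == positiveClass)
  tn <- sum(pred == negativeClass & y == negativeClass)
  fn <- sum(pred == negativeClass & y == positiveClass)
  fp <- sum(pred == positiveClass & y == negativeClass)
  rw <- rankWeights(X, yf, topFrac = topFrac, cost = cost)
  new("ClassifierReport",
      accuracy = (tp + tn) / length(y),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      foldAssignments = as.integer(folds), rankedWeights = rw$ranked,
      topSet = rw$topSet, band = as.character(band),
      positiveClass = positiveClass, seed = as.integer(seed))
}

#' Rank features by absolute linear-SVM weight
#'
#' Fits one linear SVM on the fully standardized table and ranks features by
#' the absolute value of their hyperplane coefficient, descending; ties are
#' broken by the fixed feature order. The top set keeps
#' \code{floor(topFrac * n)} features (13 of 276 at the default 5\%).
#'
#' @param X subjects x features matrix.
#' @param y two-class labels (character or factor).
#' @param topFrac fraction in (0, 1].
#' @param cost SVM cost.
#' @return list with \code{ranked} (data.frame \code{feature},
#'   \code{weight}) and \code{topSet}.
#' @export
rankWeights <- function(X, y, topFrac = 0.05, cost = 1) {
  stopIfNot(topFrac > 0 && topFrac <= 1, "'topFrac' must lie in (0, 1]")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  sc <- standardizeFit(X)
  model <- fitLinearSvm(standardizeApply(X, sc), factor(y), cost)
  w <- abs(svmWeights(model))
  # missing names can occur only if e1071 drops them; guard
  if (is.null(names(w)) || anyNA(names(w))) names(w) <- colnames(X)
  ord <- order(-w, seq_along(w))
  ranked <- data.frame(feature = colnames(X)[ord], weight = unname(w[ord]),
                       stringsAsFactors = FALSE)
  k <- max(1L, floor(topFrac * ncol(X)))
  if (topFrac == 1) k <- ncol(X)
  list(ranked = ranked, topSet = ranked$feature[seq_len(k)])
}

#' @rdname ClassifierReport-class
#' @export
setMethod("classifierMetrics", "ClassifierReport", function(x)
  c(accuracy = x@accuracy, sensitivity = x@sensitivity,
    specificity = x@specificity))

#' @rdname ClassifierReport-class
#' @export
setMethod("rankedWeights", "ClassifierReport", function(x) x@rankedWeights)

#' @rdname ClassifierReport-class
#' @export
setMethod("topFeatures", "ClassifierReport", function(x) x@topSet)

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf(
    "ClassifierReport band '%s': accuracy %.3f, sensitivity %.3f, specificity %.3f; top set %d features\n",
    object@band, object@accuracy, object@sensitivity, object@specificity,
    length(object@topSet)))
})

#' Serialize a classifier report
#'
#' @param report a \code{\link{ClassifierReport}}.
#' @param jsonFile,weightsFile output paths (either may be \code{NULL}).
#' @export
writeClassifierReport <- function(report, jsonFile = NULL,
                                  weightsFile = NULL) {
  if (!is.null(jsonFile))
    jsonlite::write_json(
      list(band = report@band, accuracy = report@accuracy,
           sensitivity = report@sensitivity,
           specificity = report@specificity,
           positiveClass = report@positiveClass, seed = report@seed,
           topSet = report@topSet),
      jsonFile, auto_unbox = TRUE, digits = NA)
  if (!is.null(weightsFile))
    utils::write.table(report@rankedWeights, weightsFile, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(report)
}
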