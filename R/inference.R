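# Group-level inference: pooled-variance t tests, max-statistic permutation
# correction, Benjamini-Hochberg FDR, and summary-statistic ANOVA /
# chi-square for cohort characteristics tables.

#' Pooled-variance two-sample t test
#'
#' Independent-samples t with the pooled variance estimate, so
#' df = n1 + n2 - 2 (80 for a 40-vs-42 comparison).
#'
#' @param x,y numeric vectors (>= 2 finite values each).
#' @return list with \code{t} and \code{df}; \code{t} is \code{NA} when the
#'   pooled variance is zero.
#' @export
ttestInd <- function(x, y) {
  stopIfNot(length(x) >= 2L && length(y) >= 2L, "need >= 2 values per group")
  stopIfNot(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (sp2 <= 0) return(list(t = NA_real_, df = df))
  list(t = (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2)), df = df)
}

# Vectorized pooled t over feature columns for a fixed group-1 index set.
colTstats <- function(X, idx1) {
  idx2 <- setdiff(seq_len(nrow(X)), idx1)
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- colMeans(X[idx1, , drop = FALSE])
  m2 <- colMeans(X[idx2, , drop = FALSE])
  v1 <- colSums(sweep(X[idx1, , drop = FALSE], 2, m1)^2)
  v2 <- colSums(sweep(X[idx2, , drop = FALSE], 2, m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  t[sp2 <= 0] <- NA_real_
  t
}

#' Max-statistic permutation threshold (nonparametric mapping)
#'
#' Family-wise inference over a feature set by label permutation: under each
#' relabelling the maximum |t| over features is recorded; the critical
#' threshold is the (1 - alpha) quantile of that null distribution and a
#' feature is flagged when its observed |t| exceeds it. When the number of
#' distinct group-1 index sets does not exceed \code{nPerm} the scheme
#' enumerates all of them exhaustively instead of sampling (recorded in the
#' result). Deterministic given \code{seed}.
#'
#' @param features subjects x features numeric matrix.
#' @param labels group label per subject (exactly two levels present).
#' @param nPerm permutations (>= 100 unless exhaustive enumeration applies).
#' @param alpha significance level; \code{alpha >= 1} flags every feature.
#' @param seed RNG seed for the permutation draws.
#' @return a \code{\link{GroupComparisonResult}}; p-values are the
#'   max-statistic-corrected exceedance probabilities.
#' @export
permutationThreshold <- function(features, labels, nPerm = 5000L,
                                 alpha = 0.05, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  lv <- unique(labels)
  stopIfNot(length(lv) == 2L, "exactly two groups required")
  idx1 <- which(labels == lv[1L])
  n <- nrow(features)
  stopIfNot(length(idx1) >= 2L && n - length(idx1) >= 2L,
            "need >= 2 subjects per group")
  tObs <- colTstats(features, idx1)
  df <- n - 2L
  nDistinct <- choose(n, length(idx1))
  exhaustive <- nDistinct <= nPerm
  if (exhaustive) {
    sets <- utils::combn(n, length(idx1))
    maxNull <- apply(sets, 2L, function(ix)
      max(abs(colTstats(features, ix)), na.rm = TRUE))
    p <- vapply(abs(tObs), function(tt) mean(maxNull >= tt - 1e-12), 0)
  } else {
    stopIfNot(nPerm >= 100L, "'nPerm' must be >= 100")
    maxNull <- withSeed(as.integer(seed), vapply(seq_len(nPerm), function(b) {
      ix <- sample.int(n, length(idx1))
      max(abs(colTstats(features, ix)), na.rm = TRUE)
    }, 0))
    p <- vapply(abs(tObs), function(tt)
      (1 + sum(maxNull >= tt - 1e-12)) / (nPerm + 1), 0)
  }
  critT <- if (alpha >= 1) -Inf else {
    srt <- sort(maxNull)
    srt[min(length(srt), max(1L, ceiling((1 - alpha) * length(srt))))]
  }
  sig <- abs(tObs) > critT
  sig[is.na(sig)] <- FALSE
  tClean <- tObs
  new("GroupComparisonResult", t = tClean, df = as.numeric(df),
      critT = critT, pValues = p, sigMask = unname(sig),
      method = "permutation_max",
      nPerm = as.integer(if (exhaustive) ncol(sets) else nPerm),
      alpha = alpha, seed = as.integer(seed), exhaustive = exhaustive)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up FDR selection at level \code{q} (a thin wrapper over
#' \code{stats::p.adjust(method = "BH")}).
#'
#' @param p p-values in [0, 1].
#' @param q FDR level.
#' @return logical mask, \code{TRUE} for discoveries; empty input gives an
#'   empty mask.
#' @export
fdrBH <- function(p, q = 0.05) {
  if (length(p) == 0L) return(logical(0))
  stopIfNot(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

#' FDR-corrected t-test comparison over features
#'
#' Per-feature pooled t tests with two-sided parametric p-values and a
#' Benjamini-Hochberg mask; the route used for ROI-level modulation-index
#' comparisons.
#'
#' @param features subjects x features matrix.
#' @param labels two-level group labels.
#' @param q FDR level.
#' @return a \code{\link{GroupComparisonResult}} with
#'   \code{method = "fdr_bh"}.
#' @export
ttestFDR <- function(features, labels, q = 0.05) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  lv <- unique(labels)
  stopIfNot(length(lv) == 2L, "exactly two groups required")
  idx1 <- which(labels == lv[1L])
  t <- colTstats(features, idx1)
  df <- nrow(features) - 2L
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  mask <- fdrBH(ifelse(is.na(p), 1, p), q)
  new("GroupComparisonResult", t = t, df = as.numeric(df), critT = NA_real_,
      pValues = p, sigMask = mask, method = "fdr_bh", nPerm = 0L,
      alpha = q, seed = NA_integer_, exhaustive = FALSE)
}

#' One-way ANOVA from summary statistics
#'
#' Reconstructs between- and within-group sums of squares from per-group
#' means, SDs and sizes (as printed in a participants table) and returns the
#' F ratio.
#'
#' @param means,sds,ns equal-length vectors (>= 2 groups, all n >= 2).
#' @return list with \code{F}, \code{df1}, \code{df2} and \code{p}.
#' @examples
#' anovaFromSummary(c(7.92, 8.32, 8.83), c(2.28, 1.45, 2.21), c(40, 40, 42))
#' @export
anovaFromSummary <- function(means, sds, ns) {
  k <- length(means)
  stopIfNot(k >= 2L && length(sds) == k && length(ns) == k,
            "need >= 2 groups with matching means/sds/ns")
  stopIfNot(all(ns >= 2), "every group needs n >= 2")
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1L; df2 <- N - k
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = as.integer(df2),
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Pearson chi-square from a contingency table
#'
#' Pearson's test with expected counts from the margins, no continuity
#' correction; df = (r - 1)(c - 1).
#'
#' @param counts r x c matrix of nonnegative integer counts with positive
#'   margins.
#' @return list with \code{X2}, \code{df} and \code{p}.
#' @examples
#' chisqFromCounts(matrix(c(25, 15, 28, 12, 23, 19), nrow = 3, byrow = TRUE))
#' @export
chisqFromCounts <- function(counts) {
  counts <- as.matrix(counts)
  stopIfNot(all(counts >= 0) && all(counts == round(counts)),
            "counts must be nonnegative integers")
  stopIfNot(all(rowSums(counts) > 0) && all(colSums(counts) > 0),
            "zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(X2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' @rdname GroupComparisonResult-class
#' @export
setMethod("tStatistics", "GroupComparisonResult", function(x) x@t)

#' @rdname GroupComparisonResult-class
#' @export
setMethod("significanceMask", "GroupComparisonResult", function(x) x@sigMask)

#' @rdname GroupComparisonResult-class
#' @export
setMethod("criticalT", "GroupComparisonResult", function(x) x@critT)

setMethod("show", "GroupComparisonResult", function(object) {
  cat(sprintf(
    "GroupComparisonResult (%s): %d features, df = %g, %d significant at alpha = %g%s\n",
    object@method, length(object@t), object@df, sum(object@sigMask),
    object@alpha,
    if (object@method == "permutation_max")
      sprintf(" (crit |t| = %.3f, %d permutations%s)", object@critT,
              object@nPerm, if (object@exhaustive) ", exhaustive" else "")
    else ""))
})

#' Write a group comparison as TSV plus a JSON provenance block
#'
#' @param res a \code{\link{GroupComparisonResult}}.
#' @param featureNames names for the feature rows.
#' @param tsvFile,jsonFile output paths (either may be \code{NULL}).
#' @export
writeComparison <- function(res, featureNames, tsvFile = NULL,
                            jsonFile = NULL) {
  if (!is.null(tsvFile))
    utils::write.table(
      data.frame(feature = featureNames, t = res@t, p = res@pValues,
                 sig = res@sigMask),
      tsvFile, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(jsonFile))
    jsonlite::write_json(
      list(method = res@method, nPerm = res@nPerm, alpha = res@alpha,
           seed = res@seed, df = res@df, critT = res@critT,
           exhaustive = res@exhaustive),
      jsonFile, auto_unbox = TRUE, digits = NA)
  invisible(res)
}
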