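test_that("pooled t test matches hand computation and printed df", {
  x <- rnorm(40); y <- rnorm(42)
  expect_equal(ttestInd(x, y)$df, 80L)
  expect_equal(ttestInd(c(1, 2, 3), c(4, 5, 6))$t, -3.674, tolerance = 1e-3)
  # agreement with the standard pooled-variance route
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ttestInd(x, y)$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ttestInd(1:5, 1:5)$t, 0)
  expect_true(is.na(ttestInd(rep(1, 3), rep(1, 4))$t))
})

test_that("permutation thresholding is deterministic and monotone in alpha", {
  nf <- nullFeatures(nPerGroup = 8L, nFeat = 6L, seed = 3L)
  r1 <- permutationThreshold(nf$X, nf$labels, nPerm = 300L, seed = 11L)
  r2 <- permutationThreshold(nf$X, nf$labels, nPerm = 300L, seed = 11L)
  expect_identical(criticalT(r1), criticalT(r2))
  expect_identical(significanceMask(r1), significanceMask(r2))
  crits <- vapply(c(0.01, 0.05, 0.2),
                  function(a) criticalT(permutationThreshold(
                    nf$X, nf$labels, nPerm = 300L, alpha = a, seed = 11L)), 0)
  expect_true(all(diff(crits) <= 0))
  rAll <- permutationThreshold(nf$X, nf$labels, nPerm = 300L, alpha = 1,
                               seed = 11L)
  expect_true(all(significanceMask(rAll)))
})

test_that("tiny cohorts fall back to exhaustive enumeration that matches an
          independent oracle", {
  X <- matrix(withr::with_seed(5, rnorm(8)), ncol = 1)
  labels <- rep(c("impaired", "control"), each = 4L)
  res <- permutationThreshold(X, labels, nPerm = 500L, seed = 1L)
  expect_true(res@exhaustive)
  expect_equal(res@nPerm, 70L)
  # oracle: enumerate all 70 group-1 assignments with a from-scratch t
  tOf <- function(ix) {
    a <- X[ix, 1]; b <- X[-ix, 1]
    sp <- sqrt(((3 * var(a)) + (3 * var(b))) / 6)
    (mean(a) - mean(b)) / (sp * sqrt(1 / 4 + 1 / 4))
  }
  tsAll <- apply(combn(8, 4), 2, tOf)
  tObs <- tOf(1:4)
  expect_equal(res@pValues[1L], mean(abs(tsAll) >= abs(tObs) - 1e-12))
})

test_that("a large planted shift is detected by the max-statistic scheme", {
  hits <- vapply(1:20, function(s) {
    nf <- nullFeatures(nPerGroup = 20L, nFeat = 10L, seed = 400L + s)
    X <- nf$X
    X[nf$labels == "impaired", 4L] <- X[nf$labels == "impaired", 4L] + 3
    res <- permutationThreshold(X, nf$labels, nPerm = 200L, seed = s)
    significanceMask(res)[4L]
  }, NA)
  expect_gt(mean(hits), 0.95)
})

test_that("BH selection matches the step-up rule", {
  expect_equal(fdrBH(c(0.001, 0.2, 0.9), 0.05), c(TRUE, FALSE, FALSE))
  expect_false(any(fdrBH(rep(1, 5))))
  expect_true(all(fdrBH(rep(0, 5))))
  expect_length(fdrBH(numeric(0)), 0L)
  expect_error(fdrBH(c(0.2, 1.4)), "0, 1")
})

test_that("summary-statistic ANOVA reproduces printed group comparisons", {
  # cohort characteristics: ages of three groups given as mean/SD/n
  res <- anovaFromSummary(c(7.92, 8.32, 8.83), c(2.28, 1.45, 2.21),
                          c(40, 40, 42))
  expect_equal(res$F, 2.103, tolerance = 0.02)
  expect_equal(res$df1, 2L)
  expect_equal(res$df2, 119L)
  expect_equal(anovaFromSummary(c(5, 5), c(1, 2), c(10, 10))$F, 0)
  # two groups: F equals the squared pooled t
  x <- rnorm(12); y <- rnorm(15, 1)
  Ft <- anovaFromSummary(c(mean(x), mean(y)), c(sd(x), sd(y)),
                         c(12, 15))$F
  expect_equal(Ft, ttestInd(x, y)$t^2, tolerance = 1e-10)
  expect_error(anovaFromSummary(c(1, 2), c(1, 1), c(1, 5)), "n >= 2")
})

test_that("Pearson chi-square reproduces printed contingency statistics", {
  sex <- matrix(c(25, 15, 28, 12, 23, 19), nrow = 3, byrow = TRUE)
  res <- chisqFromCounts(sex)
  expect_equal(res$X2, 2.026, tolerance = 0.001)
  expect_equal(res$df, 2L)
  lat <- matrix(c(10, 7, 23, 13, 14, 13), nrow = 2, byrow = TRUE)
  expect_equal(chisqFromCounts(lat)$X2, 5.502, tolerance = 0.001)
  # independence: table proportional to its margins
  ind <- outer(c(2, 3), c(1, 4, 5))
  expect_equal(chisqFromCounts(ind)$X2, 0, tolerance = 1e-12)
  expect_error(chisqFromCounts(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("FDR-corrected t route flags a planted ROI difference", {
  nf <- nullFeatures(nPerGroup = 15L, nFeat = 8L, seed = 21L)
  X <- nf$X
  X[nf$labels == "impaired", 2L] <- X[nf$labels == "impaired", 2L] + 2.5
  res <- ttestFDR(X, nf$labels)
  expect_true(significanceMask(res)[2L])
  expect_equal(res@df, 28)
  tf <- withr::local_tempfile(fileext = ".tsv")
  jf <- withr::local_tempfile(fileext = ".json")
  writeComparison(res, colnames(X), tf, jf)
  tab <- read.delim(tf)
  expect_equal(tab$feature, colnames(X))
  expect_equal(tab$t, unname(tStatistics(res)), tolerance = 1e-6)
})
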