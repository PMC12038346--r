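makeFeatures <- function(nPerGroup, nFeat, shift, shiftCols, seed,
                         labels = c("impaired", "control")) {
  X <- withr::with_seed(seed, matrix(rnorm(2 * nPerGroup * nFeat),
                                     2 * nPerGroup))
  colnames(X) <- paste0("f", seq_len(nFeat))
  y <- rep(labels, each = nPerGroup)
  X[y == labels[1L], shiftCols] <- X[y == labels[1L], shiftCols] + shift
  list(X = X, y = y)
}

test_that("a separable planted effect is classified perfectly", {
  ft <- makeFeatures(10L, 6L, shift = 20, shiftCols = 1L, seed = 1L)
  rep1 <- crossvalSvm(ft$X, ft$y, kFolds = 10L, seed = 2L)
  expect_equal(classifierMetrics(rep1)[["accuracy"]], 1)
  expect_equal(classifierMetrics(rep1)[["sensitivity"]], 1)
  expect_equal(classifierMetrics(rep1)[["specificity"]], 1)
  # determinism
  rep2 <- crossvalSvm(ft$X, ft$y, kFolds = 10L, seed = 2L)
  expect_identical(classifierMetrics(rep1), classifierMetrics(rep2))
  expect_identical(rep1@foldAssignments, rep2@foldAssignments)
  expect_identical(topFeatures(rep1), topFeatures(rep2))
})

test_that("metrics agree with a confusion-matrix oracle", {
  ft <- makeFeatures(12L, 8L, shift = 1.2, shiftCols = 1:2, seed = 3L)
  rep1 <- crossvalSvm(ft$X, ft$y, kFolds = 6L, seed = 4L,
                      positiveClass = "impaired")
  # recompute held-out predictions independently from the stored folds
  folds <- rep1@foldAssignments
  pred <- character(length(ft$y))
  for (f in unique(folds)) {
    tr <- folds != f
    mu <- colMeans(ft$X[tr, ]); sdv <- apply(ft$X[tr, ], 2, sd)
    Ztr <- scale(ft$X[tr, ], mu, sdv); Zte <- scale(ft$X[!tr, , drop = FALSE],
                                                    mu, sdv)
    m <- e1071::svm(Ztr, factor(ft$y[tr], levels = c("control", "impaired")),
                    kernel = "linear", cost = 1, scale = FALSE)
    pred[!tr] <- as.character(predict(m, Zte))
  }
  cm <- table(factor(pred, c("impaired", "control")),
              factor(ft$y, c("impaired", "control")))
  expect_equal(classifierMetrics(rep1)[["accuracy"]],
               sum(diag(cm)) / sum(cm))
  expect_equal(classifierMetrics(rep1)[["sensitivity"]],
               cm[1, 1] / sum(cm[, 1]))
  expect_equal(classifierMetrics(rep1)[["specificity"]],
               cm[2, 2] / sum(cm[, 2]))
})

test_that("label-shuffled null data classifies at chance", {
  accs <- vapply(1:50, function(s) {
    nf <- nullFeatures(nPerGroup = 10L, nFeat = 20L, seed = 600L + s)
    y <- withr::with_seed(s, sample(nf$labels))
    classifierMetrics(crossvalSvm(nf$X, y, kFolds = 10L,
                                  seed = s))[["accuracy"]]
  }, 0)
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.60)
})

test_that("weight ranking sizes the top set and finds planted features", {
  ft <- makeFeatures(20L, 276L, shift = 0, shiftCols = 1L, seed = 5L)
  rk <- rankWeights(ft$X, ft$y, topFrac = 0.05)
  expect_length(rk$topSet, 13L)
  expect_setequal(rk$ranked$feature, colnames(ft$X))
  expect_true(all(diff(rk$ranked$weight) <= 1e-12))
  rkAll <- rankWeights(ft$X, ft$y, topFrac = 1)
  expect_length(rkAll$topSet, 276L)
  # a single strongly informative feature ranks first almost always
  firsts <- vapply(1:20, function(s) {
    ft2 <- makeFeatures(15L, 30L, shift = 3, shiftCols = 7L, seed = 700L + s)
    rankWeights(ft2$X, ft2$y, topFrac = 0.05)$ranked$feature[1L]
  }, "")
  expect_gt(mean(firsts == "f7"), 0.95)
})

test_that("dropping the top feature hurts more than dropping a weak one", {
  deltas <- vapply(1:20, function(s) {
    ft <- makeFeatures(12L, 12L, shift = 1.6, shiftCols = 3L, seed = 800L + s)
    rk <- rankWeights(ft$X, ft$y)
    top <- rk$ranked$feature[1L]
    weak <- rk$ranked$feature[nrow(rk$ranked)]
    accWithout <- function(drop)
      classifierMetrics(crossvalSvm(ft$X[, setdiff(colnames(ft$X), drop)],
                                    ft$y, kFolds = 6L,
                                    seed = s))[["accuracy"]]
    accWithout(weak) - accWithout(top)
  }, 0)
  expect_gt(mean(deltas), 0)
})

test_that("network annotation maps pair features to network classes", {
  atlas <- loadAtlas()
  one <- networkAnnotate("L_V2--R_INS", atlas)
  expect_equal(one$networkPair, "SN-VN")
  expect_equal(one$count, 1L)
  empty <- networkAnnotate(character(0), atlas)
  expect_equal(nrow(empty), 0L)
  expect_error(networkAnnotate("L_V2--R_XX", atlas), "unknown ROI")
  # planted effects confined to DMN-CEN pairs dominate the recovered classes
  dmn <- atlas$roi[atlas$network == "DMN"]
  cen <- atlas$roi[atlas$network == "CEN"]
  pairs <- roiPairs(atlas$roi)
  dmncen <- pairs$name[(pairs$name %in%
    as.vector(outer(dmn, cen, paste, sep = "--"))) |
    (pairs$name %in% as.vector(outer(cen, dmn, paste, sep = "--")))]
  ft <- makeFeatures(20L, 276L, shift = 2, seed = 9L,
                     shiftCols = match(dmncen[1:6], pairs$name))
  colnames(ft$X) <- pairs$name
  top <- rankWeights(ft$X, ft$y)$topSet
  ann <- networkAnnotate(top, atlas)
  expect_equal(ann$networkPair[1L], "CEN-DMN")
})

test_that("classifier report serializes to JSON and TSV", {
  ft <- makeFeatures(8L, 10L, shift = 2, shiftCols = 1L, seed = 11L)
  rep1 <- crossvalSvm(ft$X, ft$y, kFolds = 4L, seed = 1L, band = "alpha")
  jf <- withr::local_tempfile(fileext = ".json")
  wf <- withr::local_tempfile(fileext = ".tsv")
  writeClassifierReport(rep1, jf, wf)
  j <- jsonlite::fromJSON(jf)
  expect_equal(j$accuracy, rep1@accuracy)
  expect_equal(j$band, "alpha")
  w <- read.delim(wf)
  expect_equal(w$feature, rep1@rankedWeights$feature)
})
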