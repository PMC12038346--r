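test_that("cross-spectrum is Hermitian with the expected structure", {
  rec <- noiseRecording(nCh = 3L, nEpochs = 50L, seed = 2L)
  cs <- crossSpectrum(rec, fmax = 50)
  S <- cs@S
  for (k in c(1L, dim(S)[3L])) {
    expect_equal(S[, , k], Conj(t(S[, , k])), tolerance = 1e-12)
    expect_true(all(Re(diag(S[, , k])) >= 0))
    expect_true(all(abs(Im(diag(S[, , k]))) < 1e-12))
  }
  # two independent white-noise channels: mean coherence magnitude is small
  coh <- vapply(seq_len(dim(S)[3L]), function(k)
    Mod(S[1, 2, k]) / sqrt(Re(S[1, 1, k]) * Re(S[2, 2, k])), 0)
  expect_lt(mean(coh), 0.15)
  # a duplicated channel has coherence magnitude 1 at every bin
  recDup <- identicalPairRecording()
  csDup <- crossSpectrum(recDup, fmax = 50)
  cohDup <- vapply(seq_len(length(csDup@freqs)), function(k)
    Mod(csDup@S[1, 2, k]) / sqrt(Re(csDup@S[1, 1, k]) * Re(csDup@S[2, 2, k])),
    0)
  expect_equal(cohDup, rep(1, length(cohDup)), tolerance = 1e-9)
  # a pure sinusoid peaks in its own band
  x <- sin(2 * pi * 10 * seq_len(20 * 128) / 128)
  cs10 <- crossSpectrum(segment(matrix(x, 1), 1, 128), fmax = 50)
  expect_true(cs10@freqs[which.max(Re(cs10@S[1, 1, ]))] >= 8 &&
                cs10@freqs[which.max(Re(cs10@S[1, 1, ]))] <= 13)
  expect_warning(crossSpectrum(segment(matrix(rnorm(128), 1), 1, 128)),
                 "single epoch")
})

test_that("lagged coherence hits its analytic extremes", {
  # noiseless quadrature pair at full strength -> ~1
  rec <- generateSubject(quadratureDesign(), "control", 11L)
  cs <- crossSpectrum(rec, fmax = 20)
  expect_gt(laggedCoherence(cs, c(1L, 2L), alphaBand()), 0.98)
  # identical signals (pure zero-lag coupling) -> 0
  csId <- crossSpectrum(identicalPairRecording(), fmax = 50)
  expect_equal(laggedCoherence(csId, c(1L, 2L), alphaBand()), 0)
  # symmetric in pair order, addressable by name
  expect_equal(laggedCoherence(cs, c(2L, 1L), alphaBand()),
               laggedCoherence(cs, c(1L, 2L), alphaBand()))
  expect_equal(laggedCoherence(cs, c("roi1", "roi2"), alphaBand()),
               laggedCoherence(cs, c(1L, 2L), alphaBand()))
})

test_that("estimates increase with planted coupling strength", {
  strengths <- c(0.2, 0.5, 0.8)
  means <- vapply(strengths, function(m) {
    vals <- vapply(1:20, function(s) {
      d <- quadratureDesign(strength = m, nEpochs = 30L, seed = s)
      rec <- generateSubject(d, "control", 100L + s)
      laggedCoherence(crossSpectrum(rec, fmax = 20), c(1L, 2L), alphaBand())
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("matrix values equal a brute-force recomputation from raw FFTs", {
  rec <- noiseRecording(nCh = 4L, nEpochs = 20L, seed = 3L)
  mats <- connectivityMatrices(rec, analysisBands())
  for (bn in names(mats)) {
    v <- connectivityValues(mats[[bn]])
    b <- analysisBands()[[bn]]
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(v[i, j], bruteLagCoh(rec, i, j, b), tolerance = 1e-10)
  }
})

test_that("values stay in [0, 1] over many random inputs", {
  for (s in 1:200) {
    rec <- noiseRecording(nCh = 2L, nEpochs = 5L, len = 64L, seed = s)
    cs <- crossSpectrum(rec, fmax = 50)
    v <- laggedCoherence(cs, c(1L, 2L), bandSpec("broad", 2, 50))
    expect_true(is.finite(v) && v >= 0 && v <= 1)
  }
})

test_that("instantaneous mixing does not inflate lagged coherence", {
  rec <- noiseRecording(nCh = 2L, nEpochs = 60L, seed = 6L)
  base <- laggedCoherence(crossSpectrum(rec, fmax = 50), c(1L, 2L),
                          alphaBand())
  A <- matrix(c(0.9, 0.4, 0.4, 0.9), 2)  # real instantaneous mixing
  d <- epochData(rec)
  for (e in seq_len(dim(d)[1L])) d[e, , ] <- A %*% d[e, , ]
  mixed <- epochedRecording(d, samplingRate(rec))
  mixedVal <- laggedCoherence(crossSpectrum(mixed, fmax = 50), c(1L, 2L),
                              alphaBand())
  expect_lt(mixedVal, base + 0.05)
})

test_that("vectorization yields n(n-1)/2 features in fixed pair order", {
  atlas <- loadAtlas()
  expect_equal(nrow(atlas), 24L)
  pairs <- roiPairs(atlas$roi)
  expect_equal(nrow(pairs), 276L)
  expect_equal(pairs$name[1L], "L_V1--R_V1")
  expect_equal(nrow(roiPairs(paste0("r", 1:4))), 6L)
  rec <- noiseRecording(nCh = 4L, nEpochs = 10L, seed = 4L)
  cm <- connectivityMatrices(rec, analysisBands()["alpha"])$alpha
  v <- connectivityVector(cm)
  expect_length(v, 6L)
  expect_named(v, roiPairs(channelNames(rec))$name)
  # relabelling equivariance: permuting channels then unpermuting the matrix
  perm <- c(3L, 1L, 4L, 2L)
  d <- epochData(rec)[, perm, , drop = FALSE]
  recP <- epochedRecording(d, samplingRate(rec),
                           channelNames = channelNames(rec)[perm])
  cmP <- connectivityMatrices(recP, analysisBands()["alpha"])$alpha
  vP <- connectivityValues(cmP)[channelNames(rec), channelNames(rec)]
  expect_equal(vP, connectivityValues(cm), tolerance = 1e-12)
})

test_that("connectivity output writers produce readable tables", {
  rec <- noiseRecording(nCh = 3L, nEpochs = 5L, seed = 7L)
  cm <- connectivityMatrices(rec, analysisBands()["alpha"])$alpha
  mf <- withr::local_tempfile(fileext = ".tsv")
  vf <- withr::local_tempfile(fileext = ".csv")
  writeConnectivity(cm, mf, vf)
  m <- as.matrix(read.delim(mf, row.names = 1))
  expect_equal(unname(m), unname(connectivityValues(cm)), tolerance = 1e-12)
  v <- read.csv(vf, check.names = FALSE)
  expect_equal(names(v), roiPairs(channelNames(rec))$name)
})
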