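test_that("phase extraction tracks a pure oscillation's frequency", {
  fs <- 128
  t <- seq_len(10 * fs) / fs
  pa <- phaseAmplitudeExtract(sin(2 * pi * 6 * t), rate = fs)
  slope <- coef(lm(unwrapPhase(pa$phase) ~ seq_along(pa$phase)))[2L] * fs
  expect_lt(abs(slope - 2 * pi * 6) / (2 * pi * 6), 0.01)
  expect_true(all(pa$amplitude >= 0))
  # constant-envelope carrier: amplitude nearly constant
  pa2 <- phaseAmplitudeExtract(cos(2 * pi * 40 * t), rate = fs)
  expect_lt(sd(pa2$amplitude) / mean(pa2$amplitude), 0.05)
  expect_error(phaseAmplitudeExtract(rnorm(10 * fs),
                                     ampBand = bandSpec("hi", 60, 70),
                                     rate = fs),
               "Nyquist")
})

test_that("modulation index matches its closed-form extremes and oracle", {
  nPts <- 18L * 20000L
  phase <- seq(-pi + pi / nPts, pi - pi / nPts, length.out = nPts)
  # uniform amplitude -> MI 0; single-bin concentration -> MI 1
  expect_equal(modulationIndex(phase, rep(2.5, nPts)), 0)
  amp <- as.numeric(phase > -pi & phase <= -pi + 2 * pi / 18)
  expect_equal(modulationIndex(phase, amp + 1e-12), 1, tolerance = 1e-9)
  # envelope 1 + cos(phase): compare against the closed-form binned
  # distribution P_j proportional to the integral of 1 + cos over bin j
  edges <- seq(-pi, pi, length.out = 19L)
  Pint <- diff(edges) + diff(sin(edges))        # integral of 1 + cos per bin
  Pint <- (Pint / diff(edges)) / sum(Pint / diff(edges))
  H <- -sum(Pint * log2(Pint))
  oracle <- (log2(18) - H) / log2(18)
  expect_equal(modulationIndex(phase, 1 + cos(phase), 18L), oracle,
               tolerance = 1e-6)
})

test_that("modulation index is bounded, circular and scale-free", {
  for (s in 1:1000) {
    n <- 50L + (s %% 13L)
    ph <- runif(n, -pi, pi)
    am <- abs(rnorm(n))
    mi <- suppressWarnings(modulationIndex(ph, am))
    expect_true(mi >= 0 && mi <= 1)
  }
  ph <- withr::with_seed(2, runif(4000, -pi, pi))
  am <- withr::with_seed(3, abs(rnorm(4000)))
  m0 <- modulationIndex(ph, am)
  # shifting all phases by a bin width leaves MI unchanged (circular bins)
  shifted <- ((ph + 2 * pi / 18 + pi) %% (2 * pi)) - pi
  expect_lt(abs(modulationIndex(shifted, am) - m0), 1e-6)
  expect_identical(modulationIndex(ph, 7.3 * am), m0)
  expect_warning(z <- modulationIndex(ph, am * 0), "all-zero")
  expect_equal(z, 0)
})

test_that("independent phase and amplitude give near-zero MI at study length", {
  mis <- vapply(1:20, function(s) withr::with_seed(s, {
    modulationIndex(runif(50000, -pi, pi), abs(rnorm(50000)))
  }), 0)
  expect_lt(median(mis), 0.01)
})

test_that("estimated MI increases with planted modulation depth", {
  depths <- c(0, 0.3, 0.6, 0.9)
  means <- vapply(depths, function(dep) {
    mean(vapply(1:20, function(s) {
      d <- cohortDesign(2, pacs = list(pacSpec(1L, dep)), noiseSd = 0.2,
                        samplingRate = 128, epochLen = 2, nEpochs = 20L,
                        nRoi = 1L, seed = s)
      rec <- generateSubject(d, "control", 500L + s)
      modulationIndices(pacMap(rec))[1L]
    }, 0))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("pacMap recovers the ROI carrying the planted effect", {
  d <- cohortDesign(3, pacs = list(pacSpec(2L, 0.9)), noiseSd = 0.3,
                    samplingRate = 128, epochLen = 2, nEpochs = 25L,
                    nRoi = 3L, seed = 4L)
  cohort <- generateCohort(d)
  pac <- cohortPAC(cohort)
  expect_equal(dim(pac$mi), c(6L, 3L))
  expect_equal(unname(which.max(colMeans(pac$mi))), 2L)
  # determinism: identical recording -> identical map
  rec <- cohort[[1L]]
  expect_identical(modulationIndices(pacMap(rec)),
                   modulationIndices(pacMap(rec)))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writePAC(pac, tf)
  back <- as.matrix(read.delim(tf, row.names = 1))
  expect_equal(unname(back), unname(pac$mi), tolerance = 1e-12)
})
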