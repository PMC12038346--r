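# Shared fixtures: all synthetic, built in code at test time.

alphaBand <- function() bandSpec("alpha", 8, 13)

# Small fast design: few ROIs, 1-s epochs at 128 Hz.
tinyDesign <- function(nPerGroup = 2L, couplings = list(), pacs = list(),
                       noiseSd = 1, nRoi = 3L, nEpochs = 30L, epochLen = 1,
                       samplingRate = 128, seed = 1L) {
  cohortDesign(nPerGroup = nPerGroup, couplings = couplings, pacs = pacs,
               noiseSd = noiseSd, samplingRate = samplingRate,
               epochLen = epochLen, nEpochs = nEpochs, nRoi = nRoi,
               seed = seed)
}

# Quadrature-coupled noiseless pair in a given band.
quadratureDesign <- function(strength = 1, band = alphaBand(), lag = pi / 2,
                             nEpochs = 40L, seed = 1L) {
  tinyDesign(couplings = list(couplingSpec(c(1L, 2L), band, lag, strength)),
             noiseSd = 0, nRoi = 2L, nEpochs = nEpochs, seed = seed)
}

# A recording whose two channels are identical white noise (zero lag).
identicalPairRecording <- function(nEpochs = 20L, fs = 128, seed = 5L) {
  x <- withr::with_seed(seed, rnorm(nEpochs * fs))
  m <- rbind(ch1 = x, ch2 = x)
  segment(m, 1, fs)
}

# Random white-noise recording.
noiseRecording <- function(nCh = 2L, nEpochs = 20L, len = 128L, fs = 128,
                           seed = 1L) {
  d <- withr::with_seed(seed, array(rnorm(nEpochs * nCh * len),
                                    c(nEpochs, nCh, len)))
  epochedRecording(d, fs)
}

# Direct per-pair lagged-coherence recomputation from raw epoch FFTs,
# independent of the CrossSpectrum path (no shared code).
bruteLagCoh <- function(rec, i, j, band) {
  d <- epochData(rec)
  nSamp <- dim(d)[3L]
  fs <- samplingRate(rec)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nSamp) / (nSamp + 1))
  freqs <- (seq_len(nSamp) - 1) * fs / nSamp
  Sxy <- Sxx <- Syy <- numeric(nSamp) * 0i
  for (e in seq_len(dim(d)[1L])) {
    xi <- d[e, i, ] - mean(d[e, i, ])
    xj <- d[e, j, ] - mean(d[e, j, ])
    Zi <- fft(xi * w); Zj <- fft(xj * w)
    Sxy <- Sxy + Zi * Conj(Zj)
    Sxx <- Sxx + Zi * Conj(Zi)
    Syy <- Syy + Zj * Conj(Zj)
  }
  inb <- freqs >= bandEdges(band)["lo"] & freqs <= bandEdges(band)["hi"] &
    freqs <= fs / 2
  num <- Im(Sxy[inb])^2
  den <- Re(Sxx[inb]) * Re(Syy[inb]) - Re(Sxy[inb])^2
  sum(num) / sum(den)
}

# Phase unwrapping for slope checks.
unwrapPhase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1L], p[1L] + cumsum(dp))
}

# Gaussian null feature cohort for permutation calibration.
nullFeatures <- function(nPerGroup = 10L, nFeat = 10L, seed = 1L) {
  X <- withr::with_seed(seed,
                        matrix(rnorm(2 * nPerGroup * nFeat), 2 * nPerGroup))
  colnames(X) <- paste0("f", seq_len(nFeat))
  list(X = X, labels = rep(c("impaired", "control"), each = nPerGroup))
}
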