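# Theta-gamma phase-amplitude coupling via the entropy-based modulation
# index: the normalized Shannon-entropy deficit of the phase-binned
# high-frequency amplitude distribution.

#' Extract instantaneous phase and amplitude
#'
#' Zero-phase band-pass in the phase band and the amplitude band, then the
#' analytic-signal angle (phase, radians in (-pi, pi]) and magnitude
#' (amplitude, arbitrary units). One filter length of samples is discarded
#' from each end of both outputs to drop filter edge transients.
#'
#' @param series single-channel numeric vector (>= 2 s of samples).
#' @param phaseBand,ampBand \code{\link{BandSpec}}s; defaults are the
#'   cross-frequency coupling table (theta 4--7, gamma 30--45 Hz).
#' @param rate sampling rate in Hz.
#' @return list with \code{phase} and \code{amplitude}, equal length.
#' @export
phaseAmplitudeExtract <- function(series, phaseBand = cfcBands()$theta,
                                  ampBand = cfcBands()$gamma, rate) {
  n <- length(series)
  stopIfNot(n >= 2 * rate, "need at least 2 s of samples")
  nyq <- rate / 2
  stopIfNot(ampBand@hi < nyq && phaseBand@hi < nyq,
            "band edge at or above Nyquist")
  bPhase <- firBandCoef(rate, phaseBand@lo, phaseBand@hi, n)
  bAmp <- firBandCoef(rate, ampBand@lo, ampBand@hi, n)
  xPhase <- signal::filtfilt(bPhase, series)
  xAmp <- signal::filtfilt(bAmp, series)
  trim <- max(length(bPhase), length(bAmp))
  keep <- (trim + 1L):(n - trim)
  stopIfNot(length(keep) > 0L, "series too short after edge trimming")
  list(phase = Arg(analyticSignal(xPhase))[keep],
       amplitude = Mod(analyticSignal(xAmp))[keep])
}

#' Entropy-based modulation index
#'
#' Bins the low-frequency phase into \code{nBins} equal intervals over
#' (-pi, pi], computes the distribution P(j) of mean high-frequency
#' amplitude per bin (each bin mean divided by the sum of the bin means)
#' and returns MI = (lb(n) - H(P)) / lb(n), with H the Shannon entropy of P
#' in bits. MI is 0 when amplitude is independent of phase (uniform P) and
#' 1 when all amplitude concentrates in a single bin; constant amplitude
#' gives exactly 0. An empty phase bin contributes a zero mean (with a
#' warning); an all-zero amplitude series returns 0 with a warning.
#'
#' @param phase radians.
#' @param amplitude nonnegative, same length as \code{phase}.
#' @param nBins number of phase bins (>= 2); default 18 (20-degree bins),
#'   the usual convention for this index.
#' @return MI in [0, 1].
#' @export
modulationIndex <- function(phase, amplitude, nBins = 18L) {
  stopIfNot(length(phase) == length(amplitude),
            "'phase' and 'amplitude' must have equal length")
  stopIfNot(nBins >= 2L, "'nBins' must be >= 2")
  stopIfNot(all(is.finite(phase)) && all(is.finite(amplitude)),
            "inputs must be finite")
  if (all(amplitude == 0)) {
    warning("all-zero amplitude: MI is 0")
    return(0)
  }
  # circular binning of (-pi, pi] into nBins equal intervals
  bin <- ceiling((phase + pi) / (2 * pi / nBins))
  bin[bin < 1L] <- 1L; bin[bin > nBins] <- nBins
  means <- vapply(seq_len(nBins), function(j) {
    a <- amplitude[bin == j]
    if (length(a) == 0L) NA_real_ else mean(a)
  }, 0)
  if (anyNA(means)) {
    warning("empty phase bin treated as zero mean amplitude")
    means[is.na(means)] <- 0
  }
  P <- means / sum(means)
  nz <- P > 0
  H <- -sum(P[nz] * log2(P[nz]))
  mi <- (log2(nBins) - H) / log2(nBins)
  min(max(mi, 0), 1)
}

#' Per-ROI phase-amplitude coupling map
#'
#' Computes the modulation index for every ROI of a recording: phase and
#' amplitude are extracted per epoch (with per-epoch edge trimming), pooled
#' across epochs into one phase-binned distribution per ROI, and reduced to
#' a single MI value. Deterministic: identical input gives an identical map.
#'
#' @param rec an \code{\link{EpochedRecording}} of ROI series.
#' @param phaseBand,ampBand the coupling bands (defaults: theta 4--7 and
#'   gamma 30--45 Hz).
#' @param nBins phase bins for \code{\link{modulationIndex}}.
#' @return a \code{\link{PACMap}}.
#' @export
pacMap <- function(rec, phaseBand = cfcBands()$theta,
                   ampBand = cfcBands()$gamma, nBins = 18L) {
  d <- rec@data
  nCh <- dim(d)[2L]
  mi <- stats::setNames(numeric(nCh), rec@channelNames)
  for (ch in seq_len(nCh)) {
    phases <- vector("list", dim(d)[1L])
    amps <- vector("list", dim(d)[1L])
    for (e in seq_len(dim(d)[1L])) {
      pa <- phaseAmplitudeExtract(d[e, ch, ], phaseBand, ampBand,
                                  rec@samplingRate)
      phases[[e]] <- pa$phase
      amps[[e]] <- pa$amplitude
    }
    mi[ch] <- modulationIndex(unlist(phases), unlist(amps), nBins)
  }
  new("PACMap", mi = mi, phaseBand = phaseBand, ampBand = ampBand,
      subjectId = rec@subjectId)
}

#' @rdname PACMap-class
#' @export
setMethod("modulationIndices", "PACMap", function(x) x@mi)

setMethod("show", "PACMap", function(object) {
  cat(sprintf(
    "PACMap '%s': %d ROIs, phase %g-%g Hz -> amplitude %g-%g Hz, MI range [%.4f, %.4f]\n",
    object@subjectId, length(object@mi), object@phaseBand@lo,
    object@phaseBand@hi, object@ampBand@lo, object@ampBand@hi,
    min(object@mi), max(object@mi)))
})

#' Subjects x ROI modulation-index table for a cohort
#'
#' @param cohort named list of \code{\link{EpochedRecording}}s.
#' @param ... passed to \code{\link{pacMap}}.
#' @return list with \code{mi} (subjects x ROI matrix) and \code{labels}.
#' @export
cohortPAC <- function(cohort, ...) {
  stopIfNot(length(cohort) > 0L, "empty cohort")
  rows <- lapply(cohort, function(rec) modulationIndices(pacMap(rec, ...)))
  mi <- do.call(rbind, rows)
  rownames(mi) <- names(cohort)
  list(mi = mi, labels = vapply(cohort, groupLabel, ""))
}

#' Write a cohort MI table as TSV
#'
#' @param pac result of \code{\link{cohortPAC}}.
#' @param file output path.
#' @export
writePAC <- function(pac, file) {
  utils::write.table(pac$mi, file, sep = "\t", quote = FALSE, col.names = NA)
  invisible(file)
}
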