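# Lagged-coherence functional connectivity from epoch-averaged cross-spectra.

#' Epoch-averaged cross-spectrum
#'
#' Welch-style estimate: each epoch is demeaned, Hanning-tapered and
#' Fourier-transformed; the outer products of the spectra are averaged over
#' epochs, giving a Hermitian cross-spectral matrix at each frequency bin.
#' With 2-s epochs the frequency resolution is 0.5 Hz.
#'
#' @param rec an \code{\link{EpochedRecording}} (>= 2 epochs for a
#'   non-degenerate estimate; a single epoch proceeds with a warning).
#' @param fmax highest frequency retained in Hz (default 50, covering all
#'   analysis bands).
#' @return a \code{\link{CrossSpectrum}}.
#' @export
crossSpectrum <- function(rec, fmax = 50) {
  d <- rec@data
  nEp <- dim(d)[1L]; nCh <- dim(d)[2L]; nSamp <- dim(d)[3L]
  stopIfNot(nEp >= 1L, "recording has no epochs")
  if (nEp < 2L)
    warning("single epoch: lagged coherence is degenerate (coherence 1)")
  fs <- rec@samplingRate
  freqs <- seq(0, fs / 2, by = fs / nSamp)
  keep <- which(freqs > 0 & freqs <= fmax)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nSamp) / (nSamp + 1))  # Hanning
  scale <- 1 / (sum(w^2) * fs)
  S <- array(0i, c(nCh, nCh, length(keep)))
  for (e in seq_len(nEp)) {
    X <- d[e, , , drop = TRUE]
    if (nCh == 1L) X <- matrix(X, 1L)
    X <- X - rowMeans(X)
    Z <- t(stats::mvfft(t(X * rep(w, each = nCh))))[, keep, drop = FALSE]
    for (k in seq_along(keep))
      S[, , k] <- S[, , k] + scale * (Z[, k] %o% Conj(Z[, k]))
  }
  S <- S / nEp
  new("CrossSpectrum", S = S, freqs = freqs[keep], nEpochs = as.integer(nEp),
      channelNames = rec@channelNames)
}

# Pooled in-band lagged-coherence value for one (i, j) pair: numerator and
# denominator are averaged separately over in-band bins, then divided.
# Bins where the denominator vanishes (perfect instantaneous coherence)
# carry no lagged information and are skipped.
laggedCoherencePair <- function(cs, i, j, band) {
  inBand <- cs@freqs >= band@lo & cs@freqs <= band@hi
  stopIfNot(any(inBand), sprintf("band %g-%g Hz intersects no frequency bin",
                                 band@lo, band@hi))
  Sxy <- cs@S[i, j, inBand]
  Sxx <- Re(cs@S[i, i, inBand])
  Syy <- Re(cs@S[j, j, inBand])
  num <- Im(Sxy)^2
  den <- Sxx * Syy - Re(Sxy)^2
  tiny <- .Machine$double.eps * max(Sxx * Syy, 1)
  ok <- den > tiny
  if (!all(ok) && sum(num) > tiny)
    warning("bins with vanishing lagged denominator skipped")
  if (!any(ok)) {
    # all bins degenerate: a purely instantaneous (or silent) pair carries
    # no lagged synchronization
    if (sum(num) <= tiny) return(0)
    return(NA_real_)
  }
  val <- sum(num[ok]) / sum(den[ok])
  min(max(val, 0), 1)
}

#' Lagged coherence for one ROI pair
#'
#' Band-pooled lagged coherence
#' Im[Sxy]^2 / (Sxx Syy - Re[Sxy]^2), aggregated over in-band bins by
#' averaging numerator and denominator separately. The measure discounts
#' zero-lag (instantaneously mixed, e.g. volume-conducted) coupling: it is
#' exactly 0 for identical signals and approaches 1 for a noiseless
#' quadrature pair. Symmetric in pair order; values clipped to [0, 1].
#'
#' @param cs a \code{\link{CrossSpectrum}}.
#' @param pair two channel indices or names.
#' @param band a \code{\link{BandSpec}} intersecting the frequency axis.
#' @return a value in [0, 1], or \code{NA} if every in-band bin is
#'   degenerate while lagged power remains (cannot occur for valid spectra).
#' @export
laggedCoherence <- function(cs, pair, band) {
  if (is.character(pair)) pair <- match(pair, cs@channelNames)
  stopIfNot(length(pair) == 2L && !anyNA(pair), "unknown channel pair")
  laggedCoherencePair(cs, pair[1L], pair[2L], band)
}

#' Band-wise connectivity matrices for one subject
#'
#' Computes the epoch-averaged cross-spectrum once and derives a symmetric
#' ROI x ROI lagged-coherence matrix per band.
#'
#' @param rec an \code{\link{EpochedRecording}} of ROI series.
#' @param bands band table (default \code{\link{analysisBands}}).
#' @param fmax spectral ceiling passed to \code{\link{crossSpectrum}}.
#' @return named list of \code{\link{ConnectivityMatrix}} objects.
#' @export
connectivityMatrices <- function(rec, bands = analysisBands(), fmax = NULL) {
  if (is.null(fmax)) fmax <- max(vapply(bands, function(b) b@hi, 0))
  cs <- crossSpectrum(rec, fmax = fmax)
  n <- length(cs@channelNames)
  pairs <- roiPairs(cs@channelNames)
  lapply(bands, function(b) {
    v <- matrix(0, n, n, dimnames = list(cs@channelNames, cs@channelNames))
    for (r in seq_len(nrow(pairs))) {
      val <- laggedCoherencePair(cs, pairs$i[r], pairs$j[r], b)
      v[pairs$i[r], pairs$j[r]] <- val
      v[pairs$j[r], pairs$i[r]] <- val
    }
    new("ConnectivityMatrix", values = v, band = b, subjectId = rec@subjectId)
  })
}

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("connectivityValues", "ConnectivityMatrix", function(x) x@values)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("connectivityVector", "ConnectivityMatrix", function(x) {
  pairs <- roiPairs(rownames(x@values))
  stats::setNames(x@values[cbind(pairs$i, pairs$j)], pairs$name)
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf(
    "ConnectivityMatrix '%s', band %s (%g-%g Hz): %d ROIs, %d pair features\n",
    object@subjectId, object@band@name, object@band@lo, object@band@hi,
    nrow(object@values), nrow(object@values) * (nrow(object@values) - 1) / 2))
})

#' Per-band subject x feature connectivity tables for a cohort
#'
#' Runs \code{\link{connectivityMatrices}} on every subject and stacks the
#' vectorized upper triangles into one subjects x pairs matrix per band
#' (276 columns for the 24-ROI atlas), plus the group label vector.
#'
#' @param cohort named list of \code{\link{EpochedRecording}}s.
#' @param bands band table.
#' @return list with \code{features} (named list of subjects x pairs
#'   matrices, one per band) and \code{labels} (named character vector).
#' @export
cohortConnectivity <- function(cohort, bands = analysisBands()) {
  stopIfNot(length(cohort) > 0L, "empty cohort")
  rows <- lapply(cohort, function(rec) {
    mats <- connectivityMatrices(rec, bands)
    lapply(mats, connectivityVector)
  })
  features <- lapply(names(bands), function(bn) {
    do.call(rbind, lapply(rows, `[[`, bn))
  })
  names(features) <- names(bands)
  labels <- vapply(cohort, groupLabel, "")
  for (bn in names(features)) rownames(features[[bn]]) <- names(cohort)
  list(features = features, labels = labels)
}

#' Write a connectivity matrix / vector to disk
#'
#' The matrix is written as a TSV with ROI row/column headers; the vector as
#' a single-row CSV with pair-name header.
#'
#' @param cm a \code{\link{ConnectivityMatrix}}.
#' @param matrixFile,vectorFile output paths (either may be \code{NULL}).
#' @return invisibly, the vectorized features.
#' @export
writeConnectivity <- function(cm, matrixFile = NULL, vectorFile = NULL) {
  if (!is.null(matrixFile))
    utils::write.table(cm@values, matrixFile, sep = "\t", quote = FALSE,
                       col.names = NA)
  v <- connectivityVector(cm)
  if (!is.null(vectorFile))
    utils::write.csv(as.data.frame(t(v)), vectorFile, row.names = FALSE)
  invisible(v)
}
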