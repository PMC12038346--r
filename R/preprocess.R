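# Preprocessing chain: resampling, zero-phase FIR filtering, five-band
# decomposition, fixed-length segmentation and z-score outlier exclusion.

# Hamming-window FIR band-pass coefficients. Transition width is 25% of the
# lower band edge; the order is capped so forward-backward filtering stays
# applicable to short epochs (cap = len/3), which widens the effective
# transition for very low bands on 2-s epochs.
firOrder <- function(fs, transition, len) {
  n <- ceiling(3.3 * fs / transition)
  n <- min(n, max(floor(len / 3) - 1L, 16L))
  n + n %% 2L  # even order -> odd tap count, integer group delay
}

firBandCoef <- function(fs, lo, hi, len) {
  nyq <- fs / 2
  stopIfNot(lo > 0 && hi < nyq,
            sprintf("band %g-%g Hz must lie inside (0, %g) Hz", lo, hi, nyq))
  n <- firOrder(fs, 0.25 * lo, len)
  signal::fir1(n, c(lo, hi) / nyq, type = "pass", window = signal::hamming(n + 1))
}

applyFiltfilt <- function(rec, b) {
  d <- rec@data
  for (e in seq_len(dim(d)[1L]))
    for (ch in seq_len(dim(d)[2L]))
      d[e, ch, ] <- signal::filtfilt(b, d[e, ch, ])  # b is an Ma object
  methods::initialize(rec, data = d)
}

#' Zero-phase band-pass filtering
#'
#' Applies a forward-backward (zero-phase) Hamming-window FIR band-pass to
#' every epoch and channel. Phase linearity is preserved exactly, which the
#' downstream phase metrics (lagged coherence, phase-amplitude coupling)
#' require. The filter order targets a transition width of 25\% of the lower
#' band edge and is capped at a third of the epoch length.
#'
#' @param rec an \code{\link{EpochedRecording}}.
#' @param band a \code{\link{BandSpec}} strictly inside (0, Nyquist).
#' @return the filtered recording.
#' @export
filterBand <- function(rec, band) {
  b <- firBandCoef(rec@samplingRate, band@lo, band@hi, dim(rec@data)[3L])
  applyFiltfilt(rec, b)
}

#' Power-line notch filter
#'
#' Zero-phase FIR band-stop centred on the mains frequency.
#'
#' @param rec an \code{\link{EpochedRecording}}.
#' @param freq mains frequency in Hz (default 50).
#' @param width half-width of the stop band in Hz.
#' @return the filtered recording.
#' @export
notchFilter <- function(rec, freq = 50, width = 2) {
  nyq <- rec@samplingRate / 2
  stopIfNot(freq + width < nyq, "notch band must lie below Nyquist")
  len <- dim(rec@data)[3L]
  n <- firOrder(rec@samplingRate, width, len)
  b <- signal::fir1(n, c(freq - width, freq + width) / nyq, type = "stop",
                    window = signal::hamming(n + 1))
  applyFiltfilt(rec, b)
}

#' Resample a recording
#'
#' Polyphase resampling (with anti-alias filtering) of every epoch to a
#' lower target rate. Upsampling is not supported.
#'
#' @param rec an \code{\link{EpochedRecording}}.
#' @param targetRate new sampling rate in Hz; must not exceed the current
#'   rate.
#' @return the resampled recording with updated metadata.
#' @export
resampleRecording <- function(rec, targetRate) {
  fs <- rec@samplingRate
  stopIfNot(targetRate <= fs,
            "upsampling is not supported: targetRate exceeds the current rate")
  if (targetRate == fs) return(rec)
  k <- 1000
  p <- round(targetRate * k); q <- round(fs * k)
  g <- gcdInt(p, q); p <- p / g; q <- q / g
  d <- rec@data
  newLen <- length(signal::resample(d[1L, 1L, ], p, q))
  out <- array(0, c(dim(d)[1L], dim(d)[2L], newLen))
  for (e in seq_len(dim(d)[1L]))
    for (ch in seq_len(dim(d)[2L]))
      out[e, ch, ] <- signal::resample(d[e, ch, ], p, q)
  epochedRecording(out, targetRate, rec@channelNames, rec@subjectId,
                   rec@groupLabel)
}

gcdInt <- function(a, b) if (b == 0) a else gcdInt(b, a %% b)

#' Segment a continuous record into fixed-length epochs
#'
#' Cuts a channels x samples matrix into consecutive non-overlapping epochs
#' of \code{epochLen} seconds; any trailing remainder shorter than one epoch
#' is discarded. A record shorter than one epoch yields a zero-epoch
#' recording with a warning.
#'
#' @param continuous channels x samples numeric matrix.
#' @param epochLen epoch length in seconds (> 0).
#' @param samplingRate sampling rate in Hz.
#' @param subjectId,groupLabel metadata passed through.
#' @return an \code{\link{EpochedRecording}}.
#' @export
segment <- function(continuous, epochLen, samplingRate,
                    subjectId = NA_character_, groupLabel = NA_character_) {
  stopIfNot(epochLen > 0, "'epochLen' must be > 0")
  stopIfNot(is.matrix(continuous), "'continuous' must be channels x samples")
  len <- round(epochLen * samplingRate)
  nEp <- floor(ncol(continuous) / len)
  if (nEp == 0L)
    warning("record shorter than one epoch: returning zero epochs")
  data <- array(0, c(nEp, nrow(continuous), len))
  for (e in seq_len(nEp))
    data[e, , ] <- continuous[, ((e - 1L) * len + 1L):(e * len)]
  epochedRecording(data, samplingRate,
                   channelNames = rownames(continuous),
                   subjectId = subjectId, groupLabel = groupLabel)
}

#' Decompose a recording into the five analysis bands
#'
#' @param rec an \code{\link{EpochedRecording}}.
#' @param bands a band table (default \code{\link{analysisBands}}).
#' @return named list of band-filtered recordings.
#' @export
bandDecompose <- function(rec, bands = analysisBands()) {
  lapply(bands, function(b) filterBand(rec, b))
}

#' Z-score outlier exclusion mask
#'
#' Flags observations whose z-score (against the sample mean and SD of the
#' input vector) exceeds the threshold in absolute value; used on
#' per-subject feature vectors ahead of the classification stage. A
#' zero-variance vector keeps every observation, with a warning.
#'
#' @param values numeric vector (>= 3 finite observations).
#' @param threshold z threshold in SD units (default 5).
#' @return logical keep-mask, \code{TRUE} where |z| <= threshold.
#' @examples
#' zscoreKeep(c(0, 0, 0, 0, 100))      # all TRUE: z of 100 is ~2 SD
#' @export
zscoreKeep <- function(values, threshold = 5) {
  stopIfNot(length(values) >= 3L, "need at least 3 observations")
  stopIfNot(all(is.finite(values)), "values must be finite")
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero variance: all observations kept")
    return(rep(TRUE, length(values)))
  }
  abs((values - mean(values)) / s) <= threshold
}
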