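#' @import methods
NULL

#' Named frequency band
#'
#' A frequency band with a name and lower/upper edges in Hz. The canonical
#' analysis table (\code{\link{analysisBands}}) tiles 1--44 Hz into delta,
#' theta, alpha, beta and gamma; cross-frequency coupling uses a separate
#' table (\code{\link{cfcBands}}) with theta 4--7 Hz and gamma 30--45 Hz.
#'
#' @slot name band name, e.g. \code{"alpha"}.
#' @slot lo lower edge in Hz (exclusive of 0).
#' @slot hi upper edge in Hz; must exceed \code{lo}.
#' @export
setClass("BandSpec",
  representation(name = "character", lo = "numeric", hi = "numeric"))

setValidity("BandSpec", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (length(object@lo) != 1L || length(object@hi) != 1L)
    return("'lo' and 'hi' must be scalars")
  if (!is.finite(object@lo) || !is.finite(object@hi))
    return("band edges must be finite")
  if (object@lo <= 0) return("'lo' must be > 0")
  if (object@hi <= object@lo) return("'hi' must exceed 'lo'")
  TRUE
})

#' Epoched multichannel recording
#'
#' Fixed-length epochs of channel (or ROI) time series with sampling-rate
#' metadata. The data array is epochs x channels x samples.
#'
#' @slot data numeric array, epochs x channels x samples.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelNames one name per channel/ROI.
#' @slot subjectId subject identifier.
#' @slot groupLabel group label (e.g. \code{"impaired"}, \code{"control"});
#'   may be \code{NA} for unlabelled data.
#' @export
setClass("EpochedRecording",
  representation(data = "array", samplingRate = "numeric",
                 channelNames = "character", subjectId = "character",
                 groupLabel = "character"))

setValidity("EpochedRecording", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("'data' must be a 3-d array (epochs x channels x samples)")
  if (!is.numeric(d)) return("'data' must be numeric")
  if (any(!is.finite(d))) return("'data' contains non-finite samples")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("'samplingRate' must be a positive scalar")
  if (length(object@channelNames) != dim(d)[2L])
    return("'channelNames' length must equal the channel dimension")
  TRUE
})

#' Epoch-averaged cross-spectral matrix
#'
#' Hermitian cross-spectral density at each frequency bin, averaged over
#' tapered epochs.
#'
#' @slot S complex array, channels x channels x frequency bins; Hermitian in
#'   its first two dimensions with real nonnegative diagonal.
#' @slot freqs frequency axis in Hz, strictly increasing.
#' @slot nEpochs number of epochs averaged.
#' @slot channelNames channel/ROI names.
#' @export
setClass("CrossSpectrum",
  representation(S = "array", freqs = "numeric", nEpochs = "integer",
                 channelNames = "character"))

setValidity("CrossSpectrum", function(object) {
  d <- dim(object@S)
  if (length(d) != 3L || d[1L] != d[2L])
    return("'S' must be channels x channels x freqs")
  if (d[3L] != length(object@freqs))
    return("third dimension of 'S' must match 'freqs'")
  if (is.unsorted(object@freqs, strictly = TRUE))
    return("'freqs' must be strictly increasing")
  if (object@nEpochs < 1L) return("'nEpochs' must be >= 1")
  TRUE
})

#' Band-wise lagged-coherence connectivity matrix
#'
#' Symmetric ROI x ROI lagged-coherence values in [0, 1] for one subject and
#' one band, with zero diagonal. \code{\link{connectivityVector}} flattens the
#' upper triangle (row-major, i < j) into the fixed-order feature vector
#' (276 features for the 24-ROI atlas).
#'
#' @slot values symmetric numeric matrix in [0, 1] with zero diagonal;
#'   \code{NA} marks pairs whose value is undefined.
#' @slot band a \code{\link{BandSpec}}.
#' @slot subjectId subject identifier.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", band = "BandSpec",
                 subjectId = "character"))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("'values' must be square")
  if (is.null(rownames(v))) return("'values' must carry ROI names")
  ok <- v[is.finite(v)]
  if (any(ok < -1e-12 | ok > 1 + 1e-12))
    return("'values' must lie in [0, 1]")
  if (any(abs(diag(v)) > 1e-12)) return("diagonal must be 0")
  if (max(abs(v - t(v)), na.rm = TRUE) > 1e-10)
    return("'values' must be symmetric")
  TRUE
})

#' Per-ROI phase-amplitude coupling map
#'
#' Modulation-index values in [0, 1], one per ROI, for one subject and one
#' (phase band, amplitude band) pair.
#'
#' @slot mi named numeric vector of modulation indices in [0, 1].
#' @slot phaseBand,ampBand \code{\link{BandSpec}} objects; the phase band must
#'   lie entirely below the amplitude band.
#' @slot subjectId subject identifier.
#' @export
setClass("PACMap",
  representation(mi = "numeric", phaseBand = "BandSpec", ampBand = "BandSpec",
                 subjectId = "character"))

setValidity("PACMap", function(object) {
  if (is.null(names(object@mi))) return("'mi' must be named by ROI")
  ok <- object@mi[is.finite(object@mi)]
  if (any(ok < -1e-12 | ok > 1 + 1e-12)) return("'mi' must lie in [0, 1]")
  if (object@phaseBand@hi >= object@ampBand@lo)
    return("phase band must lie below the amplitude band")
  TRUE
})

#' Group comparison result
#'
#' Per-feature two-sample t statistics with a permutation-derived
#' family-wise threshold (max-statistic scheme) or a Benjamini-Hochberg FDR
#' mask, plus the provenance needed to reproduce the inference.
#'
#' @slot t per-feature pooled-variance t statistics.
#' @slot df degrees of freedom (n1 + n2 - 2).
#' @slot critT two-sided critical |t| at level \code{alpha}
#'   (permutation mode; \code{NA} in FDR mode).
#' @slot pValues per-feature p-values (permutation or parametric).
#' @slot sigMask logical significance mask.
#' @slot method \code{"permutation_max"} or \code{"fdr_bh"}.
#' @slot nPerm number of permutations (0 in FDR mode); \code{exhaustive}
#'   records whether all distinct label assignments were enumerated.
#' @slot alpha significance level.
#' @slot seed RNG seed used for permutation draws.
#' @slot exhaustive logical flag.
#' @export
setClass("GroupComparisonResult",
  representation(t = "numeric", df = "numeric", critT = "numeric",
                 pValues = "numeric", sigMask = "logical",
                 method = "character", nPerm = "integer", alpha = "numeric",
                 seed = "integer", exhaustive = "logical"))

setValidity("GroupComparisonResult", function(object) {
  n <- length(object@t)
  if (length(object@sigMask) != n || length(object@pValues) != n)
    return("'t', 'pValues' and 'sigMask' must have equal length")
  if (!object@method %in% c("permutation_max", "fdr_bh"))
    return("unknown 'method'")
  if (object@method == "permutation_max" && is.finite(object@critT)) {
    if (!identical(unname(abs(object@t) > object@critT),
                   unname(object@sigMask)))
      return("'sigMask' must equal |t| > critT in permutation mode")
  }
  TRUE
})

#' Cross-validated classifier report
#'
#' Pooled 10-fold cross-validation metrics for a linear SVM on connectivity
#' features, together with the full-fit ranked absolute weights and the
#' top-fraction feature set.
#'
#' @slot accuracy,sensitivity,specificity proportions in [0, 1]; sensitivity
#'   treats the positive (impaired) class as cases.
#' @slot foldAssignments integer fold id per subject.
#' @slot rankedWeights data.frame with columns \code{feature} and
#'   \code{weight} (absolute linear-SVM coefficient), sorted descending.
#' @slot topSet character vector of the first k ranked features
#'   (k = floor(topFrac * n features); 13 of 276 at the default 5\%).
#' @slot band band name the features were computed in.
#' @slot positiveClass label treated as positive.
#' @slot seed fold RNG seed.
#' @export
setClass("ClassifierReport",
  representation(accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", foldAssignments = "integer",
                 rankedWeights = "data.frame", topSet = "character",
                 band = "character", positiveClass = "character",
                 seed = "integer"))

setValidity("ClassifierReport", function(object) {
  m <- c(object@accuracy, object@sensitivity, object@specificity)
  if (any(is.finite(m) & (m < 0 | m > 1)))
    return("metrics must lie in [0, 1]")
  if (!all(c("feature", "weight") %in% names(object@rankedWeights)))
    return("'rankedWeights' needs 'feature' and 'weight' columns")
  TRUE
})

## ---- synthetic-generator specification classes ----

#' Planted narrowband oscillator
#'
#' @slot centerFreq centre frequency in Hz.
#' @slot bandwidth full bandwidth in Hz.
#' @slot amplitude RMS amplitude in arbitrary units.
#' @slot roi 1-based ROI index.
#' @export
setClass("OscillatorSpec",
  representation(centerFreq = "numeric", bandwidth = "numeric",
                 amplitude = "numeric", roi = "integer"))

setValidity("OscillatorSpec", function(object) {
  if (object@centerFreq <= 0) return("'centerFreq' must be > 0")
  if (object@bandwidth <= 0) return("'bandwidth' must be > 0")
  if (object@amplitude < 0) return("'amplitude' must be >= 0")
  if (object@roi < 1L) return("'roi' must be a positive index")
  TRUE
})

#' Planted lagged coupling between two ROIs
#'
#' A band-limited component shared between the two ROIs of a pair, with the
#' second copy phase-rotated by \code{phaseLag}. \code{strength} is the target
#' in-band coherence between the pair: each ROI receives the shared component
#' with amplitude sqrt(strength) plus an independent same-band component with
#' amplitude sqrt(1 - strength), so coherence magnitude equals
#' \code{strength} and lagged coherence at quadrature lag equals
#' \code{strength}^2. May carry one strength per group (named vector).
#'
#' @slot pair integer pair of distinct 1-based ROI indices.
#' @slot band \code{\link{BandSpec}} of the shared component.
#' @slot phaseLag lag in radians in (-pi, pi].
#' @slot strength coherence target(s) in [0, 1]; scalar, or named by group.
#' @slot amplitude RMS amplitude of the band component per ROI.
#' @export
setClass("CouplingSpec",
  representation(pair = "integer", band = "BandSpec", phaseLag = "numeric",
                 strength = "numeric", amplitude = "numeric"))

setValidity("CouplingSpec", function(object) {
  if (length(object@pair) != 2L || object@pair[1L] == object@pair[2L])
    return("'pair' must be two distinct ROI indices")
  if (any(object@pair < 1L)) return("'pair' indices must be positive")
  if (object@phaseLag <= -pi || object@phaseLag > pi)
    return("'phaseLag' must lie in (-pi, pi]")
  if (any(object@strength < 0 | object@strength > 1))
    return("'strength' must lie in [0, 1]")
  if (object@amplitude < 0) return("'amplitude' must be >= 0")
  TRUE
})

#' Planted theta-gamma phase-amplitude coupling
#'
#' A narrowband amplitude-band carrier whose envelope is
#' (1 + depth * cos(phase)) / (1 + depth) times baseline, where phase is the
#' instantaneous phase of a planted phase-band oscillation in the same ROI.
#' May carry one depth per group (named vector).
#'
#' @slot roi 1-based ROI index.
#' @slot phaseBand,ampBand \code{\link{BandSpec}}s; phase band strictly below
#'   the amplitude band.
#' @slot depth modulation depth(s) in [0, 1]; scalar, or named by group.
#' @slot phaseAmplitude,carrierAmplitude RMS amplitudes of the phase-band
#'   oscillation and of the unmodulated carrier.
#' @export
setClass("PACSpec",
  representation(roi = "integer", phaseBand = "BandSpec", ampBand = "BandSpec",
                 depth = "numeric", phaseAmplitude = "numeric",
                 carrierAmplitude = "numeric"))

setValidity("PACSpec", function(object) {
  if (object@roi < 1L) return("'roi' must be a positive index")
  if (any(object@depth < 0 | object@depth > 1))
    return("'depth' must lie in [0, 1]")
  if (object@phaseBand@hi >= object@ampBand@lo)
    return("phase band upper edge must lie below amplitude band lower edge")
  if (object@phaseAmplitude < 0 || object@carrierAmplitude < 0)
    return("amplitudes must be >= 0")
  TRUE
})

#' Two-group synthetic cohort design
#'
#' The full specification of a synthetic two-group resting-state cohort:
#' per-group sizes, the planted oscillators/couplings/PAC effects (whose
#' group-specific values define the planted group differences), the noise
#' level and the recording geometry. Everything downstream is deterministic
#' given the design and its seed.
#'
#' @slot nPerGroup subjects per group (>= 2).
#' @slot groupLabels two labels; the first is the impaired group.
#' @slot oscillators list of \code{\link{OscillatorSpec}}.
#' @slot couplings list of \code{\link{CouplingSpec}}.
#' @slot pacs list of \code{\link{PACSpec}}.
#' @slot noiseSd standard deviation of additive white noise.
#' @slot samplingRate Hz; must exceed twice the highest referenced band edge.
#' @slot epochLen epoch length in seconds.
#' @slot nEpochs epochs per subject.
#' @slot nRoi number of ROIs.
#' @slot roiNames ROI names (length \code{nRoi}).
#' @slot seed master seed.
#' @export
setClass("CohortDesign",
  representation(nPerGroup = "integer", groupLabels = "character",
                 oscillators = "list", couplings = "list", pacs = "list",
                 noiseSd = "numeric", samplingRate = "numeric",
                 epochLen = "numeric", nEpochs = "integer", nRoi = "integer",
                 roiNames = "character", seed = "integer"))

setValidity("CohortDesign", function(object) {
  if (object@nPerGroup < 2L) return("'nPerGroup' must be >= 2")
  if (length(object@groupLabels) != 2L ||
      anyDuplicated(object@groupLabels))
    return("'groupLabels' must be two distinct labels")
  if (object@epochLen <= 0) return("'epochLen' must be > 0")
  if (object@nEpochs < 1L) return("'nEpochs' must be >= 1")
  if (length(object@roiNames) != object@nRoi)
    return("'roiNames' must have length 'nRoi'")
  hi <- designMaxFreq(object)
  if (hi > 0 && object@samplingRate < 2 * hi)
    return(sprintf(
      "samplingRate %.1f Hz violates the Nyquist bound for a %.1f Hz band edge",
      object@samplingRate, hi))
  specRoiMax <- designMaxRoi(object)
  if (specRoiMax > object@nRoi)
    return("a planted effect references an ROI index beyond 'nRoi'")
  TRUE
})
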