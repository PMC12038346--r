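#' @rdname EpochedRecording-class
#' @param x an object.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EpochedRecording-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname EpochedRecording-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname EpochedRecording-class
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname EpochedRecording-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname EpochedRecording-class
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' Band accessors
#' @param x an object with a frequency band.
#' @rdname BandSpec-class
#' @export
setGeneric("bandName", function(x) standardGeneric("bandName"))

#' @rdname BandSpec-class
#' @export
setGeneric("bandEdges", function(x) standardGeneric("bandEdges"))

#' @rdname ConnectivityMatrix-class
#' @param x a \code{ConnectivityMatrix}.
#' @export
setGeneric("connectivityValues", function(x) standardGeneric("connectivityValues"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("connectivityVector", function(x) standardGeneric("connectivityVector"))

#' @rdname PACMap-class
#' @param x a \code{PACMap}.
#' @export
setGeneric("modulationIndices", function(x) standardGeneric("modulationIndices"))

#' @rdname GroupComparisonResult-class
#' @param x a \code{GroupComparisonResult}.
#' @export
setGeneric("tStatistics", function(x) standardGeneric("tStatistics"))

#' @rdname GroupComparisonResult-class
#' @export
setGeneric("significanceMask", function(x) standardGeneric("significanceMask"))

#' @rdname GroupComparisonResult-class
#' @export
setGeneric("criticalT", function(x) standardGeneric("criticalT"))

#' @rdname ClassifierReport-class
#' @param x a \code{ClassifierReport}.
#' @export
setGeneric("classifierMetrics", function(x) standardGeneric("classifierMetrics"))

#' @rdname ClassifierReport-class
#' @export
setGeneric("rankedWeights", function(x) standardGeneric("rankedWeights"))

#' @rdname ClassifierReport-class
#' @export
setGeneric("topFeatures", function(x) standardGeneric("topFeatures"))
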