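#' Construct an epoched recording
#'
#' @param data epochs x channels x samples array, or a channels x samples
#'   matrix (treated as one epoch).
#' @param samplingRate sampling rate in Hz.
#' @param channelNames channel/ROI names; defaults to \code{ch1..chK}.
#' @param subjectId,groupLabel metadata.
#' @return an \code{\link{EpochedRecording}}.
#' @export
epochedRecording <- function(data, samplingRate, channelNames = NULL,
                             subjectId = NA_character_,
                             groupLabel = NA_character_) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (is.null(channelNames)) {
    channelNames <- dimnames(data)[[2L]]
    if (is.null(channelNames))
      channelNames <- paste0("ch", seq_len(dim(data)[2L]))
  }
  dimnames(data) <- list(NULL, channelNames, NULL)
  new("EpochedRecording", data = data, samplingRate = as.numeric(samplingRate),
      channelNames = as.character(channelNames),
      subjectId = as.character(subjectId),
      groupLabel = as.character(groupLabel))
}

#' @rdname EpochedRecording-class
#' @export
setMethod("samplingRate", "EpochedRecording", function(x) x@samplingRate)

#' @rdname EpochedRecording-class
#' @export
setMethod("channelNames", "EpochedRecording", function(x) x@channelNames)

#' @rdname EpochedRecording-class
#' @export
setMethod("subjectId", "EpochedRecording", function(x) x@subjectId)

#' @rdname EpochedRecording-class
#' @export
setMethod("groupLabel", "EpochedRecording", function(x) x@groupLabel)

#' @rdname EpochedRecording-class
#' @export
setMethod("nEpochs", "EpochedRecording", function(x) dim(x@data)[1L])

#' @rdname EpochedRecording-class
#' @export
setMethod("epochData", "EpochedRecording", function(x) x@data)

setMethod("show", "EpochedRecording", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochedRecording '%s' (%s): %d epochs x %d channels x %d samples @ %g Hz\n",
    object@subjectId, object@groupLabel, d[1L], d[2L], d[3L],
    object@samplingRate))
})

# Continuous channels x samples view of a recording (epochs concatenated in
# order; epochs are contiguous non-overlapping segments of the original
# record, so concatenation restores it).
continuousData <- function(rec) {
  d <- dim(rec@data)
  out <- matrix(aperm(rec@data, c(3L, 1L, 2L)), d[1L] * d[3L], d[2L])
  t(out)
}
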