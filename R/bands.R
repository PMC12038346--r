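#' Construct a frequency band
#'
#' @param name band name.
#' @param lo,hi lower/upper edges in Hz.
#' @return a \code{\link{BandSpec}}.
#' @examples
#' bandSpec("alpha", 8, 13)
#' @export
bandSpec <- function(name, lo, hi) {
  new("BandSpec", name = as.character(name), lo = as.numeric(lo),
      hi = as.numeric(hi))
}

#' Canonical frequency-band tables
#'
#' \code{analysisBands} returns the five-band decomposition used for spectral
#' and connectivity analysis: delta 1--4, theta 4--8, alpha 8--13, beta
#' 13--30 and gamma 30--44 Hz, tiling 1--44 Hz contiguously.
#' \code{cfcBands} returns the separate cross-frequency-coupling table:
#' theta 4--7 Hz (phase) and gamma 30--45 Hz (amplitude). The two tables are
#' deliberately kept distinct; each stage selects its own.
#'
#' @return a named list of \code{\link{BandSpec}} objects.
#' @examples
#' names(analysisBands())
#' cfcBands()$theta
#' @export
analysisBands <- function() {
  list(delta = bandSpec("delta", 1, 4),
       theta = bandSpec("theta", 4, 8),
       alpha = bandSpec("alpha", 8, 13),
       beta  = bandSpec("beta", 13, 30),
       gamma = bandSpec("gamma", 30, 44))
}

#' @rdname analysisBands
#' @export
cfcBands <- function() {
  list(theta = bandSpec("theta", 4, 7),
       gamma = bandSpec("gamma", 30, 45))
}

#' @rdname BandSpec-class
#' @export
setMethod("bandName", "BandSpec", function(x) x@name)

#' @rdname BandSpec-class
#' @export
setMethod("bandEdges", "BandSpec", function(x) c(lo = x@lo, hi = x@hi))

setMethod("show", "BandSpec", function(object) {
  cat(sprintf("BandSpec '%s': %g-%g Hz\n", object@name, object@lo, object@hi))
})
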