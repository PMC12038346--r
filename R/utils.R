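# Internal numeric helpers shared across stages.

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal of a real series (positive-frequency
#' spectrum doubled, negative frequencies zeroed), from which instantaneous
#' phase and amplitude are read off as \code{Arg} and \code{Mod}.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Brick-wall FFT band-pass used by the synthetic generator: exact spectral
# placement, zero phase. Not used in the preprocessing chain (which uses FIR
# filters), so generator and estimator never share a filter implementation.
fftBandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) * fs / n   # folded frequency of each FFT bin
  keep <- f >= lo & f <= hi
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE) / n)
}

# Unit-RMS narrowband Gaussian noise in [lo, hi] Hz.
narrowbandNoise <- function(n, fs, lo, hi) {
  y <- fftBandpass(stats::rnorm(n), fs, lo, hi)
  r <- sqrt(mean(y^2))
  if (r > 0) y / r else y
}

# Lehmer-style modular mix for reproducible per-subject seeds; multiplier
# 48271 keeps every intermediate product below 2^53 so the arithmetic is
# exact in doubles.
mixSeed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed %% m)
  for (v in c(...)) h <- (h * 48271 + as.numeric(v) + 1) %% m
  as.integer(h)
}

# Evaluate expr under a local RNG stream; the caller's RNG state is restored.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Highest band edge referenced by a design's planted effects (0 if none).
designMaxFreq <- function(design) {
  his <- c(
    vapply(design@oscillators, function(o) o@centerFreq + o@bandwidth / 2, 0),
    vapply(design@couplings, function(cp) cp@band@hi, 0),
    vapply(design@pacs, function(p) p@ampBand@hi, 0))
  if (length(his)) max(his) else 0
}

designMaxRoi <- function(design) {
  idx <- c(
    vapply(design@oscillators, function(o) o@roi, 1L),
    unlist(lapply(design@couplings, function(cp) cp@pair)),
    vapply(design@pacs, function(p) p@roi, 1L))
  if (length(idx)) max(idx) else 0L
}

# Group-specific value of a (possibly group-named) parameter vector.
groupValue <- function(v, group) {
  if (length(v) == 1L && is.null(names(v))) return(unname(v))
  if (!is.null(names(v)) && group %in% names(v)) return(unname(v[[group]]))
  unname(v[[1L]])
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
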