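# Standardized minimum-norm (sLORETA-style) inverse and ROI aggregation.

#' Standardized minimum-norm inverse weights
#'
#' Computes the Tikhonov-regularized minimum-norm inverse
#' W = G' (G G' + alpha I)^-1 and standardizes each row by the square root
#' of the corresponding diagonal entry of the model resolution matrix
#' R = W G. The standardized operator has the zero-localization-error
#' property: a noiseless recording generated by a single active source
#' attains its maximum standardized power at that source.
#'
#' @param gain sensors x sources leadfield matrix (finite entries,
#'   >= 2 sensors).
#' @param alpha regularization parameter (>= 0); default is 1e-2 times the
#'   mean eigenvalue of G G' (i.e. 1e-2 * tr(G G') / sensors), a scale-free
#'   choice. With \code{alpha = 0} a rank-deficient gain raises an error
#'   advising regularization.
#' @return sources x sensors standardized weight matrix.
#' @export
sloretaWeights <- function(gain, alpha = NULL) {
  stopIfNot(is.matrix(gain) && all(is.finite(gain)),
            "'gain' must be a finite numeric matrix")
  m <- nrow(gain)
  stopIfNot(m >= 2L, "need at least two sensors")
  GG <- gain %*% t(gain)
  if (is.null(alpha)) alpha <- 1e-2 * mean(diag(GG))
  stopIfNot(alpha >= 0, "'alpha' must be >= 0")
  A <- GG + alpha * diag(m)
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("gain is rank-deficient with alpha = 0; use alpha > 0 ",
         "(singular sensor covariance: ", conditionMessage(e), ")",
         call. = FALSE))
  W <- t(gain) %*% Ainv              # minimum-norm inverse
  resDiag <- rowSums(W * t(gain))    # diag(W %*% gain)
  stopIfNot(all(resDiag > 0),
            "non-positive resolution diagonal; gain has a silent source")
  W / sqrt(resDiag)
}

#' Apply inverse weights to sensor data
#'
#' @param weights sources x sensors matrix from \code{\link{sloretaWeights}}.
#' @param sensorData sensors x samples matrix.
#' @return sources x samples standardized source activity.
#' @export
applyInverse <- function(weights, sensorData) {
  stopIfNot(ncol(weights) == nrow(sensorData),
            "sensor count mismatch between weights and data")
  weights %*% sensorData
}

#' Aggregate source series into ROI series
#'
#' Per-ROI series is the first principal direction (largest singular value)
#' of the member-source series, sign-aligned to correlate positively with
#' the ROI mean series. A singleton ROI returns its source series unchanged
#' up to sign and scale.
#'
#' @param activity sources x samples matrix.
#' @param roiAssignment character/factor of length sources giving each
#'   source's ROI; every referenced ROI must be non-empty.
#' @param roiOrder optional ROI output order (default: order of first
#'   appearance).
#' @return ROI x samples matrix with ROI rownames.
#' @export
roiTimeseries <- function(activity, roiAssignment, roiOrder = NULL) {
  stopIfNot(nrow(activity) == length(roiAssignment),
            "'roiAssignment' must name every source")
  roiAssignment <- as.character(roiAssignment)
  if (is.null(roiOrder)) roiOrder <- unique(roiAssignment)
  stopIfNot(all(roiOrder %in% roiAssignment),
            "empty ROI in 'roiOrder': every ROI needs at least one source")
  out <- matrix(0, length(roiOrder), ncol(activity),
                dimnames = list(roiOrder, NULL))
  for (r in roiOrder) {
    sub <- activity[roiAssignment == r, , drop = FALSE]
    if (nrow(sub) == 1L) {
      series <- sub[1L, ]
    } else {
      sv <- svd(sub, nu = 1L, nv = 1L)
      series <- sv$d[1L] * sv$v[, 1L]
    }
    ref <- colMeans(sub)
    if (sum(series * ref) < 0) series <- -series
    out[r, ] <- series
  }
  out
}

#' Toy spherical-geometry leadfield
#'
#' Generates a small two-dimensional leadfield for desk-scale testing:
#' sensors evenly spaced on the unit circle, sources at random interior
#' positions, gain proportional to inverse squared distance. Ships in place
#' of any template head model; not a realistic forward model.
#'
#' @param nSensors,nSources counts.
#' @param seed RNG seed for source placement.
#' @return list with \code{gain} (sensors x sources), \code{sensorPos} and
#'   \code{sourcePos} (x, y columns).
#' @export
toyLeadfield <- function(nSensors = 16, nSources = 20, seed = 1L) {
  withSeed(seed, {
    a <- seq(0, 2 * pi, length.out = nSensors + 1L)[seq_len(nSensors)]
    sensors <- cbind(cos(a), sin(a))
    r <- sqrt(stats::runif(nSources, 0.05, 0.8))
    th <- stats::runif(nSources, 0, 2 * pi)
    sources <- cbind(r * cos(th), r * sin(th))
    gain <- matrix(0, nSensors, nSources)
    for (j in seq_len(nSources)) {
      d2 <- rowSums(sweep(sensors, 2, sources[j, ])^2)
      gain[, j] <- 1 / d2
    }
    list(gain = gain, sensorPos = sensors, sourcePos = sources)
  })
}
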