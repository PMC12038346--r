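#' Construct generator specifications
#'
#' Constructors for the planted-effect specifications consumed by
#' \code{\link{cohortDesign}}: a narrowband oscillator, a lagged inter-ROI
#' coupling, and a theta-gamma phase-amplitude modulation.
#'
#' @param centerFreq,bandwidth,amplitude oscillator centre frequency (Hz),
#'   bandwidth (Hz) and RMS amplitude.
#' @param roi 1-based ROI index.
#' @return the corresponding specification object.
#' @examples
#' oscillatorSpec(10, 2, 1, roi = 1)
#' @export
oscillatorSpec <- function(centerFreq, bandwidth, amplitude, roi) {
  new("OscillatorSpec", centerFreq = as.numeric(centerFreq),
      bandwidth = as.numeric(bandwidth), amplitude = as.numeric(amplitude),
      roi = as.integer(roi))
}

#' @rdname oscillatorSpec
#' @param pair two distinct 1-based ROI indices.
#' @param band a \code{\link{BandSpec}}.
#' @param phaseLag lag in radians, (-pi, pi].
#' @param strength target in-band coherence in [0, 1]; a scalar, or a named
#'   vector with one value per group label for planted group differences.
#' @export
couplingSpec <- function(pair, band, phaseLag = pi / 2, strength = 1,
                         amplitude = 1) {
  new("CouplingSpec", pair = as.integer(pair), band = band,
      phaseLag = as.numeric(phaseLag), strength = strength,
      amplitude = as.numeric(amplitude))
}

#' @rdname oscillatorSpec
#' @param phaseBand,ampBand phase/amplitude \code{\link{BandSpec}}s
#'   (defaults: the cross-frequency coupling table, theta 4--7 and gamma
#'   30--45 Hz).
#' @param depth modulation depth in [0, 1]; scalar or named per group.
#' @param phaseAmplitude,carrierAmplitude RMS amplitudes of the phase-band
#'   oscillation and of the unmodulated carrier.
#' @export
pacSpec <- function(roi, depth, phaseBand = cfcBands()$theta,
                    ampBand = cfcBands()$gamma, phaseAmplitude = 1,
                    carrierAmplitude = 1) {
  new("PACSpec", roi = as.integer(roi), phaseBand = phaseBand,
      ampBand = ampBand, depth = depth,
      phaseAmplitude = as.numeric(phaseAmplitude),
      carrierAmplitude = as.numeric(carrierAmplitude))
}

#' Construct a synthetic two-group cohort design
#'
#' Defaults mirror the retained-data scale of a resting-state paediatric
#' recording session: 500 Hz sampling, 2-s epochs and 150 epochs per subject
#' (about 5 minutes of retained data).
#'
#' @param nPerGroup subjects per group.
#' @param oscillators,couplings,pacs lists of specification objects
#'   (see \code{\link{oscillatorSpec}}); group-specific strengths/depths in
#'   those specs define the planted group effects.
#' @param noiseSd additive white-noise SD (arbitrary units).
#' @param samplingRate sampling rate in Hz.
#' @param epochLen epoch length in seconds.
#' @param nEpochs epochs per subject.
#' @param nRoi number of ROIs; defaults to 24 with atlas ROI names.
#' @param roiNames ROI names.
#' @param groupLabels two group labels, impaired first.
#' @param seed master seed; all per-subject seeds derive from it.
#' @return a validated \code{\link{CohortDesign}}.
#' @export
cohortDesign <- function(nPerGroup, oscillators = list(), couplings = list(),
                         pacs = list(), noiseSd = 1, samplingRate = 500,
                         epochLen = 2, nEpochs = 150L, nRoi = NULL,
                         roiNames = NULL,
                         groupLabels = c("impaired", "control"), seed = 1L) {
  if (is.null(nRoi) && is.null(roiNames)) {
    roiNames <- loadAtlas()$roi
    nRoi <- length(roiNames)
  } else if (is.null(roiNames)) {
    roiNames <- paste0("roi", seq_len(nRoi))
  } else if (is.null(nRoi)) {
    nRoi <- length(roiNames)
  }
  new("CohortDesign", nPerGroup = as.integer(nPerGroup),
      groupLabels = as.character(groupLabels),
      oscillators = oscillators, couplings = couplings, pacs = pacs,
      noiseSd = as.numeric(noiseSd), samplingRate = as.numeric(samplingRate),
      epochLen = as.numeric(epochLen), nEpochs = as.integer(nEpochs),
      nRoi = as.integer(nRoi), roiNames = as.character(roiNames),
      seed = as.integer(seed))
}

#' Generate one synthetic subject
#'
#' Simulates a continuous multichannel record and segments it into epochs.
#' Planted couplings are realized as a band-limited Gaussian component shared
#' between the two ROIs of each pair, the second copy phase-rotated by the
#' specified lag (frequency-domain rotation of the analytic signal), mixed
#' with an independent same-band component so that the in-band coherence
#' magnitude equals the spec's \code{strength}. Planted phase-amplitude
#' coupling multiplies a narrowband amplitude-band carrier by
#' \code{(1 + depth * cos(theta_phase)) / (1 + depth)}, where theta_phase is
#' the instantaneous phase of a planted phase-band oscillation in the same
#' ROI. Independent white noise is added at \code{noiseSd}. Output is
#' bit-identical across calls with the same arguments.
#'
#' @param design a \code{\link{CohortDesign}}.
#' @param group one of \code{design@groupLabels}.
#' @param subjectSeed integer seed for this subject (see
#'   \code{\link{generateCohort}} for the derivation used cohort-wide).
#' @param subjectId identifier stored in the recording.
#' @return an \code{\link{EpochedRecording}} with
#'   \code{nEpochs x nRoi x (epochLen * samplingRate)} data.
#' @export
generateSubject <- function(design, group, subjectSeed,
                            subjectId = paste0(group, "_s", subjectSeed)) {
  validObject(design)
  stopIfNot(group %in% design@groupLabels,
            sprintf("unknown group '%s'", group))
  stopIfNot(design@nEpochs >= 1L, "design must request at least one epoch")
  fs <- design@samplingRate
  nSamp <- round(design@nEpochs * design@epochLen * fs)
  stopIfNot(nSamp >= 2L, "design yields an empty record")
  X <- withSeed(as.integer(subjectSeed), {
    X <- matrix(0, design@nRoi, nSamp)
    for (o in design@oscillators) {
      lo <- o@centerFreq - o@bandwidth / 2
      hi <- o@centerFreq + o@bandwidth / 2
      X[o@roi, ] <- X[o@roi, ] +
        o@amplitude * narrowbandNoise(nSamp, fs, max(lo, 1e-6), hi)
    }
    for (cp in design@couplings) {
      m <- groupValue(cp@strength, group)
      shared <- narrowbandNoise(nSamp, fs, cp@band@lo, cp@band@hi)
      lagged <- Re(analyticSignal(shared) * exp(-1i * cp@phaseLag))
      a <- sqrt(m); b <- sqrt(1 - m)
      i <- cp@pair[1L]; j <- cp@pair[2L]
      X[i, ] <- X[i, ] + cp@amplitude *
        (a * shared + b * narrowbandNoise(nSamp, fs, cp@band@lo, cp@band@hi))
      X[j, ] <- X[j, ] + cp@amplitude *
        (a * lagged + b * narrowbandNoise(nSamp, fs, cp@band@lo, cp@band@hi))
    }
    for (p in design@pacs) {
      d <- groupValue(p@depth, group)
      theta <- narrowbandNoise(nSamp, fs, p@phaseBand@lo, p@phaseBand@hi)
      phase <- Arg(analyticSignal(theta))
      carrier <- narrowbandNoise(nSamp, fs, p@ampBand@lo, p@ampBand@hi)
      env <- (1 + d * cos(phase)) / (1 + d)
      X[p@roi, ] <- X[p@roi, ] + p@phaseAmplitude * theta +
        p@carrierAmplitude * carrier * env
    }
    if (design@noiseSd > 0)
      X <- X + design@noiseSd * matrix(stats::rnorm(length(X)), nrow(X))
    X
  })
  rownames(X) <- design@roiNames
  segment(X, epochLen = design@epochLen, samplingRate = fs,
          subjectId = subjectId, groupLabel = group)
}

#' Generate a labelled two-group cohort
#'
#' Produces \code{2 * nPerGroup} subjects. Per-subject seeds are derived from
#' the design seed by a stable modular hash over (seed, group index, subject
#' index), so any subject can be regenerated in isolation and no two
#' subjects share a stream.
#'
#' @param design a \code{\link{CohortDesign}}.
#' @return a named list of \code{\link{EpochedRecording}}s, impaired-group
#'   subjects first.
#' @export
generateCohort <- function(design) {
  validObject(design)
  out <- list()
  for (g in seq_along(design@groupLabels)) {
    group <- design@groupLabels[g]
    for (s in seq_len(design@nPerGroup)) {
      id <- sprintf("%s_%02d", group, s)
      stopIfNot(!id %in% names(out), sprintf("duplicate subject id '%s'", id))
      out[[id]] <- generateSubject(
        design, group, mixSeed(design@seed, g, s), subjectId = id)
    }
  }
  out
}

#' Write / read a cohort as plain-text epoch files
#'
#' One directory per subject holding one whitespace-separated text file per
#' epoch (rows = ROIs, columns = samples) and a JSON sidecar with sampling
#' rate, labels and ROI names; the cohort root carries a design sidecar with
#' the ground-truth effect table.
#'
#' @param cohort named list of \code{\link{EpochedRecording}}s.
#' @param dir output directory (created if needed).
#' @param design optional \code{\link{CohortDesign}} recorded in the root
#'   sidecar.
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir, design = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort)) {
    rec <- cohort[[id]]
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    for (e in seq_len(nEpochs(rec))) {
      utils::write.table(
        rec@data[e, , , drop = TRUE],
        file.path(sdir, sprintf("epoch_%04d.txt", e)),
        row.names = FALSE, col.names = FALSE)
    }
    side <- list(subjectId = rec@subjectId, groupLabel = rec@groupLabel,
                 samplingRate = rec@samplingRate,
                 channelNames = rec@channelNames, nEpochs = nEpochs(rec))
    jsonlite::write_json(side, file.path(sdir, "recording.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(design)) {
    truth <- list(
      nPerGroup = design@nPerGroup, groupLabels = design@groupLabels,
      noiseSd = design@noiseSd, samplingRate = design@samplingRate,
      epochLen = design@epochLen, nEpochs = design@nEpochs,
      seed = design@seed,
      couplings = lapply(design@couplings, function(cp) list(
        pair = design@roiNames[cp@pair], band = bandName(cp@band),
        phaseLag = cp@phaseLag, strength = as.list(cp@strength))),
      pacs = lapply(design@pacs, function(p) list(
        roi = design@roiNames[p@roi], depth = as.list(p@depth))))
    jsonlite::write_json(truth, file.path(dir, "design.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  stopIfNot(length(subs) > 0L, sprintf("no subject directories under '%s'", dir))
  out <- list()
  for (sdir in subs) {
    side <- jsonlite::fromJSON(file.path(sdir, "recording.json"))
    files <- sort(list.files(sdir, pattern = "^epoch_\\d+\\.txt$",
                             full.names = TRUE))
    stopIfNot(length(files) > 0L, sprintf("no epoch files in '%s'", sdir))
    epochs <- lapply(files, function(f)
      as.matrix(utils::read.table(f, header = FALSE)))
    data <- array(0, c(length(epochs), nrow(epochs[[1L]]), ncol(epochs[[1L]])))
    for (e in seq_along(epochs)) data[e, , ] <- epochs[[e]]
    out[[side$subjectId]] <- epochedRecording(
      data, side$samplingRate, channelNames = side$channelNames,
      subjectId = side$subjectId, groupLabel = side$groupLabel)
  }
  out
}
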