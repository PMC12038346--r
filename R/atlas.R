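#' The 24-ROI triple-network atlas
#'
#' Loads the packaged atlas of 24 cortical regions of interest: bilateral
#' primary/secondary visual (V1, V2) and auditory (A1, A2) cortex, and the
#' triple-network regions -- default mode (PHC, PCC, AG, MPFC), salience
#' (INS, dACC) and central executive (DLPFC, PPC) -- each with its Brodmann
#' label and network membership. ROI order is fixed (region order, left
#' before right) and defines the connectivity feature order.
#'
#' @param path path to an atlas JSON file; defaults to the packaged
#'   24-ROI resource.
#' @return a data.frame with columns \code{roi}, \code{region},
#'   \code{brodmann}, \code{abbrev}, \code{network}, \code{hemisphere}.
#' @examples
#' atlas <- loadAtlas()
#' nrow(atlas)       # 24
#' table(atlas$network)
#' @export
loadAtlas <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "atlas24.json", package = "TripleNetEEG",
                        mustWork = TRUE)
  stopIfNot(file.exists(path), sprintf("atlas file '%s' not found", path))
  atlas <- jsonlite::fromJSON(path)$rois
  stopIfNot(is.data.frame(atlas) && nrow(atlas) >= 2L,
            "atlas must list at least two ROIs")
  stopIfNot(!anyDuplicated(atlas$roi), "duplicate ROI names in atlas")
  atlas
}

#' ROI pair order for connectivity vectorization
#'
#' Upper-triangle pairs (i < j), row-major over the given ROI order; this is
#' the fixed feature order of the connectivity vector (n*(n-1)/2 pairs;
#' 276 for 24 ROIs). Pair names join the two ROI names with \code{"--"}.
#'
#' @param roiNames character vector of ROI names in atlas order.
#' @return data.frame with columns \code{i}, \code{j}, \code{name}.
#' @examples
#' nrow(roiPairs(loadAtlas()$roi))   # 276
#' @export
roiPairs <- function(roiNames) {
  n <- length(roiNames)
  stopIfNot(n >= 2L, "need at least two ROIs")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  data.frame(i = idx[, "row"], j = idx[, "col"],
             name = paste(roiNames[idx[, "row"]], roiNames[idx[, "col"]],
                          sep = "--"),
             stringsAsFactors = FALSE)
}

#' Annotate connection features with network-pair classes
#'
#' Maps each ROI-pair feature name (e.g. \code{"L_V2--R_INS"}) to its
#' unordered network pair (e.g. \code{"SN-VN"}) under the atlas network
#' membership, and counts features per class.
#'
#' @param features character vector of pair names (\code{"roi--roi"}).
#' @param atlas atlas data.frame from \code{\link{loadAtlas}}.
#' @return data.frame with columns \code{networkPair} and \code{count},
#'   sorted by decreasing count; zero rows for an empty feature set.
#' @examples
#' networkAnnotate("L_V2--R_INS", loadAtlas())
#' @export
networkAnnotate <- function(features, atlas) {
  if (length(features) == 0L)
    return(data.frame(networkPair = character(0), count = integer(0)))
  parts <- strsplit(features, "--", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 2L
  stopIfNot(!any(bad), "features must be 'roi--roi' pair names")
  net <- stats::setNames(atlas$network, atlas$roi)
  classes <- vapply(parts, function(p) {
    stopIfNot(all(p %in% names(net)),
              sprintf("unknown ROI in feature '%s'", paste(p, collapse = "--")))
    paste(sort(net[p]), collapse = "-")
  }, "")
  tab <- sort(table(classes), decreasing = TRUE)
  data.frame(networkPair = names(tab), count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
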