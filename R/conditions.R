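# Classed error conditions so callers can distinguish failure modes
# (e.g. an unstable cluster solution is recoverable; a geometry mismatch is not).

hippStop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "hippclusterError", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' @name hippcluster-conditions
#' @title Error conditions raised by hippcluster
#' @description All errors raised by the package carry the class
#'   `hippclusterError` plus one specific subclass:
#'   \describe{
#'     \item{degenerateGeometryError}{ground-truth geometry cannot hold the
#'       requested number of slabs}
#'     \item{emptyRoiError}{atlas thresholding left no voxels}
#'     \item{invalidAtlasError}{atlas values outside \[0, 1\]}
#'     \item{geometryError}{spatial dimensions of a volume and mask disagree}
#'     \item{invalidDataError}{non-finite values in voxel data}
#'     \item{alignmentError}{voxel lists or partition universes do not match}
#'     \item{invalidLabelsError}{label vector is not a valid partition}
#'     \item{undefinedIndexError}{Calinski-Harabasz index undefined (K = 1 or
#'       K = N)}
#'     \item{unstableSolutionError}{the cut-height search visited no partition
#'       with 2 <= K <= N - 1}
#'     \item{insufficientDataError}{too few complete subjects or factor levels
#'       for the requested analysis}
#'   }
#' @keywords internal
NULL
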