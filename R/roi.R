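# Builds the clustering substrate Z: probabilistic-atlas thresholding, in-mask
# time-series extraction, per-voxel standardization and concatenation across
# subjects. Left and right hippocampus are handled as entirely separate runs;
# nothing here mixes hemispheres.

#' Threshold a probabilistic atlas into an ROI mask
#'
#' A voxel enters the mask when its atlas fraction is greater than or equal to
#' the threshold (inclusive comparison). The default 0.75 reproduces the
#' conservative convention that a hippocampal voxel must be present in at
#' least 28 of the 37 reference subjects of a 37-subject atlas.
#'
#' @param atlas 3D array of fractions in \[0, 1\], or a path to a NIfTI file.
#' @param threshold inclusion threshold in \[0, 1\].
#' @param geom a [VolumeGeometry-class]; required when `atlas` is an array.
#' @return a [RoiMask-class].
#' @examples
#' a <- array(c(0.8, 0.5), c(2, 1, 1))
#' voxelList(thresholdAtlas(a, 0.75, VolumeGeometry(c(2, 1, 1))))
#' @export
thresholdAtlas <- function(atlas, threshold = 0.75, geom = NULL) {
  if (is.character(atlas)) {
    v <- readVolume(atlas)
    atlas <- v$data
    geom <- v$geometry
  }
  if (is.null(geom)) geom <- VolumeGeometry(dim(atlas))
  stopifnot(threshold >= 0, threshold <= 1)
  if (any(!is.finite(atlas)) || any(atlas < 0) || any(atlas > 1))
    hippStop("invalidAtlasError", "atlas values must be fractions in [0, 1]")
  mask <- atlas >= threshold
  if (!any(mask))
    hippStop("emptyRoiError",
             sprintf("no voxel reaches atlas threshold %g", threshold))
  vl <- which(mask, arr.ind = TRUE)
  dimnames(vl) <- NULL
  new("RoiMask", mask = mask, voxelList = vl, geometry = geom)
}

#' Extract in-mask voxel time series
#'
#' Row r of the result is the full time series of `voxelList(roi)[r, ]`.
#'
#' @param volume4d 4D array or path to a 4D NIfTI; spatial dims must equal the
#'   ROI geometry dims.
#' @param roi a [RoiMask-class].
#' @param subjectId,condition identifiers carried on the result.
#' @return a [SubjectSeries-class] (N voxels x T timepoints).
#' @export
extractTimeseries <- function(volume4d, roi, subjectId = "subject",
                              condition = "condition") {
  if (is.character(volume4d)) volume4d <- readVolume(volume4d)$data
  d <- dim(volume4d)
  if (length(d) != 4L || !identical(as.integer(d[1:3]), roi@geometry@dims))
    hippStop("geometryError",
             "4D volume spatial dims do not match the ROI geometry")
  flat <- matrix(volume4d, prod(d[1:3]), d[4])
  lin <- which(roi@mask)
  dat <- flat[lin, , drop = FALSE]
  if (any(!is.finite(dat)))
    hippStop("invalidDataError", "non-finite values inside the ROI")
  new("SubjectSeries", data = dat, subjectId = subjectId,
      condition = condition, voxelList = roi@voxelList)
}

#' Standardize voxel time series
#'
#' z-scores each voxel's series (sample SD, n - 1 denominator) so that the
#' Euclidean distances used downstream reflect time-course shape rather than
#' amplitude. Constant rows become all-zero rows and are reported with a
#' warning. Idempotent.
#'
#' @param series a [SubjectSeries-class].
#' @param method "zscore" (default) or "none".
#' @return a [SubjectSeries-class] with transformed rows.
#' @export
standardizeSeries <- function(series, method = c("zscore", "none")) {
  method <- match.arg(method)
  if (method == "none") return(series)
  x <- series@data
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  const <- sdv == 0
  if (any(const)) {
    warning(sprintf("%d constant voxel series set to zero", sum(const)))
    sdv[const] <- 1
  }
  z <- (x - mu) / sdv
  z[const, ] <- 0
  series@data <- z
  series
}

#' Concatenate subjects into the group matrix
#'
#' Column-binds the subjects' series matrices (which must share an identical
#' voxel list) into the N x p group matrix Z, recording each subject's column
#' block. Pairwise Euclidean distances on Z are invariant to the
#' concatenation order.
#'
#' @param seriesList nonempty list of [SubjectSeries-class] objects.
#' @return a [GroupMatrix-class].
#' @export
concatenateSubjects <- function(seriesList) {
  stopifnot(length(seriesList) >= 1L)
  vl <- seriesList[[1]]@voxelList
  same <- vapply(seriesList, function(s) identical(s@voxelList, vl), TRUE)
  if (!all(same))
    hippStop("alignmentError", "subjects have different voxel lists")
  Z <- do.call(cbind, lapply(seriesList, function(s) s@data))
  bounds <- c(0L, cumsum(vapply(seriesList, function(s) ncol(s@data), 1L)))
  ids <- vapply(seriesList, function(s) s@subjectId, "")
  new("GroupMatrix", Z = Z, subjectBoundaries = as.integer(bounds),
      voxelList = vl, includedSubjects = ids)
}
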